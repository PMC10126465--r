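#' Fit the four-phase germination model to a normalized trace
#'
#' Finds the breakpoint frames `(b1, b2, b3)` minimizing the sum of squared
#' errors of the continuous piecewise-linear model: a lag segment starting
#' at value 1 with non-positive slope, a rapid-release segment at least
#' `steepness_factor` times steeper, a lysis segment decreasing to 0, and a
#' constant-0 tail.  For fixed breakpoints the profiled SSE is solved in
#' closed form, so the search is exact over whichever breakpoint grid is
#' enumerated: either the full ordered-triple enumeration (`oracle = TRUE`,
#' also used automatically for short traces) or a coarse grid of every
#' `coarse_step`-th frame followed by exhaustive refinement within
#' `+/- coarse_step` of the coarse optimum.  SSE ties are broken toward
#' the lexicographically smallest `(b1, b2, b3)`.
#'
#' The spore is called germinated when the piecewise fit improves on the
#' best single-line fit by at least `min_improvement` (relative SSE
#' reduction); a flat or linear trace never passes this test.
#'
#' Reported quantities: `t_lag`, `t_release`, `t_lys` are the breakpoint
#' times; `delta_t_release = t_release - t_lag` (duration of rapid CaDPA
#' release); `delta_t_lys = t_lys - t_release` (duration of cortex lysis);
#' `i_lag`, `i_release` are the fitted model values at the first two
#' breakpoints.
#'
#' @param trace an `intensity_trace` that has been through
#'   [normalize_trace()]; non-candidates return a non-germinated record.
#' @param coarse_step coarse grid spacing in frames (default 4).
#' @param min_improvement minimum relative SSE improvement over a single
#'   line to call germination (default 0.5).
#' @param steepness_factor required ratio of release-segment to
#'   lag-segment slope (default 3); prevents the leak phase from absorbing
#'   the release phase on noisy traces.
#' @param oracle if `TRUE`, enumerate all ordered breakpoint triples.
#' @return a one-row `data.frame` (class `germination_kinetics`) with
#'   columns `spore_id`, `germinated`, `t_lag`, `t_release`, `t_lys`,
#'   `delta_t_release`, `delta_t_lys`, `i_lag`, `i_release`, `fit_sse`.
#' @export
fit_kinetics <- function(trace, coarse_step = 4, min_improvement = 0.5,
                         steepness_factor = 3, oracle = FALSE) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$times)
  if (n < 8) stop("trace shorter than 8 frames")
  blank <- data.frame(spore_id = trace$spore_id, germinated = FALSE,
                      t_lag = NA_real_, t_release = NA_real_,
                      t_lys = NA_real_, delta_t_release = NA_real_,
                      delta_t_lys = NA_real_, i_lag = NA_real_,
                      i_release = NA_real_, fit_sse = NA_real_,
                      stringsAsFactors = FALSE)
  class(blank) <- c("germination_kinetics", "data.frame")
  if (!isTRUE(trace$germination_candidate) || is.null(trace$normalized))
    return(blank)

  y <- trace$normalized
  t <- trace$times
  if (oracle || n <= 60) {
    fit <- .pwl_search(y, t, 1:(n - 1), steepness_factor)
  } else {
    grid <- unique(c(seq(1L, n - 1L, by = as.integer(coarse_step)), n - 1L))
    fit <- .pwl_search(y, t, grid, steepness_factor)
    nb <- function(b) max(1L, b - coarse_step):min(n - 1L, b + coarse_step)
    refine <- sort(unique(c(nb(fit$b1), nb(fit$b2), nb(fit$b3))))
    fit2 <- .pwl_search(y, t, refine, steepness_factor)
    if (fit2$sse < fit$sse) fit <- fit2
  }

  # germination call: relative improvement over the best single line
  line <- lm(y ~ t)
  sse_line <- sum(residuals(line)^2)
  germinated <- sse_line > 1e-12 &&
    (sse_line - fit$sse) / sse_line >= min_improvement
  if (!germinated) return(blank)

  t0 <- t[1]
  out <- data.frame(spore_id = trace$spore_id, germinated = TRUE,
                    t_lag = t[fit$b1 + 1] - t0,
                    t_release = t[fit$b2 + 1] - t0,
                    t_lys = t[fit$b3 + 1] - t0,
                    delta_t_release = t[fit$b2 + 1] - t[fit$b1 + 1],
                    delta_t_lys = t[fit$b3 + 1] - t[fit$b2 + 1],
                    i_lag = fit$i_lag, i_release = fit$i_release,
                    fit_sse = fit$sse, stringsAsFactors = FALSE)
  class(out) <- c("germination_kinetics", "data.frame")
  out
}

#' Profiled SSE of the four-phase model at fixed breakpoints
#'
#' Exposes the closed-form inner solver used by [fit_kinetics()]:
#' minimizes the SSE over `(i_lag, i_release)` subject to the slope
#' constraints, for one breakpoint triple (0-based frame indices).
#'
#' @param y normalized trace values.
#' @param t frame times.
#' @param b1,b2,b3 breakpoint frames, `1 <= b1 < b2 < b3 <= n-1` (0-based).
#' @param steepness_factor see [fit_kinetics()].
#' @return list with `sse`, `i_lag`, `i_release`.
#' @export
pwl_sse <- function(y, t, b1, b2, b3, steepness_factor = 3) {
  .pwl_sse_triple(y, t, as.integer(b1), as.integer(b2), as.integer(b3),
                  steepness_factor)
}

#' Normalize and fit a list of traces
#'
#' @param traces list of `intensity_trace` objects (raw or already
#'   normalized).
#' @param ... passed to [fit_kinetics()].
#' @param drop_fraction_threshold,tail_frames passed to
#'   [normalize_trace()] for traces not yet normalized.
#' @return a `data.frame` with one [fit_kinetics()] row per trace.
#' @export
fit_population <- function(traces, drop_fraction_threshold = 0.4,
                           tail_frames = 4, ...) {
  rows <- lapply(traces, function(tr) {
    if (is.na(tr$germination_candidate))
      tr <- normalize_trace(tr, drop_fraction_threshold, tail_frames)
    fit_kinetics(tr, ...)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("germination_kinetics", "data.frame")
  out
}

#' Summarize germination kinetics over a population
#'
#' Parameter means and standard deviations are computed over germinated
#' spores only; the germinated fraction is over all spores.  The
#' cumulative germination curve gives, for each frame time, the fraction
#' of all spores whose fitted `t_release` is at or before that time; it is
#' non-decreasing and ends at the germinated fraction.
#'
#' @param kinetics a `data.frame` of [fit_kinetics()] rows.
#' @param times frame times in minutes for the cumulative curve.
#' @return a list of class `population_summary` with `n_total`,
#'   `n_germinated`, `germinated_fraction`, `stats` (a `data.frame` with
#'   `parameter`, `mean`, `sd`) and `cumulative` (a `data.frame` with
#'   `time_min`, `fraction_germinated`).
#' @export
summarize_population <- function(kinetics, times) {
  stopifnot(nrow(kinetics) >= 1)
  g <- kinetics[kinetics$germinated, , drop = FALSE]
  pars <- c("t_lag", "t_release", "t_lys", "delta_t_release",
            "delta_t_lys", "i_lag", "i_release")
  stats_df <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p)
      if (nrow(g) > 0) mean(g[[p]]) else NA_real_, 0),
    sd = vapply(pars, function(p)
      if (nrow(g) > 1) sd(g[[p]]) else NA_real_, 0),
    stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL
  cumulative <- data.frame(
    time_min = times,
    fraction_germinated = vapply(times, function(tt)
      sum(g$t_release <= tt) / nrow(kinetics), 0))
  structure(list(n_total = nrow(kinetics), n_germinated = nrow(g),
                 germinated_fraction = nrow(g) / nrow(kinetics),
                 stats = stats_df, cumulative = cumulative),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat("population_summary:", x$n_germinated, "of", x$n_total,
      sprintf("spores germinated (%.1f%%)\n", 100 * x$germinated_fraction))
  print(x$stats, row.names = FALSE)
  invisible(x)
}
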