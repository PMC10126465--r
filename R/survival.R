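#' Reconstruct a viable titer from dilution-spot counts at one timepoint
#'
#' Replicate counts at each dilution are averaged, then the largest (most
#' dilute) dilution whose mean count lies in the countable window
#' (default 3-30 colonies per spot) is used:
#' `titer = mean_count * 10^dilution / spot_volume`.  If no dilution
#' qualifies, the dilution with mean count closest to the window is used
#' and the estimate is flagged `"outside_window"`.  If every count at
#' every dilution is zero the titer is reported at the detection limit
#' `1 * 10^min(dilution) / spot_volume` and flagged `"below_detection"`.
#'
#' @param records a `data.frame` for a single timepoint with columns
#'   `dilution_exponent`, `spot_volume_ml` and one or more `count_rep*`
#'   columns.
#' @param countable_window inclusive mean-count window (default `c(3, 30)`).
#' @return a list with `titer` (CFU/mL), `dilution_used`, `mean_count` and
#'   `flag` (`"ok"`, `"outside_window"` or `"below_detection"`).
#' @export
titer_from_spots <- function(records, countable_window = c(3, 30)) {
  stopifnot(nrow(records) >= 1,
            all(c("dilution_exponent", "spot_volume_ml") %in% names(records)))
  cols <- grep("^count_rep", names(records), value = TRUE)
  if (length(cols) == 0) stop("no count_rep* columns found")
  counts <- as.matrix(records[, cols, drop = FALSE])
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  means <- rowMeans(counts)
  vol <- records$spot_volume_ml[1]

  if (all(counts == 0)) {
    d_min <- min(records$dilution_exponent)
    return(list(titer = 1 * 10^d_min / vol, dilution_used = d_min,
                mean_count = 0, flag = "below_detection"))
  }
  in_window <- means >= countable_window[1] & means <= countable_window[2]
  if (any(in_window)) {
    i <- which(in_window)
    i <- i[which.max(records$dilution_exponent[i])]
    flag <- "ok"
  } else {
    dist <- pmax(countable_window[1] - means, means - countable_window[2], 0)
    i <- which.min(dist)
    flag <- "outside_window"
  }
  list(titer = means[i] * 10^records$dilution_exponent[i] / vol,
       dilution_used = records$dilution_exponent[i],
       mean_count = means[i], flag = flag)
}

#' Build a survival series from a full spot-count table
#'
#' Applies [titer_from_spots()] per timepoint and expresses survival as
#' log10 fraction relative to the first timepoint.
#'
#' @param counts a table as produced by [generate_survival_counts()] (or
#'   read from CSV with the same columns).
#' @param countable_window passed to [titer_from_spots()].
#' @return a `data.frame` with `time_min`, `titer`, `log10_survival`
#'   (0 at the first timepoint by construction), `dilution_used`, `flag`.
#' @export
survival_series <- function(counts, countable_window = c(3, 30)) {
  times <- sort(unique(counts$time_min))
  rows <- lapply(times, function(tt) {
    est <- titer_from_spots(counts[counts$time_min == tt, , drop = FALSE],
                            countable_window)
    data.frame(time_min = tt, titer = est$titer,
               dilution_used = est$dilution_used, flag = est$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$log10_survival <- log10(out$titer) - log10(out$titer[1])
  out[, c("time_min", "titer", "log10_survival", "dilution_used", "flag")]
}

#' Fit log-linear (first-order) inactivation
#'
#' Least-squares line through `log10(titer)` versus time.  The decimal
#' reduction time is `D = -1 / slope` (minutes per 10-fold kill) and the
#' first-order rate constant `k = ln(10) / D` per minute.  Below-detection
#' points are excluded and a non-negative slope yields an infinite D
#' (no measurable killing), flagged.
#'
#' @param times treatment times in minutes.
#' @param titers viable titers, CFU/mL (positive).
#' @param flags optional per-point flags; points flagged
#'   `"below_detection"` are excluded.
#' @return a list of class `decay_fit` with `slope` (log10/min),
#'   `intercept`, `d_value` (min), `k` (1/min), `n_used` and `flag`
#'   (`"ok"` or `"no_killing"`).
#' @export
fit_decay <- function(times, titers, flags = NULL) {
  keep <- titers > 0
  if (!is.null(flags)) keep <- keep & flags != "below_detection"
  times <- times[keep]; titers <- titers[keep]
  if (length(times) < 3)
    stop("need at least 3 timepoints with positive, detectable titers")
  fit <- lm(log10(titers) ~ times)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope >= 0) {
    return(structure(list(slope = slope, intercept = intercept,
                          d_value = Inf, k = 0, n_used = length(times),
                          flag = "no_killing"), class = "decay_fit"))
  }
  d <- -1 / slope
  structure(list(slope = slope, intercept = intercept, d_value = d,
                 k = log(10) / d, n_used = length(times), flag = "ok"),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: D = %.3g min (k = %.3g /min) from %d points%s\n",
              x$d_value, x$k, x$n_used,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Full survival pipeline: counts table to D-value
#'
#' @param counts a spot-count table (see [survival_series()]).
#' @param countable_window passed to [titer_from_spots()].
#' @return a list with `series` (the titer table) and `fit` (a
#'   `decay_fit`).
#' @export
analyze_survival <- function(counts, countable_window = c(3, 30)) {
  series <- survival_series(counts, countable_window)
  fit <- fit_decay(series$time_min, series$titer, series$flag)
  list(series = series, fit = fit)
}
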