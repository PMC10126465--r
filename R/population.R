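#' Germination rate and extent from a population curve
#'
#' Operationalizes "germination rate" as the maximum slope of the smoothed
#' baseline-subtracted fluorescence curve.  Smoothing is a centered moving
#' average (window `smooth_window` readings), which preserves the slope of
#' linear segments exactly; slopes are centered finite differences, and
#' edge readings without a full smoothing window are excluded.  The
#' plateau is the mean of the final 10% of readings, and when the
#' boiled-control reading is available, the germination extent is the
#' plateau signal as a percentage of total CaDPA:
#' `100 * (plateau - baseline) / (total_cadpa_signal - baseline)`.
#'
#' @param curve a `population_curve` (at least 5 timepoints).
#' @param smooth_window moving-average window in readings (odd; default 5).
#' @param plateau_fraction final fraction of readings averaged for the
#'   plateau (default 0.1).
#' @return a list of class `germination_metrics` with `max_rate` (RFU/min),
#'   `t_max_rate` (min), `plateau_rfu` and `extent_percent` (`NA` without a
#'   total-CaDPA reading).
#' @export
compute_metrics <- function(curve, smooth_window = 5,
                            plateau_fraction = 0.1) {
  stopifnot(inherits(curve, "population_curve"), length(curve$times) >= 5,
            smooth_window >= 1, smooth_window %% 2 == 1)
  total <- curve$total_cadpa_signal
  if (!is.null(total) && total <= curve$baseline)
    stop("total_cadpa_signal must exceed the baseline")

  y <- curve$rfu - curve$baseline
  sm <- if (smooth_window > 1)
    as.numeric(stats::filter(y, rep(1 / smooth_window, smooth_window),
                             sides = 2)) else y
  t <- curve$times
  n <- length(t)
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  ok <- which(!is.na(slope))
  max_rate <- max(slope[ok])
  t_max_rate <- t[ok[which.max(slope[ok])]]

  n_tail <- max(1L, ceiling(plateau_fraction * n))
  plateau_rfu <- mean(tail(curve$rfu, n_tail))
  extent <- if (is.null(total)) NA_real_ else
    100 * (plateau_rfu - curve$baseline) / (total - curve$baseline)
  structure(list(condition = curve$condition, max_rate = max_rate,
                 t_max_rate = t_max_rate, plateau_rfu = plateau_rfu,
                 extent_percent = extent),
            class = "germination_metrics")
}

#' @export
print.germination_metrics <- function(x, ...) {
  cat(sprintf("germination_metrics '%s': max rate %.3g RFU/min at %.3g min%s\n",
              x$condition, x$max_rate, x$t_max_rate,
              if (is.na(x$extent_percent)) ""
              else sprintf(", extent %.1f%%", x$extent_percent)))
  invisible(x)
}

#' Select the heat-activation time giving the fastest germination
#'
#' Spores are heat-activated for various times before adding germinant;
#' over-activation damages germination proteins and slows release.  This
#' picks the activation time whose curve has the largest maximum
#' germination rate; ties go to the shorter activation time.
#'
#' @param curves named list of `population_curve` objects; names are the
#'   activation times in minutes.
#' @param ... passed to [compute_metrics()].
#' @return a list with `optimal_activation_min` and `metrics`, a
#'   `data.frame` of per-activation metrics sorted by activation time.
#' @export
select_optimal_activation <- function(curves, ...) {
  stopifnot(length(curves) >= 2, !is.null(names(curves)))
  act <- as.numeric(names(curves))
  stopifnot(!any(is.na(act)))
  rows <- lapply(seq_along(curves), function(i) {
    m <- compute_metrics(curves[[i]], ...)
    data.frame(activation_min = act[i], max_rate = m$max_rate,
               t_max_rate = m$t_max_rate, plateau_rfu = m$plateau_rfu,
               extent_percent = m$extent_percent)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$activation_min), ]
  rownames(tab) <- NULL
  best <- tab$activation_min[tab$max_rate == max(tab$max_rate)]
  list(optimal_activation_min = min(best), metrics = tab)
}

#' Relative CaDPA content per spore
#'
#' Boil-release fluorescence normalized by the microscopically counted
#' spore number, expressed relative to a reference strain set at 100.
#'
#' @param samples a `data.frame` with columns `label`, `boil_release_rfu`,
#'   `blank_rfu`, `spore_count`.
#' @param reference_label label of the reference (e.g. wild-type) sample.
#' @return the table with added `per_spore_signal` and
#'   `relative_content` (reference = 100) columns.
#' @export
relative_cadpa <- function(samples, reference_label) {
  stopifnot(all(c("label", "boil_release_rfu", "blank_rfu",
                  "spore_count") %in% names(samples)),
            reference_label %in% samples$label,
            all(samples$spore_count > 0))
  s <- (samples$boil_release_rfu - samples$blank_rfu) / samples$spore_count
  s_ref <- s[match(reference_label, samples$label)]
  if (s_ref <= 0) stop("reference per-spore signal must be positive")
  samples$per_spore_signal <- s
  samples$relative_content <- 100 * s / s_ref
  samples
}
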