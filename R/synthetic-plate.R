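#' Per-spore released-CaDPA fraction
#'
#' Mirror image of the intensity model restricted to the CaDPA phases: a
#' slow leak `leak_slope * t` during the lag, a linear rise to 1 (release
#' complete) at `t_release`, and 1 thereafter.  Cortex lysis does not move
#' CaDPA, so the fraction saturates at `t_release`.  Non-germinating spores
#' release nothing.
#'
#' @param spore one row of a [generate_truth()] table.
#' @param times numeric vector of times in minutes.
#' @return released fractions in \[0, 1\], same length as `times`.
#' @export
released_fraction <- function(spore, times) {
  if (!isTRUE(spore$germinates[1])) return(rep(0, length(times)))
  t_lag <- spore$t_lag[1]; t_rel <- spore$t_release[1]
  leak <- spore$leak_slope[1]
  r_lag <- leak * t_lag                      # leaked by onset of rapid release
  r <- numeric(length(times))
  ph1 <- times < t_lag
  ph2 <- times >= t_lag & times < t_rel
  r[ph1] <- leak * times[ph1]
  r[ph2] <- r_lag + (1 - r_lag) * (times[ph2] - t_lag) / (t_rel - t_lag)
  r[times >= t_rel] <- 1
  r
}

#' Generate a synthetic Tb-DPA plate-reader germination curve
#'
#' Superposes the single-spore release schedules of a simulated population:
#' each of the `n` spores contributes `total_signal / n` RFU when fully
#' released, so the expected plateau is
#' `baseline + total_signal * frac_germinating`.  The boiled-control
#' reading for the same aliquot (all CaDPA released) is stored as
#' `total_cadpa_signal = baseline + total_signal`.
#'
#' @param truth a [generate_truth()] table.
#' @param total_signal RFU contributed by complete release from all spores
#'   (> 0).
#' @param baseline instrument baseline RFU.
#' @param frame_interval minutes between plate-reader readings.
#' @param duration total monitoring time in minutes (> 0).
#' @param noise_sd Gaussian reading noise, RFU.
#' @param condition label carried on the curve.
#' @param seed integer RNG seed.
#' @return a `population_curve` object: list with `condition`, `times`,
#'   `rfu`, `baseline`, `total_cadpa_signal`.
#' @export
generate_population_fluorescence <- function(truth, total_signal = 1000,
                                             baseline = 50,
                                             frame_interval = 0.5,
                                             duration = 60, noise_sd = 0,
                                             condition = "synthetic",
                                             seed = 1L) {
  stopifnot(total_signal > 0, nrow(truth) >= 1)
  if (duration <= 0) stop("duration must be positive")
  times <- seq(0, duration, by = frame_interval)
  n <- nrow(truth)
  total_r <- numeric(length(times))
  for (i in seq_len(n))
    total_r <- total_r + released_fraction(truth[i, ], times)
  rfu <- baseline + total_signal * total_r / n
  if (noise_sd > 0)
    rfu <- with_seed(seed, rfu + rnorm(length(rfu), sd = noise_sd))
  population_curve(condition, times, rfu, baseline = baseline,
                   total_cadpa_signal = baseline + total_signal)
}

#' Construct a population germination curve
#'
#' @param condition label (strain, germinant, activation time, ...).
#' @param times strictly increasing times in minutes.
#' @param rfu relative fluorescence units, same length as `times`.
#' @param baseline instrument baseline RFU.
#' @param total_cadpa_signal optional boiled-control RFU reading for the
#'   same spore aliquot (complete release).
#' @return an object of class `population_curve`.
#' @export
population_curve <- function(condition, times, rfu, baseline = 0,
                             total_cadpa_signal = NULL) {
  stopifnot(length(times) == length(rfu), all(diff(times) > 0))
  structure(list(condition = condition, times = times, rfu = rfu,
                 baseline = baseline,
                 total_cadpa_signal = total_cadpa_signal),
            class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat("population_curve '", x$condition, "': ", length(x$times),
      " readings over ", max(x$times), " min, baseline ", x$baseline,
      " RFU\n", sep = "")
  invisible(x)
}
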