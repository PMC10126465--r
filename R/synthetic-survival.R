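#' Generate synthetic dilution-spot colony counts under first-order killing
#'
#' Emulates the wet-heat killing assay readout: the viable titer decays as
#' `N(t) = n0 * 10^(-t / d_value)` (first-order inactivation with decimal
#' reduction time `d_value`), samples are serially diluted 10-fold, and
#' `spot_volume` mL aliquots are plated in replicate.  Each replicate count
#' is a Poisson draw with mean `N(t) * spot_volume * 10^(-dilution)`.
#'
#' @param n0 initial titer, CFU/mL.
#' @param d_value decimal reduction time in minutes (> 0).
#' @param times treatment times in minutes (>= 0).
#' @param dilutions integer 10-fold dilution exponents (>= 0).
#' @param spot_volume spotted volume in mL (default 0.01 = 10 uL).
#' @param replicates spots per (time, dilution); default 2 (duplicates).
#' @param seed integer RNG seed.
#' @return a `data.frame` with one row per (time, dilution): columns
#'   `time_min`, `dilution_exponent`, `spot_volume_ml`, `expected_count`
#'   (the analytic Poisson mean) and `count_rep1`, ..., `count_repR`.
#' @export
generate_survival_counts <- function(n0, d_value, times, dilutions,
                                     spot_volume = 0.01, replicates = 2,
                                     seed = 1L) {
  if (any(times < 0)) stop("negative treatment time")
  stopifnot(d_value > 0, spot_volume > 0, replicates >= 1, n0 > 0,
            all(dilutions >= 0))
  grid <- expand.grid(dilution_exponent = as.integer(sort(dilutions)),
                      time_min = sort(times))
  grid <- grid[, c("time_min", "dilution_exponent")]
  mu <- n0 * 10^(-grid$time_min / d_value) * spot_volume *
    10^(-grid$dilution_exponent)
  counts <- with_seed(seed, {
    matrix(rpois(nrow(grid) * replicates, rep(mu, each = replicates)),
           ncol = replicates, byrow = TRUE)
  })
  colnames(counts) <- sprintf("count_rep%d", seq_len(replicates))
  out <- cbind(grid,
               data.frame(spot_volume_ml = spot_volume,
                          expected_count = mu),
               as.data.frame(counts))
  rownames(out) <- NULL
  out
}
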