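#' Population parameters for synthetic spore ground truth
#'
#' Bundles the statistical description of a simulated spore population:
#' how many spores, what fraction germinate, and the distributions of the
#' per-spore kinetic parameters.  Germination heterogeneity is modeled as a
#' Bernoulli mixture (germinates yes/no) with independent positive-support
#' draws of the lag time, rapid-release duration and cortex-lysis duration
#' for each germinating spore.
#'
#' Distributions are given as `list(family, ...)` with families
#' `"lognormal"` (`meanlog`, `sdlog`), `"gamma"` (`shape`, `rate`) or
#' `"uniform"` (`min`, `max`); all must have positive support.
#'
#' @param n_spores number of spores (>= 1); default 300, the typical number
#'   of individual spores followed in one time-lapse field.
#' @param frac_germinating fraction of spores that germinate, in \[0, 1\].
#' @param t_lag_dist distribution of the lag time Tlag in minutes.
#' @param dt_release_dist distribution of the rapid CaDPA release duration
#'   (Trelease - Tlag) in minutes; short (~1 min) by default.
#' @param dt_lys_dist distribution of the cortex lysis duration
#'   (Tlys - Trelease) in minutes; several-fold longer than the release
#'   phase by default, so that the release and lysis segments have clearly
#'   distinct slopes across the sampled range (a spore whose two phases
#'   are collinear has no identifiable Trelease even in principle).
#' @param leak_slope_range range (min, max) of the slow CaDPA leak slope
#'   during the lag phase, in normalized intensity units per minute.
#' @param i_release_range range of the normalized intensity at Trelease.
#' @param seed integer RNG seed.
#' @return an object of class `population_params` (a named list).
#' @export
population_params <- function(n_spores = 300,
                              frac_germinating = 0.9,
                              t_lag_dist = list(family = "lognormal",
                                                meanlog = log(10), sdlog = 0.3),
                              dt_release_dist = list(family = "lognormal",
                                                     meanlog = log(1.2),
                                                     sdlog = 0.2),
                              dt_lys_dist = list(family = "lognormal",
                                                 meanlog = log(7),
                                                 sdlog = 0.25),
                              leak_slope_range = c(0.001, 0.005),
                              i_release_range = c(0.40, 0.55),
                              seed = 1L) {
  stopifnot(n_spores >= 1, frac_germinating >= 0, frac_germinating <= 1,
            length(leak_slope_range) == 2, all(leak_slope_range >= 0),
            length(i_release_range) == 2,
            all(i_release_range > 0), all(i_release_range < 1))
  for (d in list(t_lag_dist, dt_release_dist, dt_lys_dist)) .check_dist(d)
  structure(list(n_spores = as.integer(n_spores),
                 frac_germinating = frac_germinating,
                 t_lag_dist = t_lag_dist,
                 dt_release_dist = dt_release_dist,
                 dt_lys_dist = dt_lys_dist,
                 leak_slope_range = leak_slope_range,
                 i_release_range = i_release_range,
                 seed = as.integer(seed)),
            class = "population_params")
}

.check_dist <- function(d) {
  if (!is.list(d) || is.null(d$family))
    stop("distribution must be a list with a 'family' element")
  switch(d$family,
         lognormal = stopifnot(is.numeric(d$meanlog), d$sdlog >= 0),
         gamma = stopifnot(d$shape > 0, d$rate > 0),
         uniform = stopifnot(d$min > 0, d$min <= d$max),
         stop("unknown distribution family: ", d$family))
  invisible(TRUE)
}

.draw_dist <- function(d, n) {
  switch(d$family,
         lognormal = rlnorm(n, d$meanlog, d$sdlog),
         gamma = rgamma(n, shape = d$shape, rate = d$rate),
         uniform = runif(n, d$min, d$max))
}

#' Imaging parameters for the synthetic time-lapse renderer
#'
#' Defaults follow a phase-contrast setup with a 12-bit CCD camera with
#' 1340 x 1024 pixel frames recorded every 15 s.  Spores are rendered as
#' hard discs; detection difficulty is tuned through `noise_sd`.
#'
#' @param frame_interval minutes between frames (default 0.25 = 15 s).
#' @param duration total recording time in minutes.
#' @param width,height frame size in pixels.
#' @param bit_depth camera bit depth; pixel values live in
#'   \[0, 2^bit_depth - 1\].
#' @param spore_radius disc radius in pixels.
#' @param background_level,spore_amplitude background offset and dormant
#'   spore amplitude above background, in intensity counts.  Defaults give
#'   a dormant spore a windowed (20 x 20 mean) intensity drop fraction of
#'   about 0.79 on full germination, comfortably above the 0.4
#'   germination-candidate threshold of [normalize_trace()].
#' @param noise_sd Gaussian pixel noise standard deviation in counts.
#' @param min_separation minimum center-to-center spore distance in pixels
#'   (>= 2 * spore_radius); default 20 matches the analysis window so that
#'   20 x 20 windows of distinct spores never overlap.
#' @return an object of class `imaging_params`.
#' @export
imaging_params <- function(frame_interval = 0.25, duration = 40,
                           width = 1340, height = 1024, bit_depth = 12,
                           spore_radius = 4, background_level = 100,
                           spore_amplitude = 3000, noise_sd = 0,
                           min_separation = 20) {
  stopifnot(frame_interval > 0, duration >= frame_interval,
            width >= 20, height >= 20, bit_depth >= 1,
            spore_radius >= 1, spore_amplitude > 0, noise_sd >= 0,
            min_separation >= 2 * spore_radius)
  structure(list(frame_interval = frame_interval, duration = duration,
                 width = as.integer(width), height = as.integer(height),
                 bit_depth = as.integer(bit_depth),
                 spore_radius = spore_radius,
                 background_level = background_level,
                 spore_amplitude = spore_amplitude, noise_sd = noise_sd,
                 min_separation = min_separation),
            class = "imaging_params")
}

#' Generate ground-truth kinetic parameters for a spore population
#'
#' Draws one record per spore: whether it germinates and, if so, its lag
#' time, release and lysis completion times, lag-phase leak slope and
#' normalized intensity at release completion.  Spore centers are placed by
#' dart throwing so that all pairwise distances are at least
#' `imaging$min_separation` and every 20 x 20 analysis window (plus the
#' disc) stays inside the frame.
#'
#' For germinating spores `t_lag <= t_release <= t_lys` holds by
#' construction, and the leak slope is capped so that less than the full
#' CaDPA store leaks during the lag (`leak_slope * t_lag < 1`).
#' Non-germinating spores carry `NA` kinetic times.
#'
#' @param params a [population_params()] object.
#' @param imaging an [imaging_params()] object supplying the frame geometry
#'   used for center placement.
#' @return a `data.frame` of class `spore_truth` with columns `spore_id`,
#'   `x`, `y`, `germinates`, `t_lag`, `t_release`, `t_lys`, `leak_slope`,
#'   `i_lag`, `i_release`.
#' @export
generate_truth <- function(params, imaging = imaging_params()) {
  stopifnot(inherits(params, "population_params"),
            inherits(imaging, "imaging_params"))
  n <- params$n_spores
  with_seed(params$seed, {
    germinates <- runif(n) < params$frac_germinating
    t_lag <- dt_rel <- dt_lys <- leak <- i_rel <- rep(NA_real_, n)
    ng <- sum(germinates)
    if (ng > 0) {
      t_lag[germinates] <- .draw_dist(params$t_lag_dist, ng)
      dt_rel[germinates] <- .draw_dist(params$dt_release_dist, ng)
      dt_lys[germinates] <- .draw_dist(params$dt_lys_dist, ng)
      leak[germinates] <- runif(ng, params$leak_slope_range[1],
                                params$leak_slope_range[2])
      # keep lag leakage strictly below the total CaDPA store
      leak[germinates] <- pmin(leak[germinates],
                               0.9 / pmax(t_lag[germinates], 1e-6))
      i_rel[germinates] <- runif(ng, params$i_release_range[1],
                                 params$i_release_range[2])
    }
    centers <- .place_centers(n, imaging)
    out <- data.frame(
      spore_id = sprintf("spore_%04d", seq_len(n)),
      x = centers$x, y = centers$y,
      germinates = germinates,
      t_lag = t_lag,
      t_release = t_lag + dt_rel,
      t_lys = t_lag + dt_rel + dt_lys,
      leak_slope = leak,
      i_lag = 1 - leak * t_lag,
      i_release = i_rel,
      stringsAsFactors = FALSE)
    class(out) <- c("spore_truth", "data.frame")
    out
  })
}

# dart-throwing placement with a hard minimum separation; margin keeps both
# the disc and the 20x20 half-open analysis window inside the frame
.place_centers <- function(n, imaging) {
  margin <- ceiling(imaging$spore_radius) + 10
  lo_x <- margin + 1; hi_x <- imaging$width - margin
  lo_y <- margin + 1; hi_y <- imaging$height - margin
  if (hi_x <= lo_x || hi_y <= lo_y)
    stop("frame too small for the analysis window margin")
  area_per <- pi * (imaging$min_separation / 2)^2
  usable <- (hi_x - lo_x) * (hi_y - lo_y)
  if (n * area_per > 0.6 * usable)
    stop("infeasible packing: ", n, " spores cannot be placed at ",
         "min_separation ", imaging$min_separation, " in a ",
         imaging$width, "x", imaging$height, " frame")
  x <- integer(n); y <- integer(n)
  placed <- 0L; attempts <- 0L; max_attempts <- 200L * n
  min_sep2 <- imaging$min_separation^2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("infeasible packing: could not place ", n, " spores at ",
           "min_separation ", imaging$min_separation)
    cx <- sample(lo_x:hi_x, 1L); cy <- sample(lo_y:hi_y, 1L)
    if (placed > 0L) {
      d2 <- (x[seq_len(placed)] - cx)^2 + (y[seq_len(placed)] - cy)^2
      if (min(d2) < min_sep2) next
    }
    placed <- placed + 1L
    x[placed] <- cx; y[placed] <- cy
  }
  list(x = x, y = y)
}

#' Evaluate the four-phase intensity model of one spore
#'
#' The normalized phase-contrast intensity of a germinating spore follows a
#' piecewise-linear schedule: a slow linear leak from 1 during the lag
#' phase, a steep linear drop from `i_lag` to `i_release` during rapid
#' CaDPA release, a linear decay from `i_release` to 0 during cortex lysis,
#' and 0 afterwards.  Non-germinating spores stay at 1.
#'
#' @param spore one row of a [generate_truth()] table (or any list with the
#'   same fields).
#' @param times numeric vector of times in minutes.
#' @return normalized intensities, same length as `times`.
#' @export
model_trace <- function(spore, times) {
  if (!isTRUE(spore$germinates[1])) return(rep(1, length(times)))
  t_lag <- spore$t_lag[1]; t_rel <- spore$t_release[1]
  t_lys <- spore$t_lys[1]
  leak <- spore$leak_slope[1]; i_rel <- spore$i_release[1]
  i_lag <- 1 - leak * t_lag
  v <- numeric(length(times))
  ph1 <- times < t_lag
  ph2 <- times >= t_lag & times < t_rel
  ph3 <- times >= t_rel & times < t_lys
  v[ph1] <- 1 - leak * times[ph1]
  v[ph2] <- i_lag + (i_rel - i_lag) * (times[ph2] - t_lag) / (t_rel - t_lag)
  v[ph3] <- i_rel * (1 - (times[ph3] - t_rel) / (t_lys - t_rel))
  v
}
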