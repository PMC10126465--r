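#' Render a synthetic phase-contrast time-lapse stack
#'
#' Draws each spore as a hard disc of radius `imaging$spore_radius` whose
#' amplitude above background follows the four-phase piecewise-linear
#' intensity model ([model_trace()]), adds i.i.d. Gaussian pixel noise and
#' clips to the camera range \[0, 2^bit_depth - 1\].  Frame `k` (0-indexed)
#' corresponds to `t = k * frame_interval` minutes.
#'
#' @param truth a [generate_truth()] table; all centers must lie inside the
#'   frame with margin `spore_radius + 10` and discs must not overlap.
#' @param imaging an [imaging_params()] object.
#' @param seed integer RNG seed for the pixel noise.
#' @return a list with `stack` (a `spore_image_stack`: 3-D array indexed
#'   `[y, x, frame]` plus `frame_interval` and `bit_depth`) and `roster`
#'   (the truth table with a logical `duration_short` column flagging
#'   spores whose `t_lys` exceeds the recording).
#' @export
render_stack <- function(truth, imaging = imaging_params(), seed = 1L) {
  stopifnot(inherits(truth, "data.frame"), nrow(truth) >= 1,
            inherits(imaging, "imaging_params"))
  r <- imaging$spore_radius
  margin <- ceiling(r) + 10
  if (any(truth$x <= margin) || any(truth$x > imaging$width - margin) ||
      any(truth$y <= margin) || any(truth$y > imaging$height - margin))
    stop("spore centers must lie inside the frame with margin ",
         "spore_radius + 10")
  if (nrow(truth) > 1) {
    d2 <- as.matrix(stats::dist(truth[, c("x", "y")]))^2
    diag(d2) <- Inf
    if (min(d2) < (2 * r)^2) stop("overlapping spore discs")
  }

  times <- seq(0, imaging$duration, by = imaging$frame_interval)
  n_frames <- length(times)
  frames <- array(imaging$background_level,
                  dim = c(imaging$height, imaging$width, n_frames))

  # disc pixel offsets (integer raster, hard edge)
  off <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]

  for (i in seq_len(nrow(truth))) {
    g <- model_trace(truth[i, ], times)
    px <- truth$x[i] + off$dx
    py <- truth$y[i] + off$dy
    for (k in seq_len(n_frames))
      frames[cbind(py, px, k)] <- imaging$background_level +
        imaging$spore_amplitude * g[k]
  }
  if (imaging$noise_sd > 0) {
    with_seed(seed, {
      frames <- frames + rnorm(length(frames), sd = imaging$noise_sd)
    })
  }
  top <- 2^imaging$bit_depth - 1
  frames[frames < 0] <- 0
  frames[frames > top] <- top

  roster <- truth
  roster$duration_short <- !is.na(roster$t_lys) &
    roster$t_lys > imaging$duration
  if (any(roster$duration_short))
    warning("recording shorter than the slowest spore's t_lys; ",
            sum(roster$duration_short), " spore(s) flagged in the roster")

  stack <- spore_image_stack(frames, imaging$frame_interval,
                             imaging$bit_depth)
  list(stack = stack, roster = roster)
}

#' Construct an image stack object
#'
#' @param frames 3-D numeric array indexed `[y, x, frame]` with at least
#'   two frames, values within the camera range.
#' @param frame_interval minutes between frames.
#' @param bit_depth camera bit depth.
#' @return an object of class `spore_image_stack`.
#' @export
spore_image_stack <- function(frames, frame_interval, bit_depth = 12) {
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            dim(frames)[3] >= 2, frame_interval > 0,
            min(frames) >= 0, max(frames) <= 2^bit_depth - 1)
  structure(list(frames = frames, frame_interval = frame_interval,
                 bit_depth = as.integer(bit_depth)),
            class = "spore_image_stack")
}

#' @export
print.spore_image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("spore_image_stack:", d[2], "x", d[1], "px,", d[3], "frames @",
      x$frame_interval, "min,", x$bit_depth, "bit\n")
  invisible(x)
}

#' Write / read a stack as multi-page TIFF
#'
#' The 12-bit range is stored in a 16-bit container; intensities are
#' written as `value / (2^bit_depth - 1)` and rescaled on read.
#'
#' @param stack a `spore_image_stack`.
#' @param path file path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns a `spore_image_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "spore_image_stack"))
  top <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(k) stack$frames[, , k] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param frame_interval,bit_depth metadata to attach on read (TIFF pages
#'   store pixels only).
#' @export
read_stack_tiff <- function(path, frame_interval = 0.25, bit_depth = 12) {
  pages <- tiff::readTIFF(path, all = TRUE)
  top <- 2^bit_depth - 1
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * top
  spore_image_stack(frames, frame_interval, bit_depth)
}

#' Simulate window-level intensity traces without rendering pixels
#'
#' Convenience generator for kinetics studies: evaluates the piecewise
#' intensity model of each spore on the frame grid and adds i.i.d.
#' Gaussian noise directly in normalized units, bypassing the renderer.
#' Raw values are reported on the camera scale
#' (`background + amplitude * model`).
#'
#' @param truth a [generate_truth()] table.
#' @param times frame times in minutes (uniform grid starting at 0).
#' @param noise_sd trace noise standard deviation in normalized units.
#' @param imaging an [imaging_params()] object supplying background and
#'   amplitude.
#' @param seed integer RNG seed.
#' @return a list of `intensity_trace` objects (see [extract_trace()]).
#' @export
simulate_traces <- function(truth, times, noise_sd = 0,
                            imaging = imaging_params(), seed = 1L) {
  stopifnot(nrow(truth) >= 1, length(times) >= 2)
  with_seed(seed, {
    lapply(seq_len(nrow(truth)), function(i) {
      g <- model_trace(truth[i, ], times)
      if (noise_sd > 0) g <- g + rnorm(length(g), sd = noise_sd)
      new_intensity_trace(truth$spore_id[i], times,
                          imaging$background_level +
                            imaging$spore_amplitude * g)
    })
  })
}
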