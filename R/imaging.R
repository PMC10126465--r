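#' Construct a single-spore intensity trace
#'
#' @param spore_id identifier.
#' @param times frame times in minutes.
#' @param raw mean window intensity per frame.
#' @param normalized optional endpoint-normalized values.
#' @param germination_candidate logical flag set by [normalize_trace()].
#' @return an object of class `intensity_trace`.
#' @export
new_intensity_trace <- function(spore_id, times, raw, normalized = NULL,
                                germination_candidate = NA) {
  stopifnot(length(times) == length(raw))
  structure(list(spore_id = spore_id, times = times, raw = raw,
                 normalized = normalized,
                 germination_candidate = germination_candidate),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat("intensity_trace", x$spore_id, "-", length(x$times), "frames,",
      if (isTRUE(x$germination_candidate)) "germination candidate"
      else if (isFALSE(x$germination_candidate)) "not a candidate"
      else "not yet normalized", "\n")
  invisible(x)
}

# separable Gaussian smoothing with edge replication
.gaussian_smooth <- function(img, sd) {
  if (sd <= 0) return(img)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-(-r:r)^2 / (2 * sd^2)); k <- k / sum(k)
  pad_rows <- function(m) rbind(m[rep(1, r), , drop = FALSE], m,
                                m[rep(nrow(m), r), , drop = FALSE])
  # stats::filter smooths each column of a matrix
  sm <- stats::filter(pad_rows(img), k, sides = 2)
  sm <- as.matrix(sm)[(r + 1):(r + nrow(img)), , drop = FALSE]
  sm <- stats::filter(pad_rows(t(sm)), k, sides = 2)
  t(as.matrix(sm)[(r + 1):(r + ncol(img)), , drop = FALSE])
}

#' Detect spores in a frame
#'
#' Locates bright spore candidates as local maxima of a Gaussian-smoothed
#' frame that exceed `median + threshold_k * MAD` of the smoothed image
#' (MAD scaled to be consistent with the standard deviation under
#' normality).  Peaks closer than `min_separation` are resolved by keeping
#' the brighter one; among equal-height peaks the lexicographically
#' smaller (y, x) is kept.  Candidates whose 20 x 20 analysis window would
#' cross the frame edge are discarded and counted in the
#' `n_edge_discarded` attribute.
#'
#' @param frame numeric matrix indexed `[y, x]` (a single stack frame).
#' @param smoothing_sd Gaussian smoothing sd in pixels.
#' @param threshold_k threshold in robust standard deviations above the
#'   background median; the default 6 keeps the expected number of
#'   spurious noise maxima well below one per megapixel frame, while true
#'   spore peaks sit far above it at any workable contrast.
#' @param min_separation minimum center-to-center distance in pixels.
#' @return a `data.frame` with columns `spore_id`, `x`, `y`, `peak_value`,
#'   ordered by decreasing peak value; may have zero rows.
#' @export
detect_spores <- function(frame, smoothing_sd = 2, threshold_k = 6,
                          min_separation = 20) {
  stopifnot(is.matrix(frame), nrow(frame) > 0, ncol(frame) > 0)
  sm <- .gaussian_smooth(frame, smoothing_sd)
  thr <- median(sm) + threshold_k * mad(sm)

  h <- nrow(sm); w <- ncol(sm)
  core <- sm[2:(h - 1), 2:(w - 1)]
  is_max <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max &
      core >= sm[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(.empty_rois())
  cand <- data.frame(y = idx[, 1] + 1L, x = idx[, 2] + 1L)
  cand$peak_value <- sm[cbind(cand$y, cand$x)]
  # brighter first; equal heights resolved toward smaller (y, x)
  cand <- cand[order(-cand$peak_value, cand$y, cand$x), ]

  keep <- logical(nrow(cand))
  kx <- numeric(0); ky <- numeric(0)
  min_sep2 <- min_separation^2
  for (i in seq_len(nrow(cand))) {
    if (length(kx) == 0 ||
        min((kx - cand$x[i])^2 + (ky - cand$y[i])^2) >= min_sep2) {
      keep[i] <- TRUE
      kx <- c(kx, cand$x[i]); ky <- c(ky, cand$y[i])
    }
  }
  cand <- cand[keep, ]

  inside <- cand$x - 10 >= 1 & cand$x + 9 <= w &
    cand$y - 10 >= 1 & cand$y + 9 <= h
  n_edge <- sum(!inside)
  cand <- cand[inside, , drop = FALSE]
  out <- data.frame(spore_id = sprintf("roi_%04d", seq_len(nrow(cand))),
                    x = cand$x, y = cand$y, peak_value = cand$peak_value,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_edge_discarded") <- n_edge
  out
}

.empty_rois <- function() {
  out <- data.frame(spore_id = character(0), x = integer(0), y = integer(0),
                    peak_value = numeric(0), stringsAsFactors = FALSE)
  attr(out, "n_edge_discarded") <- 0L
  out
}

#' Extract the mean-intensity trace of one spore
#'
#' Averages the 400 pixels of the half-open 20 x 20 window
#' `[x-10, x+10) x [y-10, y+10)` around the spore center in every frame.
#'
#' @param stack a `spore_image_stack`.
#' @param x,y integer center coordinates (1-based pixels).
#' @param spore_id identifier carried on the trace.
#' @return an `intensity_trace` with `times[k] = (k-1) * frame_interval`
#'   and raw values only.
#' @export
extract_trace <- function(stack, x, y, spore_id = "spore") {
  stopifnot(inherits(stack, "spore_image_stack"))
  d <- dim(stack$frames)
  xs <- (x - 10):(x + 9); ys <- (y - 10):(y + 9)
  if (min(xs) < 1 || max(xs) > d[2] || min(ys) < 1 || max(ys) > d[1])
    stop("analysis window out of bounds for center (", x, ", ", y, ")")
  raw <- apply(stack$frames[ys, xs, , drop = FALSE], 3, mean)
  times <- (seq_len(d[3]) - 1) * stack$frame_interval
  new_intensity_trace(spore_id, times, raw)
}

#' Extract traces for a table of ROIs
#'
#' @param stack a `spore_image_stack`.
#' @param rois a `data.frame` with `spore_id`, `x`, `y` (e.g. from
#'   [detect_spores()] or a renderer roster).
#' @return a list of `intensity_trace` objects.
#' @export
extract_traces <- function(stack, rois) {
  lapply(seq_len(nrow(rois)), function(i)
    extract_trace(stack, rois$x[i], rois$y[i], rois$spore_id[i]))
}

#' Endpoint-normalize an intensity trace
#'
#' Rescales the raw trace so that the first frame maps to 1 and the mean
#' of the last `tail_frames` frames maps to 0.  A trace qualifies as a
#' germination candidate only if its fractional intensity drop
#' `(I0 - Iend) / I0` reaches `drop_fraction_threshold`; flat or weakly
#' decaying traces (non-germinators) are flagged and left unnormalized,
#' since forcing the endpoint of a flat trace to zero would fabricate a
#' release event.
#'
#' @param trace an `intensity_trace` with raw values.
#' @param drop_fraction_threshold minimum fractional drop (default 0.4).
#' @param tail_frames number of final frames averaged for the endpoint
#'   (default 4).
#' @return the trace with `normalized` and `germination_candidate` filled
#'   in (`normalized` stays `NULL` for non-candidates).
#' @export
normalize_trace <- function(trace, drop_fraction_threshold = 0.4,
                            tail_frames = 4) {
  stopifnot(inherits(trace, "intensity_trace"),
            tail_frames >= 1, tail_frames <= length(trace$raw))
  i0 <- trace$raw[1]
  iend <- mean(tail(trace$raw, tail_frames))
  if (i0 == iend) {
    trace$germination_candidate <- FALSE
    trace$normalized <- NULL
    return(trace)
  }
  drop <- (i0 - iend) / i0
  if (drop >= drop_fraction_threshold) {
    trace$germination_candidate <- TRUE
    trace$normalized <- (trace$raw - iend) / (i0 - iend)
  } else {
    trace$germination_candidate <- FALSE
    trace$normalized <- NULL
  }
  trace
}

#' Convert traces to/from a long-format table
#'
#' The long format has one row per (spore, frame) with columns `spore_id`,
#' `frame` (0-based), `time_min`, `raw` and `normalized` (`NA` where
#' undefined), suitable for CSV round trips.
#'
#' @param traces a list of `intensity_trace` objects.
#' @return `traces_to_df` returns a `data.frame`; `df_to_traces` returns a
#'   list of `intensity_trace` objects.
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(spore_id = tr$spore_id,
               frame = seq_along(tr$times) - 1L,
               time_min = tr$times,
               raw = tr$raw,
               normalized = if (is.null(tr$normalized)) NA_real_
                            else tr$normalized,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname traces_to_df
#' @param df a long-format trace table.
#' @export
df_to_traces <- function(df) {
  lapply(split(df, df$spore_id), function(d) {
    d <- d[order(d$frame), ]
    norm <- if (all(is.na(d$normalized))) NULL else d$normalized
    new_intensity_trace(d$spore_id[1], d$time_min, d$raw, norm,
                        germination_candidate = !is.null(norm))
  })
}
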