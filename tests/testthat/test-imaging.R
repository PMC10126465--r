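test_that("a blank noisy frame yields no detections", {
  set.seed(21)
  frame <- matrix(100 + rnorm(200 * 200, sd = 10), 200, 200)
  rois <- detect_spores(frame, threshold_k = 5)
  expect_equal(nrow(rois), 0)
})

test_that("detection recovers rendered spore centers within 1 px", {
  im <- imaging_params(width = 300, height = 300, duration = 0.5,
                       noise_sd = 50)
  truth <- generate_truth(population_params(n_spores = 3,
                                            frac_germinating = 0,
                                            seed = 31), im)
  rs <- render_stack(truth, im, seed = 32)
  rois <- detect_spores(rs$stack$frames[, , 1])
  expect_equal(nrow(rois), 3)
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((rois$x - truth$x[i])^2 + (rois$y - truth$y[i])^2)
    expect_lte(min(d), 1)
  }
})

test_that("peaks closer than min_separation collapse to the brighter one", {
  frame <- matrix(0, 120, 120)
  frame[60, 50] <- 100     # brighter
  frame[60, 60] <- 80      # 10 px away
  rois <- detect_spores(frame, smoothing_sd = 1, threshold_k = 5,
                        min_separation = 20)
  expect_equal(nrow(rois), 1)
  expect_equal(rois$x, 50)
  expect_equal(rois$y, 60)
})

test_that("equal-height peak ties keep the lexicographically smaller (y, x)", {
  frame <- matrix(0, 120, 120)
  frame[60, 50] <- 100
  frame[60, 58] <- 100
  rois <- detect_spores(frame, smoothing_sd = 1, threshold_k = 5,
                        min_separation = 20)
  expect_equal(nrow(rois), 1)
  expect_equal(rois$x, 50)
})

test_that("edge-crossing windows are discarded and counted", {
  frame <- matrix(0, 100, 100)
  frame[50, 5] <- 100      # window would cross the left edge
  frame[50, 50] <- 100
  rois <- detect_spores(frame, smoothing_sd = 1, threshold_k = 5)
  expect_equal(nrow(rois), 1)
  expect_equal(attr(rois, "n_edge_discarded"), 1)
})

test_that("extract_trace averages the 20x20 window", {
  frames <- array(7, dim = c(40, 40, 2))
  frames[, , 2] <- 3
  st <- spore_image_stack(frames, frame_interval = 0.25)
  tr <- extract_trace(st, 20, 20)
  expect_equal(tr$raw, c(7, 3))
  expect_equal(tr$times, c(0, 0.25))

  half <- array(0, dim = c(40, 40, 2))
  half[1:19, , ] <- 10          # window rows [10, 30) are half 10s, half 0s
  st2 <- spore_image_stack(half, frame_interval = 1, bit_depth = 12)
  tr2 <- extract_trace(st2, 20, 20)
  expect_equal(tr2$raw[1], 5)

  expect_error(extract_trace(st, 5, 20), "out of bounds")
})

test_that("noise-free rendered window trace matches the analytic model", {
  im <- imaging_params(width = 120, height = 120, duration = 25,
                       noise_sd = 0)
  truth <- data.frame(spore_id = "s1", x = 60, y = 60, germinates = TRUE,
                      t_lag = 8, t_release = 12, t_lys = 20,
                      leak_slope = 0.002, i_lag = 1 - 0.002 * 8,
                      i_release = 0.5)
  rs <- render_stack(truth, im)
  tr <- extract_trace(rs$stack, 60, 60)
  n_disc <- sum(outer((-4:4)^2, (-4:4)^2, "+") <= 16)   # disc pixels
  mod <- im$background_level +
    im$spore_amplitude * model_trace(truth, tr$times) * n_disc / 400
  expect_equal(tr$raw, mod, tolerance = 1e-12)
})

test_that("normalization maps endpoints to 1 and 0 and applies the drop rule", {
  tr <- new_intensity_trace("a", 0:4, c(10, 8, 6, 4, 2))
  out <- normalize_trace(tr, tail_frames = 1)
  expect_true(out$germination_candidate)
  expect_equal(out$normalized, c(1, 0.75, 0.5, 0.25, 0))

  flat <- normalize_trace(new_intensity_trace("b", 0:3, rep(5, 4)))
  expect_false(flat$germination_candidate)
  expect_null(flat$normalized)

  weak <- normalize_trace(new_intensity_trace("c", 0:9,
                                              seq(100, 90, length.out = 10)))
  expect_false(weak$germination_candidate)
})

test_that("normalization invariants hold and are affine-invariant", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(12:80, 1)
    raw <- 100 + 900 * c(1, sort(runif(n - 2), decreasing = TRUE), 0) +
      rnorm(n, sd = 5)
    tr <- normalize_trace(new_intensity_trace("p", (0:(n - 1)) * 0.25, raw))
    if (!isTRUE(tr$germination_candidate)) next
    expect_identical(tr$normalized[1], 1)
    expect_equal(mean(tail(tr$normalized, 4)), 0, tolerance = 1e-12)
    # gain/offset changes leave the normalized trace unchanged
    gain <- runif(1, 0.1, 7); offset <- runif(1, -20, 50)
    tr2 <- normalize_trace(new_intensity_trace("p", tr$times,
                                               gain * raw + offset))
    expect_equal(tr2$normalized, tr$normalized, tolerance = 1e-9)
  }
})

test_that("trace tables round-trip through the long format", {
  tr <- list(
    normalize_trace(new_intensity_trace("a", 0:9, seq(100, 10, by = -10))),
    new_intensity_trace("b", 0:9, rep(50, 10)))
  df <- traces_to_df(tr)
  expect_equal(nrow(df), 20)
  back <- df_to_traces(df)
  expect_equal(back[["a"]]$raw, tr[[1]]$raw)
  expect_equal(back[["a"]]$normalized, tr[[1]]$normalized)
  expect_null(back[["b"]]$normalized)
})
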