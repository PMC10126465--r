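test_that("noise-free grid-aligned traces are recovered exactly", {
  tr <- make_trace(b1 = 40, b2 = 60, b3 = 120, n = 140)
  k <- fit_kinetics(tr)
  expect_true(k$germinated)
  expect_equal(k$t_lag, 10)        # 40 * 0.25
  expect_equal(k$t_release, 15)
  expect_equal(k$t_lys, 30)
  expect_equal(k$delta_t_release, 5)
  expect_equal(k$delta_t_lys, 15)
  expect_equal(k$i_lag, 0.95, tolerance = 1e-6)
  expect_equal(k$i_release, 0.5, tolerance = 1e-6)
  expect_lt(k$fit_sse, 1e-12)
})

test_that("rendered off-grid truth is recovered within one frame interval", {
  im <- imaging_params(width = 200, height = 200, duration = 30,
                       noise_sd = 0)
  truth <- generate_truth(population_params(n_spores = 6,
                                            frac_germinating = 1, seed = 2,
                                            t_lag_dist = list(
                                              family = "lognormal",
                                              meanlog = log(8),
                                              sdlog = 0.2)), im)
  rs <- render_stack(truth, im)
  traces <- extract_traces(rs$stack, rs$roster)
  for (i in seq_along(traces)) {
    k <- fit_kinetics(normalize_trace(traces[[i]]))
    expect_true(k$germinated)
    expect_lte(abs(k$t_lag - truth$t_lag[i]), 0.25)
    expect_lte(abs(k$t_release - truth$t_release[i]), 0.25)
    expect_lte(abs(k$t_lys - truth$t_lys[i]), 0.25)
    expect_gte(k$i_lag, k$i_release)
  }
})

test_that("flat and non-candidate traces are not called germinated", {
  flat <- new_intensity_trace("f", (0:19) * 0.25, rep(1, 20),
                              normalized = rep(1, 20),
                              germination_candidate = TRUE)
  expect_false(fit_kinetics(flat)$germinated)

  noncand <- new_intensity_trace("n", (0:19) * 0.25, rep(5, 20),
                                 normalized = NULL,
                                 germination_candidate = FALSE)
  k <- fit_kinetics(noncand)
  expect_false(k$germinated)
  expect_true(is.na(k$t_lag))

  short <- new_intensity_trace("s", 0:5, 6:1)
  expect_error(fit_kinetics(short), "shorter than 8")
})

test_that("inner QP solution matches direct model evaluation and is optimal", {
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(15:50, 1)
    t <- (0:(n - 1)) * 0.25
    y <- rnorm(n, 0.5, 0.3)
    b <- sort(sample(1:(n - 1), 3))
    fit <- pwl_sse(y, t, b[1], b[2], b[3])
    # prefix-sum SSE agrees with brute-force model evaluation
    direct <- direct_pwl_sse(y, t, b[1], b[2], b[3], fit$i_lag,
                             fit$i_release)
    expect_equal(fit$sse, direct, tolerance = 1e-8)
    # no random feasible parameter pair beats the QP solution
    T1 <- t[b[1] + 1]; d2 <- t[b[2] + 1] - T1
    for (j in 1:25) {
      il <- runif(1, -0.5, 1); ir <- runif(1, 0, 1)
      if (!pwl_feasible(il, ir, T1, d2)) next
      expect_gte(direct_pwl_sse(y, t, b[1], b[2], b[3], il, ir),
                 fit$sse - 1e-8)
    }
  }
})

test_that("the fitter equals exhaustive enumeration on short traces", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(12:40, 1)
    b <- sort(sample(1:(n - 1), 3))
    tr <- make_trace(b[1], b[2], b[3], n, noise_sd = 0.05)
    k <- fit_kinetics(tr)
    # independent enumeration in R over all ordered triples
    best <- Inf; arg <- NULL
    for (b1 in 1:(n - 3)) for (b2 in (b1 + 1):(n - 2))
      for (b3 in (b2 + 1):(n - 1)) {
        s <- pwl_sse(tr$normalized, tr$times, b1, b2, b3)$sse
        if (s < best) { best <- s; arg <- c(b1, b2, b3) }
      }
    if (k$germinated) {
      expect_equal(k$fit_sse, best, tolerance = 1e-10)
      expect_equal(c(k$t_lag, k$t_release, k$t_lys) / 0.25, arg)
    }
  }
})

test_that("coarse search matches the oracle on long clean traces", {
  set.seed(12)
  for (rep in 1:10) {
    n <- 150
    b <- sort(sample(c(10:60, 80:140), 3))
    while (b[2] - b[1] < 3 || b[3] - b[2] < 3) b <- sort(sample(5:145, 3))
    tr <- make_trace(b[1], b[2], b[3], n, noise_sd = 0.01)
    k_coarse <- fit_kinetics(tr)            # coarse + refine path (n > 60)
    k_oracle <- fit_kinetics(tr, oracle = TRUE)
    expect_equal(k_coarse$fit_sse, k_oracle$fit_sse, tolerance = 1e-6)
  }
})

test_that("SSE ties break toward the lexicographically smallest triple", {
  # a perfectly linear decay: many triples fit exactly; the first wins
  n <- 20
  t <- (0:(n - 1)) * 0.25
  y <- seq(1, 0, length.out = n)
  res <- sporekinetics:::.pwl_search(y, t, 1:(n - 1), 3)
  enum <- list(sse = Inf)
  for (b1 in 1:(n - 3)) for (b2 in (b1 + 1):(n - 2))
    for (b3 in (b2 + 1):(n - 1)) {
      s <- pwl_sse(y, t, b1, b2, b3)$sse
      if (s < enum$sse - 1e-12) enum <- list(sse = s, b = c(b1, b2, b3))
    }
  expect_equal(c(res$b1, res$b2, res$b3), enum$b)
})

test_that("population summaries aggregate germinated spores only", {
  kin <- data.frame(
    spore_id = c("a", "b", "c", "d"),
    germinated = c(TRUE, TRUE, FALSE, FALSE),
    t_lag = c(10, 20, NA, NA), t_release = c(12, 24, NA, NA),
    t_lys = c(20, 30, NA, NA), delta_t_release = c(2, 4, NA, NA),
    delta_t_lys = c(8, 6, NA, NA), i_lag = c(0.95, 0.9, NA, NA),
    i_release = c(0.5, 0.4, NA, NA), fit_sse = c(0, 0, NA, NA))
  s <- summarize_population(kin, times = seq(0, 30, 0.5))
  expect_equal(s$germinated_fraction, 0.5)
  expect_equal(s$stats$mean[s$stats$parameter == "t_lag"], 15)
  expect_equal(s$stats$sd[s$stats$parameter == "t_lag"], 7.071, tolerance = 1e-3)
  expect_true(all(diff(s$cumulative$fraction_germinated) >= 0))
  expect_equal(tail(s$cumulative$fraction_germinated, 1), 0.5)

  none <- summarize_population(kin[3:4, ], times = 0:5)
  expect_equal(none$germinated_fraction, 0)
  expect_true(all(is.na(none$stats$mean)))
})

test_that("median breakpoint shift under mild noise stays within 2 frames", {
  set.seed(33)
  shifts <- c()
  for (rep in 1:30) {
    b <- c(sample(20:40, 1), 0, 0)
    b[2] <- b[1] + sample(5:12, 1)
    b[3] <- b[2] + sample(10:30, 1)
    clean <- make_trace(b[1], b[2], b[3], n = 100)
    noisy <- clean
    noisy$normalized <- clean$normalized + rnorm(100, sd = 0.02)
    k0 <- fit_kinetics(clean)
    k1 <- fit_kinetics(noisy)
    shifts <- c(shifts, abs(c(k1$t_lag - k0$t_lag,
                              k1$t_release - k0$t_release,
                              k1$t_lys - k0$t_lys)) / 0.25)
  }
  expect_lte(median(shifts), 2)
})
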