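# Independent oracles used across the suite.  These deliberately avoid the
# package's prefix-sum / DP code paths: the piecewise model is evaluated
# directly and alignment scores come from recursive enumeration.

# direct SSE of the four-phase model at explicit (i_lag, i_release)
direct_pwl_sse <- function(y, t, b1, b2, b3, i_lag, i_release) {
  tau <- t - t[1]
  T1 <- tau[b1 + 1]; T2 <- tau[b2 + 1]; T3 <- tau[b3 + 1]
  f <- numeric(length(tau))
  for (k in seq_along(tau)) {
    tt <- tau[k]
    f[k] <- if (tt <= T1) 1 + (i_lag - 1) * tt / T1
    else if (tt <= T2) i_lag + (i_release - i_lag) * (tt - T1) / (T2 - T1)
    else if (tt <= T3) i_release * (1 - (tt - T2) / (T3 - T2))
    else 0
  }
  sum((y - f)^2)
}

pwl_feasible <- function(i_lag, i_release, T1, d2, rho = 3) {
  i_lag <= 1 + 1e-9 && i_release >= -1e-9 &&
    T1 * i_release - (T1 + rho * d2) * i_lag + rho * d2 <= 1e-9
}

# exhaustive recursive enumeration of all global alignments, linear gap
# cost `gap` per gap residue; exponential, for tiny sequences only
enum_align_score <- function(a, b, sub, gap) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1, j + 1))
    if (i <= n) best <- max(best, -gap + rec(i + 1, j))
    if (j <= m) best <- max(best, -gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# memoized variant of the same recursion (handles all pairs up to length 6)
memo_align_score <- function(a, b, sub, gap) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- matrix(NA_real_, n + 1, m + 1)
  memo[n + 1, m + 1] <- 0
  for (i in (n + 1):1) for (j in (m + 1):1) {
    if (i == n + 1 && j == m + 1) next
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[ca[i], cb[j]] + memo[i + 1, j + 1])
    if (i <= n) best <- max(best, -gap + memo[i + 1, j])
    if (j <= m) best <- max(best, -gap + memo[i, j + 1])
    memo[i, j] <- best
  }
  memo[1, 1]
}

# all sequences of length 1..max_len over the given alphabet
all_seqs <- function(alphabet, max_len) {
  out <- character(0)
  for (L in seq_len(max_len)) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(g, 1, paste, collapse = ""))
  }
  out
}

# a clean synthetic normalized trace with known breakpoints on the grid
make_trace <- function(b1, b2, b3, n, i_lag = 0.95, i_release = 0.5,
                       dt = 0.25, noise_sd = 0, id = "t") {
  t <- (0:(n - 1)) * dt
  tau <- t
  T1 <- tau[b1 + 1]; T2 <- tau[b2 + 1]; T3 <- tau[b3 + 1]
  f <- ifelse(tau <= T1, 1 + (i_lag - 1) * tau / T1,
        ifelse(tau <= T2, i_lag + (i_release - i_lag) * (tau - T1) / (T2 - T1),
        ifelse(tau <= T3, i_release * (1 - (tau - T2) / (T3 - T2)), 0)))
  y <- f + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
  new_intensity_trace(id, t, y, normalized = y, germination_candidate = TRUE)
}
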