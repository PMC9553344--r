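# Independent brute-force oracles: literal transcriptions with explicit
# loops, kept free of any code shared with the package implementation.

# Fuzzy entropy: embed, Chebyshev distances, graded memberships, averages
# excluding self, log-ratio. N - m windows for both window lengths.
fe_oracle <- function(x, m = 2L, r = 0.25, n_exp = 2, relative = TRUE) {
  n <- length(x)
  sdev <- sqrt(mean((x - mean(x))^2))
  if (sdev == 0) return(0)
  reff <- if (relative) r * sdev else r
  phi <- function(w) {
    N <- n - m
    total <- 0
    for (i in seq_len(N)) {
      s <- 0
      for (j in seq_len(N)) {
        if (j == i) next
        d <- max(abs(x[i:(i + w - 1)] - x[j:(j + w - 1)]))
        s <- s + exp(-(d / reff)^n_exp)
      }
      total <- total + s / (N - 1)
    }
    total / N
  }
  log(phi(m)) - log(phi(m + 1L))
}

# Two-class ReliefF update, enumerated instance by instance. Shares only
# the sampling contract (seeded uniform draw without replacement) with the
# implementation; scaling, neighbour search, and the weight update are
# re-derived with plain loops.
relieff_oracle <- function(X, y, m_iter, k_nn, seed) {
  n <- nrow(X); p <- ncol(X)
  Xs <- X
  for (cc in seq_len(p)) {
    rng <- max(X[, cc]) - min(X[, cc])
    Xs[, cc] <- if (rng > 0) (X[, cc] - min(X[, cc])) / rng else 0
  }
  m_used <- min(m_iter, n)
  idx <- withr::with_seed(seed, sample.int(n, m_used))
  w <- numeric(p)
  for (i in idx) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- sqrt(sum((Xs[i, ] - Xs[j, ])^2))
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    hits <- same[order(d[same])[seq_len(k_nn)]]
    misses <- other[order(d[other])[seq_len(k_nn)]]
    for (cc in seq_len(p)) {
      w[cc] <- w[cc] - mean(abs(Xs[i, cc] - Xs[hits, cc])) / m_used +
        mean(abs(Xs[i, cc] - Xs[misses, cc])) / m_used
    }
  }
  w
}

# Fraction of a spectrum's energy inside [lo, hi) Hz, by FFT.
fft_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(p[f >= lo & f < hi]) / sum(p)
}
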