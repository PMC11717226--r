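# Independent oracles used across the suite.  Each recomputes a quantity by
# the most literal route available (per-sample loops, dense materialization,
# transform-domain algebra) so the fast implementation paths are checked
# against something that shares no code with them.

# Sample-by-sample recursion applying the AR and MA sums term by term.
naive_simulate <- function(filters, x, e) {
  n_time <- nrow(e); d_y <- filters$d_y
  y <- matrix(0, n_time, d_y)
  for (t in seq_len(n_time)) {
    acc <- e[t, ]
    if (filters$n_a > 0) for (l in seq_len(filters$n_a)) if (t - l >= 1)
      for (k in seq_len(d_y))
        acc[k] <- acc[k] + sum(filters$A[l, k, ] * y[t - l, ])
    if (filters$n_b > 0) for (l in 0:(filters$n_b - 1)) if (t - l >= 1)
      for (k in seq_len(d_y))
        acc[k] <- acc[k] + sum(filters$B[l + 1, k, ] * x[t - l, ])
    y[t, ] <- acc
  }
  y
}

# Dense lagged design with an explicit per-sample validity loop (the
# window rule spelled out sample by sample).
oracle_design <- function(Y, X, n_a, n_b, segment_starts = 1L) {
  n_time <- nrow(Y); d_y <- ncol(Y)
  d_x <- if (is.null(X)) 0L else ncol(X)
  seg <- rep(seq_along(segment_starts),
             diff(c(segment_starts, n_time + 1L)))
  N <- d_y * n_a + d_x * n_b
  Phi <- matrix(NA_real_, n_time, N)
  valid <- logical(n_time)
  for (t in seq_len(n_time)) {
    row <- numeric(0)
    if (n_a > 0) for (j in seq_len(d_y)) for (l in seq_len(n_a))
      row <- c(row, if (t - l >= 1 && seg[t - l] == seg[t]) Y[t - l, j]
               else NA_real_)
    if (n_b > 0) for (j in seq_len(d_x)) for (l in 0:(n_b - 1))
      row <- c(row, if (t - l >= 1 && seg[t - l] == seg[t]) X[t - l, j]
               else NA_real_)
    Phi[t, ] <- row
    valid[t] <- all(is.finite(Y[t, ])) && all(is.finite(row))
  }
  list(Phi = Phi, valid = valid)
}

# Transform-domain impulse response: evaluate (I - A(z))^-1 B(z) on a DFT
# grid and invert; independent of the time-domain recursion.
freq_impulse <- function(filters, horizon, M = 4096) {
  d_y <- filters$d_y; d_x <- filters$d_x
  Hf <- array(0i, c(M, d_y, d_x))
  for (m in seq_len(M)) {
    z <- exp(-2i * pi * (m - 1) / M)
    Aw <- matrix(0i, d_y, d_y)
    if (filters$n_a > 0) for (l in seq_len(filters$n_a))
      Aw <- Aw + matrix(filters$A[l, , ], d_y, d_y) * z^l
    Bw <- matrix(0i, d_y, d_x)
    if (filters$n_b > 0) for (l in seq_len(filters$n_b))
      Bw <- Bw + matrix(filters$B[l, , ], d_y, d_x) * z^(l - 1)
    Hf[m, , ] <- solve(diag(d_y) - Aw, Bw)
  }
  H <- array(0, c(horizon, d_y, d_x))
  for (k in seq_len(d_y)) for (j in seq_len(d_x))
    H[, k, j] <- Re(stats::fft(Hf[, k, j], inverse = TRUE))[seq_len(horizon)] / M
  H
}

# Gaussian log-likelihood of residuals at the variance MLE.
gauss_loglik <- function(resid) {
  n <- length(resid)
  s2 <- mean(resid^2)
  -n / 2 * (log(2 * pi * s2) + 1)
}

# Random stable filter set for property loops.
random_stable_filters <- function(d_y, d_x, n_a, n_b, sd_a = 0.2) {
  repeat {
    A <- if (n_a > 0) array(stats::rnorm(n_a * d_y * d_y, sd = sd_a),
                            c(n_a, d_y, d_y)) else NULL
    B <- if (n_b > 0) array(stats::rnorm(n_b * d_y * d_x),
                            c(n_b, d_y, d_x)) else NULL
    f <- varx_filters(A = A, B = B, d_y = d_y,
                      d_x = if (is.null(B)) 0L else d_x)
    if (f$n_a == 0 || spectral_radius(f) < 0.9) return(f)
  }
}
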