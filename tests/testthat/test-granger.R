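test_that("deviance equals twice the Gaussian log-likelihood ratio", {
  expect_equal(deviance_stat(c(2, 3), c(2, 3), 50), c(0, 0))
  expect_equal(deviance_stat(exp(1) * 4, 4, 100), 100)
  expect_error(deviance_stat(c(1, 0), c(1, 1), 10), "positive")

  # toy regression: D from variances vs 2 * (llf - llr) from the
  # log-likelihoods evaluated directly
  set.seed(31)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.5 * x1 + 0.3 * x2 + rnorm(n)
  rf <- residuals(lm(y ~ 0 + x1 + x2))
  rr <- residuals(lm(y ~ 0 + x1))
  D <- deviance_stat(mean(rr^2), mean(rf^2), n)
  expect_equal(D, 2 * (gauss_loglik(rf) - gauss_loglik(rr)),
               tolerance = 1e-10)
})

test_that("chi-square p-values behave as the CDF complement", {
  expect_equal(chi2_pvalue(0, 2), 1)
  expect_equal(chi2_pvalue(5.991, 2), 0.05, tolerance = 1e-3)
  D <- c(1, 2, 5, 10)
  expect_true(all(diff(chi2_pvalue(D, 3)) < 0))
  expect_error(chi2_pvalue(c(1, 2), 0), "positive")
  expect_error(chi2_pvalue(-1, 2), "nonnegative")
})

test_that("generalized R-squared maps deviance to [0, 1)", {
  expect_equal(effect_size(0, 100), 0)
  expect_equal(effect_size(100 * log(2), 100), 0.5)
  expect_gt(effect_size(1e6, 100), 1 - 1e-10)
})

test_that("bias correction is zero at OLS, nonnegative, and matches its quadratic-form definition", {
  set.seed(32)
  T <- 150
  f <- random_stable_filters(2, 1, 2, 2)
  x <- matrix(rnorm(T), T, 1)
  y <- simulate_varx(f, x = x, innovations = matrix(rnorm(2 * T), T, 2))
  ne <- build_normal_equations(multi_series(y, x), n_a = 2, n_b = 2)

  # gamma = 0: R_xe = 0 up to rounding, so b = 0 (exactly, after the solve)
  rs0 <- residual_stats(ne, ridge_solve(ne, 0))
  b0 <- bias_correction(rs0$R_xe, ne$R_xx, rs0$R_ee_diag)
  expect_lt(max(b0), 1e-12)

  # ridge fit (N = 6, d_y = 2): matches a direct dense evaluation with an
  # explicit matrix inverse
  rs <- residual_stats(ne, ridge_solve(ne, 0.5))
  b <- bias_correction(rs$R_xe, ne$R_xx, rs$R_ee_diag)
  expect_true(all(b >= 0))
  b_dense <- 0.5 * diag(t(rs$R_xe) %*% solve(ne$R_xx) %*% rs$R_xe) /
    rs$R_ee_diag
  expect_equal(b, b_dense, tolerance = 1e-10)
})

test_that("de-biased deviance reduces to the plain one when bias terms cancel", {
  s_r <- c(1.2, 1.5); s_f <- c(1.0, 1.1)
  expect_equal(debiased_deviance(s_r, s_f, c(0, 0), c(0, 0), 80),
               deviance_stat(s_r, s_f, 80))
  expect_equal(debiased_deviance(s_r, s_f, c(3, 4), c(3, 4), 80),
               deviance_stat(s_r, s_f, 80))
  # clamped at zero when the correction overshoots
  expect_equal(debiased_deviance(1.0001, 1, 10, 0, 100), 0)
})

test_that("reduced-model submatrix solve equals a refit from scratch", {
  set.seed(33)
  T <- 300
  f <- random_stable_filters(3, 1, 2, 2)
  x <- matrix(rnorm(T), T, 1)
  y <- simulate_varx(f, x = x, innovations = matrix(rnorm(3 * T), T, 3))
  fit <- varx(y, x, n_a = 2, n_b = 2, demean = FALSE)
  orc <- oracle_design(y, x, 2, 2)
  Phi <- orc$Phi[orc$valid, , drop = FALSE]
  Yv <- y[orc$valid, , drop = FALSE]
  for (blk in fit$ne$index_map) {
    keep <- setdiff(seq_len(fit$N), blk$cols)
    E <- Yv - Phi[, keep] %*% qr.solve(Phi[, keep, drop = FALSE], Yv)
    s2_refit <- colSums(E^2) / nrow(Yv)
    D_refit <- pmax(fit$T_used * log(s2_refit / fit$sigma2), 0)
    got <- if (blk$kind == "endogenous")
      fit$A_deviance[, blk$name] else fit$B_deviance[, blk$name]
    expect_equal(unname(got), unname(D_refit), tolerance = 1e-7)
  }
})

test_that("nested-model property holds at gamma = 0", {
  set.seed(34)
  for (i in 1:5) {
    T <- 150
    f <- random_stable_filters(2, 1, 2, 1)
    x <- matrix(rnorm(T), T, 1)
    y <- simulate_varx(f, x = x, innovations = matrix(rnorm(2 * T), T, 2))
    fit <- varx(y, x, n_a = 2, n_b = 1)
    expect_true(all(fit$A_deviance >= 0))
    expect_true(all(fit$B_deviance >= 0))
    expect_true(all(fit$A_pval >= 0 & fit$A_pval <= 1))
    expect_true(all(fit$A_R2 >= 0 & fit$A_R2 < 1))
  }
})

test_that("null-channel p-values are uniform (KS distance < 0.05)", {
  set.seed(35)
  reps <- 1000
  p_null <- numeric(reps)
  for (r in seq_len(reps)) {
    # two independent white-noise channels: every cross test is null
    y <- matrix(rnorm(2 * 500), 500, 2)
    fit <- varx(y, n_a = 2, n_b = 0)
    p_null[r] <- fit$A_pval[1, 2]
  }
  ks <- max(abs(sort(p_null) - (seq_len(reps) - 0.5) / reps))
  expect_lt(ks, 0.05)
  rej <- mean(p_null < 0.05)
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("deviance grows linearly with sample size for a true effect", {
  set.seed(36)
  A <- array(0, c(1, 2, 2)); A[1, 1, 1] <- 0.3; A[1, 2, 2] <- 0.3
  A[1, 2, 1] <- 0.2
  f <- varx_filters(A = A)
  D_at <- function(T) {
    D <- replicate(8, {
      y <- simulate_varx(f, innovations = matrix(rnorm(2 * T), T, 2))
      varx(y, n_a = 1, n_b = 0)$A_deviance[2, 1]
    })
    mean(D)
  }
  r <- D_at(8000) / D_at(4000)
  expect_gt(r, 1.6); expect_lt(r, 2.4)
})

test_that("per-test failures degrade to NA with a warning, not a crash", {
  set.seed(37)
  y <- matrix(rnorm(300), 100, 3)
  y[, 2] <- 1                                # zero-variance channel
  expect_warning(fit <- varx(y, n_a = 1, n_b = 0), "zero variance")
  # the constant channel is excluded both as a source and (degenerate
  # target variance) as a target; the healthy 2x2 sub-block is intact
  expect_true(all(is.na(fit$A_pval[, 2])))
  expect_true(all(is.na(fit$A_pval[2, ])))
  expect_false(anyNA(fit$A_pval[c(1, 3), c(1, 3)]))
})

test_that("granger_edges flattens, thresholds and adjusts", {
  set.seed(38)
  f <- random_stable_filters(2, 1, 1, 1)
  x <- matrix(rnorm(400), 400, 1)
  y <- simulate_varx(f, x = x, innovations = matrix(rnorm(800), 400, 2))
  fit <- varx(y, x, n_a = 1, n_b = 1)
  ed <- granger_edges(fit)
  expect_equal(nrow(ed), 4 + 2)              # 2x2 endogenous + 2 exogenous
  expect_setequal(unique(ed$kind), c("A", "B"))
  expect_equal(ed$R, sqrt(ed$R2))
  ed_bh <- granger_edges(fit, adjust = "BH")
  expect_true(all(ed_bh$pval >= ed$pval - 1e-12))
  ed_sig <- granger_edges(fit, alpha = 0.05)
  expect_true(all(ed_sig$pval < 0.05))
})
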