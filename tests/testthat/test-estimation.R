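test_that("gaussian_basis builds covering, unit-max, unimodal columns", {
  bs <- gaussian_basis(30, 20)
  expect_equal(dim(bs$W), c(30L, 20L))
  expect_true(all(bs$W >= 0))
  expect_equal(unname(apply(bs$W, 2, max)), rep(1, 20))
  expect_true(min(rowSums(bs$W)) > 0)
  # unimodal in lag: differences change sign at most once per column
  for (k in c(1, 10, 20)) {
    s <- sign(diff(bs$W[, k]))
    expect_lte(sum(diff(s[s != 0]) != 0), 1)
  }
  expect_error(gaussian_basis(5, 6), "n_basis")
})

test_that("a square basis spans the full lag space: fit equals unconstrained", {
  set.seed(21)
  f <- random_stable_filters(2, 1, 1, 5)
  x <- matrix(rnorm(400), 400, 1)
  y <- simulate_varx(f, x = x, innovations = matrix(rnorm(800), 400, 2))
  fit_raw <- varx(y, x, n_a = 1, n_b = 5)
  # narrow square basis (width at the 0.5-lag floor): same span, same B
  fit_sq <- varx(y, x, n_a = 1, n_b = 5, n_basis = 5)
  # gaussian_basis defaults give sd = spacing = 1 here; W is invertible, so
  # the compressed fit must reproduce the unconstrained estimate
  expect_equal(fit_sq$filters$B, fit_raw$filters$B, tolerance = 1e-8)
  expect_equal(fit_sq$filters$A, fit_raw$filters$A, tolerance = 1e-8)
})

test_that("a smooth lag profile is reconstructed through the basis", {
  n_b <- 24; n_basis <- 10
  bs <- gaussian_basis(n_b, n_basis)
  lags <- 0:(n_b - 1)
  target <- exp(-0.5 * ((lags - 9) / 4)^2)          # smooth bump
  recon <- bs$W %*% qr.solve(bs$W, target)          # pseudo-inverse projection
  expect_lt(max(abs(recon - target)) / max(abs(target)), 0.05)
})

test_that("T_used follows the valid-history window rule", {
  set.seed(22)
  T <- 100
  Y <- matrix(rnorm(2 * T), T, 2); X <- matrix(rnorm(T), T, 1)
  ne <- build_normal_equations(multi_series(Y, X), n_a = 2, n_b = 2)
  expect_equal(ne$T_used, T - 2L)      # only the first max(n_a, n_b-1) lack history

  # a single missing value knocks out exactly the windows covering it
  Y2 <- Y; Y2[50, 1] <- NA
  ne2 <- build_normal_equations(multi_series(Y2, X), n_a = 2, n_b = 2)
  orc <- oracle_design(Y2, X, 2, 2)
  expect_equal(ne2$T_used, sum(orc$valid))
  expect_equal(ne2$T_used, T - 2L - 3L)   # t = 50, 51, 52 all lose validity

  expect_error(build_normal_equations(multi_series(matrix(NA_real_, 5, 1)),
                                      n_a = 1), "finite")
})

test_that("masking matches the per-sample validity oracle on random patterns", {
  set.seed(23)
  for (i in 1:100) {
    T <- 60
    Y <- matrix(rnorm(2 * T), T, 2); X <- matrix(rnorm(T), T, 1)
    Y[sample(T * 2, 5)] <- NA
    X[sample(T, 2)] <- NaN
    segs <- sort(unique(c(1L, sample(2:T, sample(0:2, 1)))))
    n_a <- sample(0:3, 1); n_b <- sample(1:3, 1)
    if (n_a == 0 && n_b == 0) n_b <- 1
    ne <- build_normal_equations(multi_series(Y, X, segment_starts = segs),
                                 n_a = n_a, n_b = n_b)
    orc <- oracle_design(Y, X, n_a, n_b, segs)
    expect_equal(ne$T_used, sum(orc$valid))
    Phi <- orc$Phi[orc$valid, , drop = FALSE]
    expect_equal(ne$R_xx, crossprod(Phi), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(ne$R_xy, crossprod(Phi, Y[orc$valid, , drop = FALSE]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("history windows never straddle a segment boundary", {
  set.seed(24)
  Y <- matrix(rnorm(40), 40, 1)
  ne_one <- build_normal_equations(multi_series(Y), n_a = 3)
  ne_two <- build_normal_equations(multi_series(Y, segment_starts = c(1, 21)),
                                   n_a = 3)
  expect_equal(ne_one$T_used, 37L)
  expect_equal(ne_two$T_used, 34L)   # 3 more samples lost at the boundary
  expect_error(build_normal_equations(
    multi_series(matrix(rnorm(4), 4, 1)), n_a = 5), "no valid samples")
})

test_that("normal equations and gamma = 0 solve agree with dense least squares", {
  set.seed(25)
  for (i in 1:5) {
    T <- sample(80:200, 1)
    d_y <- sample(1:3, 1); d_x <- sample(1:2, 1)
    n_a <- sample(1:3, 1); n_b <- sample(1:3, 1)
    f <- random_stable_filters(d_y, d_x, n_a, n_b)
    x <- matrix(rnorm(T * d_x), T, d_x)
    y <- simulate_varx(f, x = x, innovations = matrix(rnorm(T * d_y), T, d_y))
    ne <- build_normal_equations(multi_series(y, x), n_a = n_a, n_b = n_b)
    H <- ridge_solve(ne, 0)
    orc <- oracle_design(y, x, n_a, n_b)
    Phi <- orc$Phi[orc$valid, , drop = FALSE]
    H_dense <- qr.solve(Phi, y[orc$valid, , drop = FALSE])
    expect_lt(max(abs(H - H_dense)) / max(abs(H_dense)), 1e-8)
  }
})

test_that("ridge solution minimizes the penalized loss and vanishes as gamma grows", {
  set.seed(26)
  T <- 120
  Phi <- matrix(rnorm(T * 5), T, 5)
  yv <- Phi %*% rnorm(5) + rnorm(T)
  ne <- list(R_xx = crossprod(Phi), R_xy = crossprod(Phi, yv),
             R_yy_diag = sum(yv^2), T_used = T)
  gam <- 0.7
  h <- ridge_solve(ne, gam)
  loss <- function(w) sum((yv - Phi %*% w)^2) + gam * sum(diag(ne$R_xx) * w^2)
  opt <- optim(rep(0, 5), loss, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(as.vector(h), opt$par, tolerance = 1e-4)
  expect_lt(loss(as.vector(h)), opt$value + 1e-6)
  # penalty dominates
  expect_lt(max(abs(ridge_solve(ne, 1e8))), 1e-6)
})

test_that("rank-deficient unregularized systems are reported", {
  Phi <- cbind(1:20, 2 * (1:20))          # collinear predictors
  ne <- list(R_xx = crossprod(Phi), R_xy = crossprod(Phi, rnorm(20)))
  expect_error(ridge_solve(ne, 0), "rank deficient")
  expect_silent(ridge_solve(ne, 0.1))
})

test_that("residual_stats matches explicit residual computation", {
  set.seed(27)
  T <- 150
  f <- random_stable_filters(2, 1, 2, 2)
  x <- matrix(rnorm(T), T, 1)
  y <- simulate_varx(f, x = x, innovations = matrix(rnorm(2 * T), T, 2))
  ne <- build_normal_equations(multi_series(y, x), n_a = 2, n_b = 2)

  # H = 0: total variance
  rs0 <- residual_stats(ne, matrix(0, ne$N, 2))
  expect_equal(rs0$sigma2, ne$R_yy_diag / ne$T_used)

  # gamma = 0: matches materialized residuals, and R_xe = 0 (orthogonality)
  H <- ridge_solve(ne, 0)
  rs <- residual_stats(ne, H)
  orc <- oracle_design(y, x, 2, 2)
  Phi <- orc$Phi[orc$valid, , drop = FALSE]
  E <- y[orc$valid, ] - Phi %*% H
  expect_equal(rs$sigma2, colSums(E^2) / ne$T_used, tolerance = 1e-10)
  expect_lt(max(abs(rs$R_xe)) / max(abs(ne$R_xy)), 1e-10)

  # noiseless data at correct orders: near-exact fit
  y0 <- simulate_varx(f, x = x, innovations = matrix(0, T, 2))
  ne0 <- build_normal_equations(multi_series(y0, x), n_a = 2, n_b = 2)
  rs_exact <- residual_stats(ne0, ridge_solve(ne0, 0))
  expect_lt(max(rs_exact$sigma2), 1e-12)
})

test_that("unpack_coefficients inverts the design layout (with and without basis)", {
  set.seed(28)
  f <- random_stable_filters(2, 2, 3, 4)
  T <- 2000
  x <- matrix(rnorm(T * 2), T, 2)
  y <- simulate_varx(f, x = x, innovations = matrix(rnorm(T * 2), T, 2))
  fit <- varx(y, x, n_a = 3, n_b = 4)
  # recovered tensors sit near the truth, in the right slots
  expect_lt(max(abs(fit$filters$A - f$A)), 0.12)
  expect_lt(max(abs(fit$filters$B - f$B)), 0.12)
  # basis path: B equals W %*% B_compressed by construction
  fitb <- varx(y, x, n_a = 3, n_b = 4, n_basis = 3)
  bs <- gaussian_basis(4, 3)
  blk <- Filter(function(b) b$kind == "exogenous", fitb$ne$index_map)[[1]]
  expect_equal(fitb$filters$B[, , 1],
               bs$W %*% fitb$coefficients[blk$cols, ], ignore_attr = TRUE)
})

test_that("coefficient error shrinks with sample size", {
  set.seed(29)
  f <- random_stable_filters(2, 1, 2, 2)
  err <- sapply(c(500, 5000), function(T) {
    x <- matrix(rnorm(T), T, 1)
    y <- simulate_varx(f, x = x, innovations = matrix(rnorm(2 * T), T, 2))
    fit <- varx(y, x, n_a = 2, n_b = 2)
    max(abs(fit$filters$A - f$A), abs(fit$filters$B - f$B))
  })
  expect_lt(err[2], err[1])
})

test_that("n_a = 0 reduces to the moving-average (mTRF) model", {
  set.seed(30)
  T <- 500; n_b <- 4
  B <- array(rnorm(n_b * 2), c(n_b, 2, 1))
  f <- varx_filters(B = B)
  x <- matrix(rnorm(T), T, 1)
  y <- simulate_varx(f, x = x, innovations = matrix(rnorm(2 * T), T, 2))
  fit <- varx(y, x, n_a = 0, n_b = n_b, demean = FALSE)
  expect_null(fit$A_pval)                   # no endogenous tests exist
  # predictions equal the direct convolution of x with the estimated B
  Bh <- fit$filters$B
  yhat <- matrix(0, T, 2)
  for (l in 0:(n_b - 1))
    yhat[(1 + l):T, ] <- yhat[(1 + l):T, ] +
      x[1:(T - l), , drop = FALSE] %*% t(matrix(Bh[l + 1, , ], 2, 1))
  rows <- n_b:T                              # samples with full history
  orc <- oracle_design(y, x, 0, n_b)
  Phi <- orc$Phi[orc$valid, , drop = FALSE]
  expect_equal(unname(yhat[rows, ]), unname(Phi %*% fit$coefficients),
               tolerance = 1e-10)
})
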