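#' Build block-Toeplitz normal equations
#'
#' Accumulates the cross-product matrices `R_xx = sum_t phi(t) phi(t)'` and
#' `R_xy = sum_t phi(t) y(t)'` of the lagged-predictor regression
#' `Y = X H + E`, where `phi(t)` stacks, per endogenous channel, the lags
#' `y_j(t-1) .. y_j(t-n_a)` and, per exogenous channel, the lags
#' `x_j(t) .. x_j(t-n_b+1)` (optionally compressed through a [gaussian_basis()]).
#'
#' A sample `t` contributes only if `y(t)`, its full endogenous history and
#' its full exogenous history are all present and finite and lie within a
#' single recording segment; all other samples are omitted.  Missing values
#' (`NA`/`NaN`) are masked by the same window rule.  Cross-products are
#' accumulated per segment and summed, so the result is independent of
#' segment order.
#'
#' @param data a [multi_series] (or a plain matrix of endogenous series).
#' @param n_a endogenous (autoregressive) filter length, lags `1..n_a`.
#' @param n_b exogenous (moving-average) filter length, lags `0..n_b-1`.
#' @param basis optional [gaussian_basis()]; exogenous lag blocks are
#'   pre-multiplied so the compressed predictors enter the cross-products.
#' @return Object of class `normal_equations`: `R_xx` `[N, N]`, `R_xy`
#'   `[N, d_y]`, `R_yy_diag`, `T_used`, `N`, `index_map` (one entry per
#'   predictor block: name, kind, column indices, block size), plus model
#'   dimensions.
#' @export
build_normal_equations <- function(data, n_a, n_b = 0, basis = NULL) {
  ms <- as_multi_series(data)
  n_a <- as.integer(n_a); n_b <- as.integer(n_b)
  stopifnot(n_a >= 0, n_b >= 0)
  if (n_b > 0 && ms$d_x == 0)
    stop("n_b > 0 requires exogenous series in the data")
  if (ms$d_x > 0 && n_b == 0)
    n_b <- 0L  # exogenous series present but unused
  if (!is.null(basis)) {
    stopifnot(inherits(basis, "lag_basis"))
    if (basis$n_b != n_b)
      stop("basis was built for n_b = ", basis$n_b, ", fit uses n_b = ", n_b)
  }
  n_bb <- if (is.null(basis)) n_b else basis$n_basis
  N <- ms$d_y * n_a + ms$d_x * n_bb
  if (N == 0) stop("model has no predictors (n_a = 0 and n_b = 0)")

  index_map <- list(); col <- 0L
  for (j in seq_len(ms$d_y)) {
    if (n_a == 0) break
    index_map[[length(index_map) + 1L]] <-
      list(name = ms$names_y[j], kind = "endogenous",
           cols = col + seq_len(n_a), size = n_a)
    col <- col + n_a
  }
  if (n_b > 0) for (j in seq_len(ms$d_x)) {
    index_map[[length(index_map) + 1L]] <-
      list(name = ms$names_x[j], kind = "exogenous",
           cols = col + seq_len(n_bb), size = n_bb)
    col <- col + n_bb
  }

  # all-missing variables are a configuration error, not a fitting surprise
  for (j in seq_len(ms$d_y))
    if (!any(is.finite(ms$Y[, j])))
      stop("endogenous variable '", ms$names_y[j], "' has no finite values")
  if (n_b > 0) for (j in seq_len(ms$d_x))
    if (!any(is.finite(ms$X[, j])))
      stop("exogenous variable '", ms$names_x[j], "' has no finite values")

  R_xx <- matrix(0, N, N)
  R_xy <- matrix(0, N, ms$d_y)
  R_yy <- numeric(ms$d_y)
  T_used <- 0L
  seg_bounds <- c(ms$segment_starts, ms$T + 1L)
  for (s in seq_along(ms$segment_starts)) {
    rows <- seg_bounds[s]:(seg_bounds[s + 1L] - 1L)
    ph <- segment_design(ms, rows, n_a, n_b, basis)
    if (is.null(ph)) next
    R_xx <- R_xx + crossprod(ph$Phi)
    R_xy <- R_xy + crossprod(ph$Phi, ph$Y)
    R_yy <- R_yy + colSums(ph$Y^2)
    T_used <- T_used + nrow(ph$Phi)
  }
  if (T_used == 0L)
    stop("no valid samples: every sample lacks a complete finite history")
  structure(list(R_xx = R_xx, R_xy = R_xy, R_yy_diag = R_yy,
                 T_used = T_used, N = N, index_map = index_map,
                 n_a = n_a, n_b = n_b, n_basis = n_bb,
                 basis = basis, d_y = ms$d_y, d_x = ms$d_x,
                 names_y = ms$names_y, names_x = ms$names_x),
            class = "normal_equations")
}

# Lagged design for one contiguous segment; returns NULL when no row is
# valid.  Rows with incomplete or non-finite windows are dropped here.
segment_design <- function(ms, rows, n_a, n_b, basis) {
  len <- length(rows)
  Yseg <- ms$Y[rows, , drop = FALSE]
  n_bb <- if (is.null(basis)) n_b else basis$n_basis
  N <- ms$d_y * n_a + ms$d_x * n_bb
  Phi <- matrix(NA_real_, len, N)
  col <- 0L
  if (n_a > 0) for (j in seq_len(ms$d_y)) {
    for (l in seq_len(n_a)) {
      col <- col + 1L
      if (len > l) Phi[(l + 1L):len, col] <- Yseg[1:(len - l), j]
    }
  }
  if (n_b > 0) {
    Xseg <- ms$X[rows, , drop = FALSE]
    for (j in seq_len(ms$d_x)) {
      raw <- matrix(NA_real_, len, n_b)
      for (l in 0:(n_b - 1L))
        if (len > l) raw[(l + 1L):len, l + 1L] <- Xseg[1:(len - l), j]
      if (!is.null(basis)) raw <- raw %*% basis$W   # NA rows stay NA
      Phi[, col + seq_len(n_bb)] <- raw
      col <- col + n_bb
    }
  }
  ok <- rowSums(!is.finite(Phi)) == 0 & rowSums(!is.finite(Yseg)) == 0
  if (!any(ok)) return(NULL)
  list(Phi = Phi[ok, , drop = FALSE], Y = Yseg[ok, , drop = FALSE])
}

#' @export
print.normal_equations <- function(x, ...) {
  cat("normal_equations: N =", x$N, "predictors,", "T_used =", x$T_used,
      "samples, d_y =", x$d_y, "\n")
  invisible(x)
}

#' Closed-form ridge solution of the normal equations
#'
#' Solves `H = (R_xx + gamma * Gamma)^-1 R_xy` with the Tikhonov weight
#' `Gamma = diag(R_xx)`, so every predictor is regularized equally relative
#' to its own scale; `gamma = 0` gives ordinary least squares.  The system
#' is solved through a Cholesky factorization (falling back to a QR-based
#' solve if the matrix is not numerically positive definite); no explicit
#' inverse is formed.
#'
#' @param ne a [build_normal_equations()] result, or any list with `R_xx`
#'   and `R_xy`.
#' @param gamma nonnegative ridge weight (dimensionless).
#' @return Coefficient matrix `H` `[N, d_y]`.
#' @export
ridge_solve <- function(ne, gamma = 0) {
  stopifnot(gamma >= 0)
  M <- ne$R_xx
  if (gamma > 0) {
    d <- diag(M)
    diag(M) <- d + gamma * d
  }
  sym_solve(M, ne$R_xy, gamma)
}

sym_solve <- function(M, rhs, gamma = 0) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(backsolve(ch, forwardsolve(t(ch), rhs)))
  out <- tryCatch(qr.solve(M, rhs), error = function(e) NULL)
  if (!is.null(out)) return(out)
  stop("normal equations are rank deficient",
       if (gamma == 0) "; consider gamma > 0" else "")
}

#' Residual statistics of a fitted coefficient matrix
#'
#' Evaluates the per-output residual cross-products
#' `R_ee = H' R_xx H - 2 H' R_xy + R_yy` of the lagged regression, the
#' innovation variance `sigma2 = diag(R_ee) / T_used`, and the
#' predictor-residual cross-correlation `R_xe = R_xy - R_xx H` (zero at the
#' ordinary least-squares solution; nonzero under ridge shrinkage, where it
#' feeds the deviance bias correction).
#'
#' @param ne a [build_normal_equations()] result.
#' @param H_hat coefficient matrix `[N, d_y]` from [ridge_solve()].
#' @return List with `sigma2`, `R_ee_diag` (both length `d_y`) and `R_xe`
#'   `[N, d_y]`.
#' @export
residual_stats <- function(ne, H_hat) {
  stopifnot(nrow(H_hat) == nrow(ne$R_xx), ncol(H_hat) == ncol(ne$R_xy))
  RH <- ne$R_xx %*% H_hat
  ree <- colSums(H_hat * RH) - 2 * colSums(H_hat * ne$R_xy) + ne$R_yy_diag
  tol <- -1e-8 * (ne$R_yy_diag + 1)
  if (any(ree < tol))
    stop("negative residual variance: numerical failure in the solve")
  ree <- pmax(ree, 0)
  list(sigma2 = ree / ne$T_used, R_ee_diag = ree,
       R_xe = ne$R_xy - RH)
}

#' Unpack a coefficient matrix into VARX filters
#'
#' Maps the stacked regression coefficients back to the lag-domain filter
#' tensors `A` (lags `1..n_a`) and `B` (lags `0..n_b-1`).  When the fit used
#' a lag basis, the compressed input coefficients are expanded as
#' `B(l) = sum_k W[l, k] B_c(k)`.
#'
#' @param H_hat coefficient matrix `[N, d_y]`.
#' @param ne the [build_normal_equations()] object the fit used.
#' @param basis optional [gaussian_basis()]; defaults to the one recorded
#'   in `ne`.
#' @return A [varx_filters] object.
#' @export
unpack_coefficients <- function(H_hat, ne, basis = ne$basis) {
  d_y <- ne$d_y; d_x <- ne$d_x
  A <- NULL; B <- NULL
  if (ne$n_a > 0) {
    A <- array(0, c(ne$n_a, d_y, d_y))
    for (blk in ne$index_map) {
      if (blk$kind != "endogenous") next
      j <- match(blk$name, ne$names_y)
      # H rows blk$cols are lags 1..n_a of source j; columns are targets
      A[, , j] <- H_hat[blk$cols, , drop = FALSE]
    }
  }
  if (ne$n_b > 0) {
    B <- array(0, c(ne$n_b, d_y, d_x))
    for (blk in ne$index_map) {
      if (blk$kind != "exogenous") next
      j <- match(blk$name, ne$names_x)
      Bc <- H_hat[blk$cols, , drop = FALSE]        # [n_bb, d_y]
      B[, , j] <- if (is.null(basis)) Bc else basis$W %*% Bc
    }
  }
  varx_filters(A = A, B = B, d_y = d_y, d_x = d_x,
               names_y = ne$names_y,
               names_x = if (d_x > 0) ne$names_x else NULL)
}
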