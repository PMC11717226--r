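#' Deviance between nested Gaussian models
#'
#' The likelihood-ratio (deviance) statistic `D = T * log(sigma2_r /
#' sigma2_f)` comparing a reduced to a full model per output channel.  For
#' normal i.i.d. errors this equals twice the Gaussian log-likelihood ratio
#' and is asymptotically chi-square under the null, with degrees of freedom
#' equal to the number of removed parameters.
#'
#' @param sigma2_reduced,sigma2_full strictly positive residual-variance
#'   vectors of the reduced and full models (elementwise).
#' @param T_used number of samples entering both fits.
#' @return Deviance vector, one element per output channel.
#' @seealso [debiased_deviance()], [chi2_pvalue()], [effect_size()]
#' @export
deviance_stat <- function(sigma2_reduced, sigma2_full, T_used) {
  check_variances(sigma2_reduced, sigma2_full)
  T_used * log(sigma2_reduced / sigma2_full)
}

check_variances <- function(sr, sf) {
  if (any(!is.finite(sr)) || any(!is.finite(sf)) ||
      any(sr <= 0) || any(sf <= 0))
    stop("degenerate fit: residual variances must be strictly positive")
  invisible(NULL)
}

#' Deviance bias correction under L2 regularization
#'
#' Ridge shrinkage leaves the residuals correlated with the predictors
#' (`R_xe != 0`), which biases the plain deviance.  The correction per
#' output channel is the quadratic form
#' `b = 0.5 * diag(R_xe' R_xx^-1 R_xe) / diag(R_ee)`,
#' computed for the full and reduced models and differenced inside
#' [debiased_deviance()].  At the ordinary least-squares solution
#' `R_xe = 0` and the correction vanishes exactly.
#'
#' @param R_xe predictor-residual cross-products `[N, d_y]` from
#'   [residual_stats()].
#' @param R_xx predictor cross-product matrix `[N, N]` (unregularized, as
#'   the correction formula is written; see `regularized`).
#' @param R_ee_diag residual sum-of-squares per output channel.
#' @param gamma,regularized if `regularized = TRUE` the inverse of the
#'   regularized matrix `R_xx + gamma * diag(R_xx)` is used instead of the
#'   raw inverse — a sensitivity variant, off by default.
#' @return Nonnegative bias vector `b`, length `d_y`.
#' @export
bias_correction <- function(R_xe, R_xx, R_ee_diag, gamma = 0,
                            regularized = FALSE) {
  M <- R_xx
  if (regularized && gamma > 0) diag(M) <- diag(M) * (1 + gamma)
  S <- sym_solve(M, R_xe)
  q <- colSums(R_xe * S)                      # diag(R_xe' M^-1 R_xe)
  b <- ifelse(R_ee_diag > 0, 0.5 * q / R_ee_diag, 0)
  pmax(b, 0)
}

#' De-biased deviance for ridge-regularized fits
#'
#' `D = T_eff * log(sigma2_r / sigma2_f) - b_r + b_f`, where `b_f` and
#' `b_r` are the [bias_correction()] terms of the full and reduced models
#' and `T_eff` is the effective sample count (`T - N`, the residual degrees
#' of freedom of the full model, which is the conservative choice for
#' finite samples).  Slightly negative values can occur once the bias terms
#' are subtracted; they are clamped to 0, which maps to p = 1.
#'
#' @inheritParams deviance_stat
#' @param b_reduced,b_full bias-correction vectors for the two models.
#' @param T_effective effective sample count `T' = T_used - N`.
#' @return Nonnegative de-biased deviance vector.
#' @export
debiased_deviance <- function(sigma2_reduced, sigma2_full,
                              b_reduced, b_full, T_effective) {
  check_variances(sigma2_reduced, sigma2_full)
  pmax(T_effective * log(sigma2_reduced / sigma2_full) -
         b_reduced + b_full, 0)
}

#' Chi-square p-values for deviance statistics
#'
#' `p = 1 - F(D, n)` with `F` the chi-square CDF and `n` the number of
#' parameters removed in the reduced model (`n_a` for an endogenous
#' channel, `n_b` — or the basis count — for an exogenous channel).
#'
#' @param D nonnegative deviance vector.
#' @param n_removed degrees of freedom, a positive integer.
#' @return p-value vector in `[0, 1]`.
#' @export
chi2_pvalue <- function(D, n_removed) {
  if (length(n_removed) != 1 || n_removed < 1)
    stop("n_removed must be a single positive integer")
  if (any(D < 0, na.rm = TRUE)) stop("deviance must be nonnegative")
  stats::pchisq(D, df = n_removed, lower.tail = FALSE)
}

#' Generalized R-squared effect size
#'
#' `R2 = 1 - exp(-D / T)`: the coefficient of determination generalized to
#' nested likelihood comparisons.  Unlike the deviance, which grows
#' linearly with `T`, this is a per-sample effect size; figures typically
#' display its square root `R`.
#'
#' @param D deviance vector.
#' @param T_used sample count used in the deviance.
#' @return Vector of effect sizes in `[0, 1)`.
#' @export
effect_size <- function(D, T_used) {
  stopifnot(T_used > 0)
  1 - exp(-D / T_used)
}

#' Fit a VARX model and run per-channel Granger tests
#'
#' Estimates the full model once from the block-Toeplitz normal equations,
#' then, for every predictor variable (each endogenous channel's `n_a` lags
#' and each exogenous channel's `n_b` — or basis-compressed — lags), solves
#' the reduced model by deleting that block's rows and columns from the
#' cached cross-products, with no re-scan of the data.  Each comparison
#' yields a deviance, a chi-square p-value, and a generalized R-squared,
#' arranged as target-by-source matrices.  The diagonal of the `A` matrices
#' tests each channel's own history like any other predictor.
#'
#' With `gamma > 0` and `bias_correction = TRUE` (the default in that
#' case), deviances are de-biased with [bias_correction()] terms and the
#' effective sample count `T' = T_used - N`; at `gamma = 0` the plain
#' deviance with `T_used` is used.
#'
#' @param y endogenous series: matrix/data frame `[T, d_y]` or a
#'   [multi_series] (in which case `x` and `segment_starts` are taken from
#'   it).
#' @param x optional exogenous series `[T, d_x]`.
#' @param n_a,n_b endogenous and exogenous filter lengths.
#' @param gamma ridge weight (see [ridge_solve()]); default 0.  No
#'   automatic selection is performed.
#' @param n_basis optional number of Gaussian basis functions for the
#'   exogenous filters (see [gaussian_basis()]).
#' @param demean subtract each variable's mean (computed over finite
#'   samples) before fitting; the model carries no intercept, so this is
#'   the zero-mean-signals convention.  Default `TRUE`.
#' @param bias_correction apply the de-biased deviance; default on exactly
#'   when `gamma > 0`.
#' @param regularized_inverse use the regularized inverse inside
#'   [bias_correction()] (sensitivity variant; default `FALSE`).
#' @param segment_starts independent-segment start indices (ignored when
#'   `y` is a [multi_series]).
#' @return Object of class `varx_granger` with elements `filters` (a
#'   [varx_filters]), `A_deviance`, `A_pval`, `A_R2` (`[d_y, d_y]`,
#'   target x source), `B_deviance`, `B_pval`, `B_R2` (`[d_y, d_x]`),
#'   `sigma2` (full-model innovation variances), `bias_full`,
#'   `A_bias_reduced`, `B_bias_reduced`, `T_used`, `T_effective`, `N`, the
#'   fitted `ne` (normal equations), and the configuration echo.
#' @examples
#' set.seed(1)
#' f <- varx_filters(A = array(c(0.5, 0.2, 0, 0.4), c(1, 2, 2)),
#'                   B = array(c(1, 0), c(1, 2, 1)))
#' x <- matrix(rnorm(500), 500, 1)
#' y <- simulate_varx(f, x = x)
#' fit <- varx(y, x, n_a = 1, n_b = 1)
#' fit$A_pval
#' @export
varx <- function(y, x = NULL, n_a, n_b = 0, gamma = 0, n_basis = NULL,
                 demean = TRUE, bias_correction = gamma > 0,
                 regularized_inverse = FALSE, segment_starts = 1L) {
  ms <- as_multi_series(y, x, segment_starts)
  if (demean) {
    ms$Y <- scale(ms$Y, center = TRUE, scale = FALSE)[, , drop = FALSE]
    if (ms$d_x > 0)
      ms$X <- scale(ms$X, center = TRUE, scale = FALSE)[, , drop = FALSE]
  }
  basis <- if (!is.null(n_basis)) gaussian_basis(n_b, n_basis) else NULL
  ne <- build_normal_equations(ms, n_a = n_a, n_b = n_b, basis = basis)
  # a predictor with zero variance after masking carries no information and
  # makes the unregularized system singular: exclude it from the model and
  # from testing, with a warning
  degenerate <- vapply(ne$index_map,
                       function(b) any(diag(ne$R_xx)[b$cols] <=
                                         1e-12 * ne$T_used),
                       logical(1))
  if (any(degenerate)) {
    warning("predictor(s) with zero variance after masking excluded ",
            "from model and testing: ",
            paste(vapply(ne$index_map[degenerate], `[[`, "", "name"),
                  collapse = ", "), call. = FALSE)
    ne <- drop_predictor_blocks(ne, which(degenerate))
  }
  use_debias <- isTRUE(bias_correction) && gamma > 0
  if (gamma == 0 && ne$T_used <= ne$N)
    stop("T_used (", ne$T_used, ") must exceed N (", ne$N,
         ") for an unregularized fit; consider gamma > 0")

  H_f <- ridge_solve(ne, gamma)
  rs_f <- residual_stats(ne, H_f)
  b_f <- if (use_debias)
    bias_correction(rs_f$R_xe, ne$R_xx, rs_f$R_ee_diag,
                    gamma = gamma, regularized = regularized_inverse)
  else numeric(ne$d_y)
  T_eff <- if (use_debias) ne$T_used - ne$N else ne$T_used
  if (T_eff <= 0)
    stop("effective sample count T' = T_used - N is not positive")

  d_y <- ne$d_y; d_x <- ne$d_x
  mk <- function(nc, cn) matrix(NA_real_, d_y, nc,
                                dimnames = list(ne$names_y, cn))
  A_D <- mk(d_y, ne$names_y); A_p <- mk(d_y, ne$names_y)
  A_R2 <- mk(d_y, ne$names_y); A_br <- mk(d_y, ne$names_y)
  has_B <- ne$n_b > 0
  B_D <- mk(d_x, ne$names_x); B_p <- mk(d_x, ne$names_x)
  B_R2 <- mk(d_x, ne$names_x); B_br <- mk(d_x, ne$names_x)

  for (blk in ne$index_map) {
    res <- tryCatch(
      reduced_test(ne, blk, H_full_sigma2 = rs_f$sigma2, b_f = b_f,
                   gamma = gamma, use_debias = use_debias, T_eff = T_eff,
                   regularized_inverse = regularized_inverse),
      error = function(e) {
        warning("test for predictor '", blk$name, "' failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    if (blk$kind == "endogenous") {
      j <- match(blk$name, ne$names_y)
      A_D[, j] <- res$D; A_p[, j] <- res$p
      A_R2[, j] <- res$R2; A_br[, j] <- res$b_r
    } else {
      j <- match(blk$name, ne$names_x)
      B_D[, j] <- res$D; B_p[, j] <- res$p
      B_R2[, j] <- res$R2; B_br[, j] <- res$b_r
    }
  }

  has_A <- ne$n_a > 0
  structure(list(
    filters = unpack_coefficients(H_f, ne),
    coefficients = H_f,
    A_deviance = if (has_A) A_D else NULL,
    A_pval = if (has_A) A_p else NULL,
    A_R2 = if (has_A) A_R2 else NULL,
    B_deviance = if (has_B) B_D else NULL,
    B_pval = if (has_B) B_p else NULL,
    B_R2 = if (has_B) B_R2 else NULL,
    sigma2 = rs_f$sigma2,
    bias_full = b_f,
    A_bias_reduced = if (has_A) A_br else NULL,
    B_bias_reduced = if (has_B) B_br else NULL,
    T_used = ne$T_used, T_effective = T_eff, N = ne$N,
    ne = ne,
    config = list(n_a = ne$n_a, n_b = ne$n_b, gamma = gamma,
                  n_basis = n_basis, demean = demean,
                  bias_correction = use_debias,
                  regularized_inverse = regularized_inverse,
                  segment_starts = ms$segment_starts)),
    class = "varx_granger")
}

drop_predictor_blocks <- function(ne, drop_idx) {
  drop_cols <- unlist(lapply(ne$index_map[drop_idx], `[[`, "cols"))
  keep <- setdiff(seq_len(ne$N), drop_cols)
  ne$R_xx <- ne$R_xx[keep, keep, drop = FALSE]
  ne$R_xy <- ne$R_xy[keep, , drop = FALSE]
  ne$index_map <- ne$index_map[-drop_idx]
  col <- 0L
  for (i in seq_along(ne$index_map)) {
    ne$index_map[[i]]$cols <- col + seq_len(ne$index_map[[i]]$size)
    col <- col + ne$index_map[[i]]$size
  }
  ne$N <- length(keep)
  ne
}

# Elementwise deviance that tolerates degenerate (zero-variance) targets by
# reporting NA for them instead of failing the whole comparison.
lenient_deviance <- function(sr, sf, T_eff, b_r = NULL, b_f = NULL) {
  ok <- is.finite(sr) & is.finite(sf) & sr > 0 & sf > 0
  D <- rep(NA_real_, length(sr))
  D[ok] <- T_eff * log(sr[ok] / sf[ok])
  if (!is.null(b_r)) D[ok] <- D[ok] - b_r[ok] + b_f[ok]
  pmax(D, 0)
}

# One leave-one-block-out comparison: submatrix solve on the cached normal
# equations, never a re-scan of the data.
reduced_test <- function(ne, blk, H_full_sigma2, b_f, gamma, use_debias,
                         T_eff, regularized_inverse) {
  dxx <- diag(ne$R_xx)[blk$cols]
  if (any(dxx <= 0))
    stop("predictor block has zero variance after masking")
  keep <- setdiff(seq_len(ne$N), blk$cols)
  ne_r <- list(R_xx = ne$R_xx[keep, keep, drop = FALSE],
               R_xy = ne$R_xy[keep, , drop = FALSE],
               R_yy_diag = ne$R_yy_diag, T_used = ne$T_used)
  H_r <- ridge_solve(ne_r, gamma)
  rs_r <- residual_stats_raw(ne_r, H_r)
  if (use_debias) {
    b_r <- bias_correction(rs_r$R_xe, ne_r$R_xx, rs_r$R_ee_diag,
                           gamma = gamma, regularized = regularized_inverse)
    D <- lenient_deviance(rs_r$sigma2, H_full_sigma2, T_eff, b_r, b_f)
  } else {
    b_r <- numeric(length(H_full_sigma2))
    D <- lenient_deviance(rs_r$sigma2, H_full_sigma2, T_eff)
  }
  p <- rep(NA_real_, length(D))
  p[!is.na(D)] <- chi2_pvalue(D[!is.na(D)], blk$size)
  list(D = D, p = p,
       R2 = effect_size(D, T_eff), b_r = b_r,
       sigma2_r = rs_r$sigma2)
}

# residual_stats for a bare list (reduced model) — same algebra
residual_stats_raw <- function(ne, H_hat) {
  RH <- ne$R_xx %*% H_hat
  ree <- pmax(colSums(H_hat * RH) - 2 * colSums(H_hat * ne$R_xy) +
                ne$R_yy_diag, 0)
  list(sigma2 = ree / ne$T_used, R_ee_diag = ree, R_xe = ne$R_xy - RH)
}

#' @export
print.varx_granger <- function(x, digits = 3, ...) {
  cat("VARX Granger analysis: d_y =", x$ne$d_y, ", d_x =", x$ne$d_x,
      ", n_a =", x$ne$n_a, ", n_b =", x$ne$n_b, "\n")
  cat("T_used =", x$T_used, ", N =", x$N,
      ", gamma =", x$config$gamma,
      if (x$config$bias_correction) ", de-biased deviance (T' = T - N)",
      "\n")
  if (!is.null(x$A_R2)) {
    cat("\nEndogenous effects, sqrt(R2) [target x source]:\n")
    print(round(sqrt(x$A_R2), digits))
    cat("\nEndogenous p-values:\n")
    print(signif(x$A_pval, digits))
  }
  if (!is.null(x$B_pval)) {
    cat("\nExogenous effects, sqrt(R2) [target x input]:\n")
    print(round(sqrt(x$B_R2), digits))
    cat("\nExogenous p-values:\n")
    print(signif(x$B_pval, digits))
  }
  invisible(x)
}

#' Edge list of significant Granger effects
#'
#' Flattens the test matrices of a [varx()] fit into a long table for graph
#' consumers, optionally thresholded on (optionally Benjamini-Hochberg
#' adjusted) p-values.  No adjustment is applied by default; the full raw
#' p-value matrices remain in the fit object.
#'
#' @param fit a `varx_granger` object.
#' @param alpha optional significance threshold; `NULL` keeps every edge.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment across all reported tests.
#' @return `data.frame` with columns `source`, `target`, `kind` (`"A"` for
#'   endogenous, `"B"` for exogenous), `R`, `R2`, `deviance`, `pval`.
#' @export
granger_edges <- function(fit, alpha = NULL, adjust = c("none", "BH")) {
  stopifnot(inherits(fit, "varx_granger"))
  adjust <- match.arg(adjust)
  grab <- function(D, p, R2, kind, sources) {
    if (is.null(p)) return(NULL)
    data.frame(
      source = rep(sources, each = nrow(p)),
      target = rep(rownames(p), times = ncol(p)),
      kind = kind,
      R = sqrt(as.vector(R2)),
      R2 = as.vector(R2),
      deviance = as.vector(D),
      pval = as.vector(p),
      stringsAsFactors = FALSE)
  }
  edges <- rbind(
    grab(fit$A_deviance, fit$A_pval, fit$A_R2, "A", colnames(fit$A_pval)),
    grab(fit$B_deviance, fit$B_pval, fit$B_R2, "B",
         colnames(fit$B_pval %||% matrix(NA, 0, 0))))
  if (adjust == "BH") edges$pval <- stats::p.adjust(edges$pval, "BH")
  if (!is.null(alpha)) edges <- edges[!is.na(edges$pval) &
                                        edges$pval < alpha, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}
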