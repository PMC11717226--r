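#' Gaussian lag basis for the input filters
#'
#' Builds a bank of `n_basis` Gaussian bumps over the lag axis `0..n_b - 1`
#' used to compress the moving-average filters `B` as `B = W %*% B_c`:
#' long, smooth input responses are then estimated with `n_basis < n_b`
#' parameters per input channel, which both regularizes and rebalances the
#' parameter count against the (short) autoregressive filters.
#'
#' Centers are equally spaced across the lag range including both endpoints
#' (first center at lag 0, last at `n_b - 1`); the standard deviation
#' defaults to the center spacing, with a floor of 0.5 lag so no column
#' degenerates.  Columns are normalized to unit maximum.
#'
#' @param n_b filter length (number of lags) being represented.
#' @param n_basis number of basis functions, `1 <= n_basis <= n_b`.
#' @param width optional standard deviation in lag units (default: center
#'   spacing); the 0.5-lag floor always applies.
#' @return Object of class `lag_basis`: list with `W` (matrix
#'   `[n_b, n_basis]`, nonnegative, unit column maxima), `centers`,
#'   `widths`, `n_b`, `n_basis`.
#' @examples
#' bs <- gaussian_basis(30, 20)
#' dim(bs$W)
#' @export
gaussian_basis <- function(n_b, n_basis, width = NULL) {
  n_b <- as.integer(n_b); n_basis <- as.integer(n_basis)
  if (n_basis < 1 || n_basis > n_b)
    stop("n_basis must satisfy 1 <= n_basis <= n_b (got n_basis = ",
         n_basis, ", n_b = ", n_b, ")")
  lags <- 0:(n_b - 1L)
  if (n_basis == 1L) {
    centers <- (n_b - 1) / 2
    spacing <- max(n_b - 1, 1)
  } else {
    centers <- seq(0, n_b - 1, length.out = n_basis)
    spacing <- centers[2] - centers[1]
  }
  sd <- max(width %||% spacing, 0.5)
  W <- outer(lags, centers, function(l, c) exp(-0.5 * ((l - c) / sd)^2))
  W <- sweep(W, 2, apply(W, 2, max), "/")
  if (min(rowSums(W)) <= 0)
    stop("basis leaves uncovered lags")  # cannot occur for Gaussians
  structure(list(W = W, centers = centers,
                 widths = rep(sd, n_basis),
                 n_b = n_b, n_basis = n_basis),
            class = "lag_basis")
}

#' @export
print.lag_basis <- function(x, ...) {
  cat("Gaussian lag basis:", x$n_basis, "functions over", x$n_b,
      "lags (sd =", format(x$widths[1], digits = 3), "lag)\n")
  invisible(x)
}
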