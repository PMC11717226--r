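#' Simulate a VARX (equation-error) process
#'
#' Runs the recursion
#' `y(t) = sum_l A(l) y(t-l) + sum_l B(l) x(t-l) + e(t)` with all
#' pre-history samples (`t <= 0`) treated as zero.  The innovation `e(t)`
#' enters the recursion, so it drives the endogenous dynamic (equation-error
#' convention); contrast [simulate_output_error()].
#'
#' @param filters a [varx_filters] object.
#' @param x exogenous series, matrix `[T, d_x]` (or `NULL` when `d_x = 0`).
#' @param innovations either an explicit matrix `[T, d_y]` (reproducibility)
#'   or `NULL`, in which case i.i.d. Gaussian innovations with standard
#'   deviation `innovation_sd` are drawn (seed the session RNG, or pass
#'   `seed`).
#' @param n_time series length; required when both `x` and `innovations` are
#'   `NULL`, otherwise inferred.
#' @param innovation_sd standard deviation of drawn Gaussian innovations.
#' @param seed optional integer; when given, the innovation draw uses it via
#'   a local RNG state (the session RNG stream is left untouched).
#' @return Matrix `[T, d_y]` of simulated outputs (columns named).  If the
#'   recursion diverges to non-finite values the full series is still
#'   returned, with a warning of class `varx_instability` carrying the first
#'   offending time index (`attr(w, "first_nonfinite")`); values are never
#'   clipped.
#' @seealso [simulate_output_error()], [impulse_response()]
#' @export
simulate_varx <- function(filters, x = NULL, innovations = NULL,
                          n_time = NULL, innovation_sd = 1, seed = NULL) {
  stopifnot(inherits(filters, "varx_filters"))
  d_y <- filters$d_y; d_x <- filters$d_x
  n_a <- filters$n_a; n_b <- filters$n_b
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (ncol(x) != d_x)
      stop("x has ", ncol(x), " columns but filters declare d_x = ", d_x)
    if (is.null(n_time)) n_time <- nrow(x)
    if (n_time != nrow(x)) stop("n_time does not match nrow(x)")
  } else if (d_x > 0 && n_b > 0) {
    stop("filters declare d_x = ", d_x, " inputs but x is missing")
  }
  if (!is.null(innovations)) {
    innovations <- as.matrix(innovations)
    if (ncol(innovations) != d_y)
      stop("innovations must have d_y = ", d_y, " columns")
    if (is.null(n_time)) n_time <- nrow(innovations)
    if (n_time != nrow(innovations))
      stop("innovations length does not match series length")
  }
  if (is.null(n_time))
    stop("series length cannot be inferred; supply x, innovations or n_time")
  if (is.null(innovations)) {
    innovations <- local_rnorm_matrix(n_time, d_y, innovation_sd, seed)
  }

  # drive term u(t) = B * x(t) + e(t), fully vectorizable
  u <- innovations
  if (n_b > 0 && d_x > 0) {
    for (l in 0:(n_b - 1L)) {
      Bl <- matrix(filters$B[l + 1L, , ], d_y, d_x)
      rows <- seq_len(n_time - l)
      u[rows + l, ] <- u[rows + l, , drop = FALSE] +
        x[rows, , drop = FALSE] %*% t(Bl)
    }
  }
  y <- ar_recursion(filters$A, n_a, u)
  colnames(y) <- filters$names_y
  check_finite_series(y)
  y
}

# y(t) = u(t) + sum_l A(l) y(t-l); pre-history zero.
ar_recursion <- function(A, n_a, u) {
  n_time <- nrow(u); d_y <- ncol(u)
  if (n_a == 0 || n_time == 0) return(u)
  Al <- lapply(seq_len(n_a), function(l) matrix(A[l, , ], d_y, d_y))
  y <- u
  for (t in seq_len(n_time)) {
    acc <- y[t, ]
    for (l in seq_len(min(n_a, t - 1L)))
      acc <- acc + Al[[l]] %*% y[t - l, ]
    y[t, ] <- acc
  }
  y
}

check_finite_series <- function(y) {
  bad <- !is.finite(y)
  if (any(bad)) {
    first <- min(which(rowSums(bad) > 0))
    w <- simpleWarning(paste0(
      "simulated series becomes non-finite at t = ", first,
      " (unstable recursion?)"))
    class(w) <- c("varx_instability", class(w))
    attr(w, "first_nonfinite") <- first
    warning(w)
  }
  invisible(y)
}

local_rnorm_matrix <- function(n, d, sd, seed) {
  if (is.null(seed))
    return(matrix(stats::rnorm(n * d, sd = sd), n, d))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  matrix(stats::rnorm(n * d, sd = sd), n, d)
}

#' Simulate an output-error process
#'
#' Runs the noise-free recursion `z(t) = sum_l A(l) z(t-l) + sum_l B(l)
#' x(t-l)` and observes `y(t) = z(t) + e(t)`: the noise is purely
#' observational and never enters the recursion.  With zero noise this
#' coincides exactly with [simulate_varx()] at `e = 0`.
#'
#' @inheritParams simulate_varx
#' @param noise explicit observation-noise matrix `[T, d_y]`, or `NULL` to
#'   draw i.i.d. Gaussian noise with standard deviation `noise_sd`.
#' @param noise_sd standard deviation of drawn observation noise.
#' @param return_state if `TRUE`, return `list(y, z)` with the hidden
#'   noise-free state `z`; otherwise just `y`.
#' @return Matrix `[T, d_y]` (or a list, see `return_state`).
#' @export
simulate_output_error <- function(filters, x = NULL, noise = NULL,
                                  n_time = NULL, noise_sd = 1, seed = NULL,
                                  return_state = FALSE) {
  stopifnot(inherits(filters, "varx_filters"))
  if (!is.null(x) && is.null(n_time)) n_time <- nrow(as.matrix(x))
  if (!is.null(noise) && is.null(n_time)) n_time <- nrow(as.matrix(noise))
  if (is.null(n_time))
    stop("series length cannot be inferred; supply x, noise or n_time")
  z <- simulate_varx(filters, x = x,
                     innovations = matrix(0, n_time, filters$d_y),
                     n_time = n_time)
  if (is.null(noise))
    noise <- local_rnorm_matrix(n_time, filters$d_y, noise_sd, seed)
  noise <- as.matrix(noise)
  if (!all(dim(noise) == c(n_time, filters$d_y)))
    stop("noise must be a [T, d_y] matrix")
  y <- z + noise
  colnames(y) <- filters$names_y
  if (return_state) list(y = y, z = z) else y
}
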