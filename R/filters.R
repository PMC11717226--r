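#' VARX filter set
#'
#' Container for the filters of a vector autoregressive model with exogenous
#' input (VARX),
#' \deqn{y(t) = \sum_{l=1}^{n_a} A(l)\,y(t-l) + \sum_{l=0}^{n_b-1} B(l)\,x(t-l) + e(t),}
#' where `A` holds the endogenous (autoregressive) filters and `B` the
#' exogenous (moving-average) filters.  Lag conventions: `A` acts on
#' `y(t-l)` for `l = 1..n_a`; `B` acts on `x(t-l)` for `l = 0..n_b-1`.
#'
#' @param A numeric array `[n_a, d_y, d_y]` indexed `[lag, target, source]`,
#'   or `NULL` for a pure moving-average model (`n_a = 0`).  Row = target.
#' @param B numeric array `[n_b, d_y, d_x]` indexed `[lag, target, input]`
#'   where the first slice is lag 0, or `NULL` for a pure VAR (`n_b = 0`,
#'   `d_x = 0`).
#' @param d_y,d_x dimensions, required only when they cannot be inferred
#'   (e.g. `A = NULL` needs `d_y`; `B = NULL` leaves `d_x = 0`).
#' @param names_y,names_x optional variable names.
#'
#' @return An object of class `varx_filters` with elements `A`, `B`, `n_a`,
#'   `n_b`, `d_y`, `d_x`, `names_y`, `names_x`.
#' @examples
#' f <- varx_filters(A = array(0.5, c(1, 1, 1)), B = array(1, c(1, 1, 1)))
#' spectral_radius(f)
#' @export
varx_filters <- function(A = NULL, B = NULL, d_y = NULL, d_x = NULL,
                         names_y = NULL, names_x = NULL) {
  if (!is.null(A)) {
    A <- as_lag_array(A, "A")
    if (dim(A)[2] != dim(A)[3])
      stop("A must be square in (target, source): got [",
           paste(dim(A), collapse = ", "), "]")
    if (is.null(d_y)) d_y <- dim(A)[2]
    if (d_y != dim(A)[2]) stop("d_y inconsistent with dim(A)")
  }
  if (!is.null(B)) {
    B <- as_lag_array(B, "B")
    if (is.null(d_y)) d_y <- dim(B)[2]
    if (d_y != dim(B)[2])
      stop("target dimension of B (", dim(B)[2], ") does not match d_y (",
           d_y, ")")
    if (is.null(d_x)) d_x <- dim(B)[3]
    if (d_x != dim(B)[3]) stop("d_x inconsistent with dim(B)")
  }
  if (is.null(d_y)) stop("d_y cannot be inferred; supply A, B or d_y")
  if (is.null(d_x)) d_x <- 0L
  n_a <- if (is.null(A)) 0L else dim(A)[1]
  n_b <- if (is.null(B)) 0L else dim(B)[1]
  if (is.null(A)) A <- array(0, c(0L, d_y, d_y))
  if (is.null(B)) B <- array(0, c(0L, d_y, d_x))
  if (length(A) && any(!is.finite(A))) stop("A contains non-finite values")
  if (length(B) && any(!is.finite(B))) stop("B contains non-finite values")
  if (!is.null(names_y) && length(names_y) != d_y)
    stop("names_y must have length d_y")
  if (!is.null(names_x) && length(names_x) != d_x)
    stop("names_x must have length d_x")
  structure(
    list(A = A, B = B, n_a = as.integer(n_a), n_b = as.integer(n_b),
         d_y = as.integer(d_y), d_x = as.integer(d_x),
         names_y = names_y %||% paste0("y", seq_len(d_y)),
         names_x = names_x %||% (if (d_x > 0) paste0("x", seq_len(d_x))
                                 else character())),
    class = "varx_filters")
}

# Coerce scalar / matrix shorthand into a [lag, target, source] array.
as_lag_array <- function(a, what) {
  if (is.null(dim(a)) && length(a) >= 1) a <- array(a, c(length(a), 1, 1))
  if (length(dim(a)) == 2) a <- array(a, c(1, dim(a)))
  if (length(dim(a)) != 3)
    stop(what, " must be a 3-d array [lag, target, source]")
  storage.mode(a) <- "double"
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.varx_filters <- function(x, ...) {
  cat("VARX filters: d_y =", x$d_y, ", d_x =", x$d_x,
      ", n_a =", x$n_a, ", n_b =", x$n_b, "\n")
  if (x$n_a > 0)
    cat("  spectral radius of A:", format(spectral_radius(x), digits = 4),
        "\n")
  invisible(x)
}

#' Spectral radius of the autoregressive part
#'
#' Largest eigenvalue magnitude of the companion matrix of `A`.  A value
#' below 1 means the recursion `y(t) = A * y(t-1) + ...` is stable; the
#' estimator itself never enforces stability, so this is a diagnostic.
#'
#' @param filters a [varx_filters] object.
#' @return Nonnegative scalar; 0 by convention when `n_a = 0`.
#' @export
spectral_radius <- function(filters) {
  stopifnot(inherits(filters, "varx_filters"))
  n_a <- filters$n_a; d_y <- filters$d_y
  if (n_a == 0 || d_y == 0) return(0)
  # companion matrix: first block-row = [A(1) ... A(n_a)], subdiagonal I
  n <- n_a * d_y
  C <- matrix(0, n, n)
  for (l in seq_len(n_a))
    C[seq_len(d_y), (l - 1L) * d_y + seq_len(d_y)] <- filters$A[l, , ]
  if (n_a > 1)
    C[(d_y + 1L):n, seq_len(n - d_y)] <- diag(n - d_y)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Total system impulse response
#'
#' The total response of the system to a unit impulse in each input,
#' \eqn{H = (I - A)^{-1} B} in the transform domain.  Computed in the time
#' domain by passing a unit impulse through [simulate_varx()] with the
#' innovation set to zero, truncated at `horizon` lags.
#'
#' @param filters a [varx_filters] object with `d_x >= 1`.
#' @param horizon number of lags (>= 1) to return; `horizon >= n_b` is
#'   recommended so the direct feed-through is fully covered.
#' @return Array `[horizon, d_y, d_x]`; slice `[l, , j]` is the response at
#'   lag `l - 1` to an impulse in input `j`.  An unstable `A` produces a
#'   diverging (still truncated) response with a warning.
#' @export
impulse_response <- function(filters, horizon) {
  stopifnot(inherits(filters, "varx_filters"), horizon >= 1)
  if (filters$d_x == 0)
    stop("impulse_response requires at least one input (d_x >= 1)")
  H <- array(0, c(horizon, filters$d_y, filters$d_x),
             dimnames = list(NULL, filters$names_y, filters$names_x))
  for (j in seq_len(filters$d_x)) {
    x <- matrix(0, horizon, filters$d_x)
    x[1, j] <- 1
    y <- withCallingHandlers(
      simulate_varx(filters, x = x,
                    innovations = matrix(0, horizon, filters$d_y)),
      varx_instability = function(w) invokeRestart("muffleWarning"))
    H[, , j] <- y
  }
  if (filters$n_a > 0 && spectral_radius(filters) >= 1)
    warning("unstable AR filter (spectral radius >= 1): ",
            "impulse response diverges and is returned truncated",
            call. = FALSE)
  H
}

#' Write / read VARX filters as JSON
#'
#' Serializes filters to a JSON document with fields `n_a`, `n_b`, `d_y`,
#' `d_x`, nested coefficient lists `A[lag][target][source]` and
#' `B[lag][target][input]`, and variable names.  Values are written at full
#' precision so that a write/read cycle round-trips exactly.
#'
#' @param filters a [varx_filters] object.
#' @param path file path; `write_filters` creates or overwrites it.
#' @return `read_filters` returns a [varx_filters] object;
#'   `write_filters` returns `path` invisibly.
#' @export
write_filters <- function(filters, path) {
  stopifnot(inherits(filters, "varx_filters"))
  doc <- list(
    n_a = filters$n_a, n_b = filters$n_b,
    d_y = filters$d_y, d_x = filters$d_x,
    names_y = as.list(filters$names_y),
    names_x = as.list(filters$names_x),
    A = lag_array_to_list(filters$A),
    B = lag_array_to_list(filters$B))
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_filters
#' @export
read_filters <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  A <- lag_list_to_array(doc$A, doc$n_a, doc$d_y, doc$d_y)
  B <- lag_list_to_array(doc$B, doc$n_b, doc$d_y, doc$d_x)
  varx_filters(A = if (doc$n_a > 0) A else NULL,
               B = if (doc$n_b > 0) B else NULL,
               d_y = doc$d_y, d_x = doc$d_x,
               names_y = unlist(doc$names_y),
               names_x = if (doc$d_x > 0) unlist(doc$names_x) else NULL)
}

lag_array_to_list <- function(a) {
  if (dim(a)[1] == 0) return(list())
  lapply(seq_len(dim(a)[1]), function(l) {
    m <- a[l, , , drop = FALSE]
    dim(m) <- dim(a)[2:3]
    lapply(seq_len(nrow(m)), function(i) m[i, ])
  })
}

lag_list_to_array <- function(lst, n_lag, d1, d2) {
  a <- array(0, c(n_lag, d1, d2))
  for (l in seq_len(n_lag))
    for (i in seq_len(d1))
      a[l, i, ] <- unlist(lst[[l]][[i]])
  a
}
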