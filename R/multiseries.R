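#' Multivariate time series with endogenous/exogenous roles
#'
#' Light container pairing an endogenous matrix `Y` `[T, d_y]` with an
#' optional exogenous matrix `X` `[T, d_x]`, a missing-value mask (any
#' non-finite entry counts as missing), and segment boundaries marking
#' independent recording segments.  A fitted sample's lagged history is
#' never allowed to straddle a segment boundary.
#'
#' @param Y numeric matrix or data frame, rows = time samples; may contain
#'   `NA`/`NaN`.
#' @param X optional exogenous matrix with the same number of rows.
#' @param segment_starts sorted integer vector of first sample indices of
#'   each independent segment; must start at 1 and be strictly increasing.
#' @param names_y,names_x optional variable names (default from columns).
#' @return Object of class `multi_series` with elements `Y`, `X`, `T`,
#'   `d_y`, `d_x`, `names_y`, `names_x`, `segment_starts`.
#' @export
multi_series <- function(Y, X = NULL, segment_starts = 1L,
                         names_y = NULL, names_x = NULL) {
  Y <- as.matrix(Y); storage.mode(Y) <- "double"
  n_time <- nrow(Y)
  if (!is.null(X)) {
    X <- as.matrix(X); storage.mode(X) <- "double"
    if (nrow(X) != n_time)
      stop("Y and X must have the same number of rows (",
           n_time, " vs ", nrow(X), ")")
  } else {
    X <- matrix(numeric(0), n_time, 0)
  }
  segment_starts <- as.integer(segment_starts)
  if (length(segment_starts) == 0 || segment_starts[1] != 1L)
    stop("segment_starts must begin with 1 (the first sample)")
  if (any(diff(segment_starts) <= 0))
    stop("segment_starts must be strictly increasing")
  if (any(segment_starts > n_time))
    stop("segment start beyond the end of the series")
  names_y <- names_y %||% colnames(Y) %||% paste0("y", seq_len(ncol(Y)))
  names_x <- names_x %||%
    (if (ncol(X) > 0) colnames(X) %||% paste0("x", seq_len(ncol(X)))
     else character())
  colnames(Y) <- names_y
  if (ncol(X) > 0) colnames(X) <- names_x
  structure(list(Y = Y, X = X, T = n_time,
                 d_y = ncol(Y), d_x = ncol(X),
                 names_y = names_y, names_x = names_x,
                 segment_starts = segment_starts),
            class = "multi_series")
}

#' @export
print.multi_series <- function(x, ...) {
  cat("multi_series: T =", x$T, ", d_y =", x$d_y, ", d_x =", x$d_x,
      ",", length(x$segment_starts), "segment(s)\n")
  n_miss <- sum(!is.finite(x$Y)) + sum(!is.finite(x$X))
  if (n_miss > 0) cat("  missing values:", n_miss, "\n")
  invisible(x)
}

as_multi_series <- function(y, x = NULL, segment_starts = 1L) {
  if (inherits(y, "multi_series")) return(y)
  multi_series(y, x, segment_starts = segment_starts)
}

segment_index <- function(ms) {
  # segment id per sample
  rep(seq_along(ms$segment_starts),
      diff(c(ms$segment_starts, ms$T + 1L)))
}
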