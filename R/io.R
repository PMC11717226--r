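#' Read a delimited time-series file into a multi_series
#'
#' Reads comma- (`.csv`) or tab- (`.tsv`, `.txt`) delimited text with a
#' mandatory header row, one row per time sample.  The configuration names
#' which columns are endogenous and exogenous; column order follows the
#' configuration, not the file.  `NA`, `NaN`, `nan` and empty fields are
#' all treated as missing.
#'
#' @param path file path.
#' @param config list with `endogenous` (character, required), `exogenous`
#'   (character, optional) and `segments` (integer start indices,
#'   optional); typically from [read_run_config()].
#' @return A [multi_series].
#' @export
read_timeseries <- function(path, config) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(config$endogenous) || length(config$endogenous) == 0)
    stop("config must name at least one endogenous variable")
  sep <- delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("NA", "NaN", "nan", ""),
                          check.names = FALSE, colClasses = "numeric")
  wanted <- c(config$endogenous, config$exogenous)
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols) > 0)
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         "; available columns: ", paste(names(df), collapse = ", "))
  Y <- as.matrix(df[config$endogenous])
  X <- if (length(config$exogenous) > 0) as.matrix(df[config$exogenous])
  multi_series(Y, X,
               segment_starts = config$segments %||% 1L,
               names_y = config$endogenous,
               names_x = config$exogenous)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Write a multi_series (or matrix) as delimited text
#'
#' Header row of variable names, one row per sample, missing values
#' written as `NaN`.  Values are written with enough digits to round-trip
#' doubles exactly.
#'
#' @param data a [multi_series], or a numeric matrix/data frame.
#' @param path output path; the delimiter follows the extension
#'   (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  m <- if (inherits(data, "multi_series")) {
    if (data$d_x > 0) cbind(data$Y, data$X) else data$Y
  } else as.matrix(data)
  sep <- delim_for(path)
  chr <- apply(m, 2, function(v)
    ifelse(is.finite(v), sprintf("%.17g", v), "NaN"))
  chr <- matrix(chr, nrow = nrow(m))
  lines <- c(paste(colnames(m), collapse = sep),
             apply(chr, 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' Keys: `endogenous`, `exogenous`, `n_a`, `n_b`, `gamma`, `n_basis`,
#' `segments`, `alpha`, `seed`.  The format is chosen from the extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml: ", path)
}

#' Write a Granger-analysis result bundle
#'
#' Writes a directory of plain-text outputs: `summary.json` (resolved
#' configuration, seed, sample counts, innovation variances),
#' `filters.json` (the fitted filters, see [write_filters()]), the test
#' matrices `A_pval.csv`, `B_pval.csv`, `A_R2.csv`, `B_R2.csv`,
#' `A_deviance.csv`, `B_deviance.csv` with variable-name headers, an
#' `edges.csv` edge list (see [granger_edges()], optionally thresholded at
#' `alpha`), and `log.txt`.
#'
#' @param fit a [varx()] result.
#' @param dir output directory (created if needed).
#' @param alpha optional threshold applied to `edges.csv` only.
#' @param seed seed to record in the summary (reproducibility contract).
#' @param log_lines character vector appended to `log.txt`.
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(fit, dir, alpha = NULL, seed = NULL,
                                log_lines = character()) {
  stopifnot(inherits(fit, "varx_granger"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    config = fit$config, seed = seed, alpha = alpha,
    T_used = fit$T_used, T_effective = fit$T_effective, N = fit$N,
    sigma2 = as.list(stats::setNames(fit$sigma2, fit$ne$names_y)))
  writeLines(jsonlite::toJSON(summary, digits = NA, auto_unbox = TRUE,
                              null = "null", pretty = TRUE),
             file.path(dir, "summary.json"))
  write_filters(fit$filters, file.path(dir, "filters.json"))
  wm <- function(m, name) if (!is.null(m))
    utils::write.csv(m, file.path(dir, name), row.names = TRUE)
  wm(fit$A_pval, "A_pval.csv");         wm(fit$B_pval, "B_pval.csv")
  wm(fit$A_R2, "A_R2.csv");             wm(fit$B_R2, "B_R2.csv")
  wm(fit$A_deviance, "A_deviance.csv"); wm(fit$B_deviance, "B_deviance.csv")
  utils::write.csv(granger_edges(fit, alpha = alpha),
                   file.path(dir, "edges.csv"), row.names = FALSE)
  writeLines(c(log_lines,
               paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      " bundle written (seed=",
                      seed %||% "NULL", ")")),
             file.path(dir, "log.txt"))
  invisible(dir)
}

#' Write a study report as JSON plus a summary table
#'
#' `report.json` carries the full report (rates, standard errors, labels,
#' configuration, seed); `summary.csv` is a flat human-readable table of
#' named rates and their binomial standard errors.
#'
#' @param report a `study_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- unclass(report)
  if (!is.null(ser$recovery)) {
    ser$recovery$fit <- NULL          # fitted object is not serializable
    ser$recovery$truth <- NULL
  }
  writeLines(jsonlite::toJSON(ser, digits = NA, auto_unbox = TRUE,
                              null = "null", pretty = TRUE, force = TRUE),
             file.path(dir, "report.json"))
  rows <- list()
  for (nm in names(report$rates)) {
    r <- report$rates[[nm]]; s <- report$se[[nm]]
    if (length(r) == 0) next
    idx <- if (is.matrix(r))
      paste0("[", row(r), ",", col(r), "]") else ""
    rows[[nm]] <- data.frame(rate = nm, channel = as.vector(idx),
                             value = as.vector(r), se = as.vector(s))
  }
  if (!is.null(report$recovery))
    rows$recovery <- data.frame(
      rate = c("correlation", "max_abs_error"), channel = "",
      value = c(report$recovery$correlation,
                report$recovery$max_abs_error),
      se = NA_real_)
  utils::write.csv(do.call(rbind, rows), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}
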