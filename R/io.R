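#' Read a per-cell measurement table from CSV/TSV
#'
#' Reads a delimited file with one row per cell and required header columns
#' \code{method, measurand, replicate, input_level, value}. The delimiter
#' (comma or tab) is sniffed from the header line. Values must be numeric
#' and present; the first offending row is named in the error. Input levels
#' are ordered numerically when parseable, otherwise by first appearance
#' with a warning.
#'
#' @param path path to the file.
#' @return A validated data frame (one row per cell).
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("cell table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  suppressWarnings(v <- as.numeric(df$value))
  bad <- which(!is.finite(v))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric or missing value '%s' in column 'value' at data row %d",
                 df$value[bad[1L]], bad[1L]), call. = FALSE)
  }
  df$value <- v
  validate_cell_table(df)
}

#' Write a per-cell measurement table as CSV
#'
#' Inverse of \code{\link{read_cell_table}}; record count and values
#' round-trip exactly (values are written with full precision).
#'
#' @param table validated cell table.
#' @param path output path.
#' @export
write_cell_table <- function(table, path) {
  table <- validate_cell_table(table)
  table$value <- formatC(table$value, digits = 17, format = "g")
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transition matrix from CSV
#'
#' Expects a rectangular numeric CSV with columns as input levels and rows
#' as output bins. Columns already summing to 1 (within 1e-6) are accepted
#' as probabilities; otherwise the file is treated as raw counts and
#' normalized per column, with a notice. Negative entries and all-zero
#' columns are errors.
#'
#' @param path path to the CSV file.
#' @param header whether the file has a header row (default \code{FALSE}).
#' @return A validated K x J transition matrix.
#' @export
read_transition_matrix <- function(path, header = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  M <- as.matrix(utils::read.csv(path, header = header))
  if (!is.numeric(M)) stop("transition matrix file contains non-numeric entries", call. = FALSE)
  if (any(!is.finite(M))) stop("transition matrix file contains missing entries", call. = FALSE)
  if (any(M < 0)) stop("transition matrix has negative entries", call. = FALSE)
  cs <- colSums(M)
  if (any(cs == 0)) {
    stop(sprintf("transition matrix column %d is all zeros", which(cs == 0)[1L]), call. = FALSE)
  }
  if (any(abs(cs - 1) > 1e-6)) {
    message("columns do not sum to 1; treating the file as raw counts and normalizing")
    M <- sweep(M, 2L, cs, `/`)
  }
  # renormalize exactly so downstream validation at 1e-12 passes
  M <- sweep(M, 2L, colSums(M), `/`)
  dimnames(M) <- NULL
  validate_transition_matrix(M)
  M
}

#' Write a study report to JSON (with a text rendering)
#'
#' Serializes every method summary at full float precision, together with
#' the per-measurand rankings, any bin sweeps, and the configuration echo.
#' A human-readable aligned table (capacities rounded to 2 decimals for
#' display) is included under \code{$text} and also written next to the
#' JSON when \code{text_path} is given.
#'
#' @param report a \code{\link{run_study}} result.
#' @param path output JSON path.
#' @param text_path optional path for the plain-text table.
#' @export
write_report <- function(report, path, text_path = NULL) {
  if (!inherits(report, "study_report")) stop("not a study_report", call. = FALSE)
  if (length(report$summaries) == 0L) stop("report contains no method summaries", call. = FALSE)
  payload <- list(
    summaries = lapply(report$summaries, function(s) {
      list(method = s$method, measurand = s$measurand, n_bins = s$n_bins,
           replicate_capacities = as.list(s$replicate_capacities),
           mean_bits = s$mean_bits,
           sd_bits = if (is.na(s$sd_bits)) NULL else s$sd_bits,
           bin_sweep = if (is.null(s$sweep)) NULL else s$sweep$table)
    }),
    rankings = report$rankings,
    config = report$config,
    text = format_report_text(report)
  )
  # I(17) significant digits: doubles round-trip the JSON exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       dataframe = "rows")
  if (!is.null(text_path)) writeLines(format_report_text(report), text_path)
  invisible(path)
}
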