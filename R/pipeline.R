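REQUIRED_COLUMNS <- c("method", "measurand", "replicate", "input_level", "value")

# Input levels are categorical to the capacity math; numeric parsing is
# used only to put the stimulus ladder in order. Non-numeric labels fall
# back to first-appearance order with a warning.
order_input_levels <- function(levels) {
  u <- unique(as.character(levels))
  num <- suppressWarnings(as.numeric(u))
  if (!any(is.na(num))) {
    u[order(num)]
  } else {
    warning("input levels are not numeric; using first-appearance order", call. = FALSE)
    u
  }
}

validate_cell_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("cell table must be a non-empty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(table))
  if (length(missing_cols) > 0L) {
    stop(sprintf("cell table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  v <- table$value
  if (!is.numeric(v)) {
    suppressWarnings(v <- as.numeric(as.character(v)))
  }
  bad <- which(!is.finite(v))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric or missing value in column 'value' at row %d", bad[1L]),
         call. = FALSE)
  }
  table$value <- v
  table
}

# Split one method's rows into per-replicate sample sets with a common,
# ordered set of input levels.
table_to_sample_sets <- function(table) {
  level_order <- order_input_levels(table$input_level)
  reps <- unique(as.character(table$replicate))
  sets <- lapply(reps, function(r) {
    sub <- table[as.character(table$replicate) == r, , drop = FALSE]
    levels_here <- unique(as.character(sub$input_level))
    if (!setequal(levels_here, level_order)) {
      stop(sprintf("replicate '%s' does not have the same input levels as the others", r),
           call. = FALSE)
    }
    if (length(unique(sub$value)) < 2L) {
      stop(sprintf("replicate '%s' has fewer than 2 distinct values", r), call. = FALSE)
    }
    vals <- lapply(level_order, function(l) sub$value[as.character(sub$input_level) == l])
    names(vals) <- level_order
    sample_set(vals)
  })
  names(sets) <- reps
  sets
}

summarize_capacities <- function(caps) {
  list(mean_bits = mean(caps),
       sd_bits = if (length(caps) >= 2L) stats::sd(caps) else NA_real_)
}

#' Capacity summary for one measurement method
#'
#' Runs the full capacity pipeline for a single (method, measurand) slice
#' of a cell table: bin selection across the method's replicates, a
#' Blahut-Arimoto capacity per replicate at the selected bin count, and
#' aggregation to mean plus sample standard deviation (n - 1 denominator;
#' reported as \code{NA}, not zero, for a single replicate). Replicates are
#' never pooled into one sample: capacity is computed per replicate and
#' then aggregated.
#'
#' @param table data frame with columns \code{method, measurand, replicate,
#'   input_level, value}, one row per cell, restricted to one method and
#'   measurand.
#' @param eps Blahut-Arimoto convergence threshold in bits.
#' @param threshold_bits bin-doubling plateau threshold in bits.
#' @param bins \code{"auto"} for the doubling rule, or a fixed integer bin
#'   count.
#' @return An object of class \code{"method_capacity_summary"} with the
#'   method and measurand labels, \code{n_bins}, per-replicate capacities,
#'   \code{mean_bits}, \code{sd_bits}, and (for \code{bins = "auto"}) the
#'   full bin sweep.
#' @export
method_capacity <- function(table, eps = 1e-4, threshold_bits = 0.1, bins = "auto") {
  table <- validate_cell_table(table)
  if (length(unique(as.character(table$method))) != 1L) {
    stop("method_capacity expects a table restricted to one method", call. = FALSE)
  }
  if (length(unique(as.character(table$measurand))) != 1L) {
    stop("method_capacity expects a table restricted to one measurand", call. = FALSE)
  }
  if (length(unique(as.character(table$input_level))) < 2L) {
    stop("need at least 2 input levels for capacity analysis", call. = FALSE)
  }
  sets <- table_to_sample_sets(table)

  if (identical(bins, "auto")) {
    sweep <- select_bin_count(sets, eps = eps, threshold_bits = threshold_bits)
    sel <- sweep$selected_n_bins
    caps <- sweep$replicate_capacities[, match(sel, sweep$table$n_bins)]
    names(caps) <- names(sets)
  } else {
    if (!is.numeric(bins) || length(bins) != 1L || bins < 2L) {
      stop("bins must be \"auto\" or an integer >= 2", call. = FALSE)
    }
    sweep <- NULL
    sel <- as.integer(bins)
    caps <- replicate_capacities(sets, sel, eps = eps)
    names(caps) <- names(sets)
  }
  agg <- summarize_capacities(caps)
  structure(list(method = as.character(table$method[1L]),
                 measurand = as.character(table$measurand[1L]),
                 n_bins = sel,
                 replicate_capacities = caps,
                 mean_bits = agg$mean_bits,
                 sd_bits = agg$sd_bits,
                 sweep = sweep),
            class = "method_capacity_summary")
}

#' @export
print.method_capacity_summary <- function(x, ...) {
  cat(format_summary_line(x), "\n")
  invisible(x)
}

format_summary_line <- function(s) {
  sd_txt <- if (is.na(s$sd_bits)) "NA" else sprintf("%.2f", s$sd_bits)
  sprintf("%-28s %-8s N_B=%-4d %.2f ± %s bits",
          s$method, s$measurand, s$n_bins, s$mean_bits, sd_txt)
}

#' Rank measurement methods within one measurand
#'
#' Sorts method summaries by descending mean capacity. A higher measured
#' channel capacity indicates a higher-quality measurement, but only
#' methods measuring the same measurand share a biological channel, so
#' mixing measurands is refused: capacities of, say, an RNA method and a
#' protein method are not comparable.
#'
#' @param summaries list of \code{\link{method_capacity}} results.
#' @param measurand the measurand label all summaries must share.
#' @return data frame with columns \code{rank, method, measurand,
#'   mean_bits, sd_bits, n_bins, tie}; ties on mean capacity are broken by
#'   method label and flagged.
#' @export
compare_methods <- function(summaries, measurand) {
  if (length(summaries) < 1L) stop("no summaries to rank", call. = FALSE)
  meas <- vapply(summaries, function(s) s$measurand, character(1))
  if (!all(meas == measurand)) {
    stop(sprintf(paste("cannot rank methods across measurands: capacities are only",
                       "comparable between measurements of the same measurand",
                       "(requested '%s', found: %s)"),
                 measurand, paste(unique(meas), collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(
    method = vapply(summaries, function(s) s$method, character(1)),
    measurand = meas,
    mean_bits = vapply(summaries, function(s) s$mean_bits, numeric(1)),
    sd_bits = vapply(summaries, function(s) s$sd_bits, numeric(1)),
    n_bins = vapply(summaries, function(s) s$n_bins, integer(1)),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$mean_bits, df$method), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$tie <- duplicated(df$mean_bits) | duplicated(df$mean_bits, fromLast = TRUE)
  rownames(df) <- NULL
  df[, c("rank", "method", "measurand", "mean_bits", "sd_bits", "n_bins", "tie")]
}

#' Run the full capacity study over a cell table
#'
#' Groups the table by (method, measurand), computes a capacity summary for
#' each group, and ranks methods within each measurand. Deterministic:
#' identical inputs and configuration reproduce the report exactly.
#'
#' @inheritParams method_capacity
#' @return An object of class \code{"study_report"}: the list of
#'   \code{\link{method_capacity}} summaries, one ranking data frame per
#'   measurand, and an echo of the configuration used.
#' @export
run_study <- function(table, eps = 1e-4, threshold_bits = 0.1, bins = "auto") {
  table <- validate_cell_table(table)
  groups <- unique(data.frame(method = as.character(table$method),
                              measurand = as.character(table$measurand),
                              stringsAsFactors = FALSE))
  summaries <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sub <- table[as.character(table$method) == groups$method[i] &
                   as.character(table$measurand) == groups$measurand[i], , drop = FALSE]
    message(sprintf("Computing capacity: method=%s measurand=%s (%d cells)",
                    groups$method[i], groups$measurand[i], nrow(sub)))
    summaries[[i]] <- method_capacity(sub, eps = eps,
                                      threshold_bits = threshold_bits, bins = bins)
  }
  names(summaries) <- paste(groups$method, groups$measurand, sep = "/")
  rankings <- lapply(unique(groups$measurand), function(m) {
    compare_methods(summaries[groups$measurand == m], m)
  })
  names(rankings) <- unique(groups$measurand)
  structure(list(summaries = summaries,
                 rankings = rankings,
                 config = list(eps = eps, threshold_bits = threshold_bits, bins = bins)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(format_report_text(x))
  invisible(x)
}

# Human-readable table: one row per method, "mean +/- SD bits" at 2 d.p.
# (display only; full precision is kept in the object and the JSON).
format_report_text <- function(report) {
  lines <- c("Method                       Measurand  N_B  Channel capacity")
  for (m in names(report$rankings)) {
    r <- report$rankings[[m]]
    for (i in seq_len(nrow(r))) {
      sd_txt <- if (is.na(r$sd_bits[i])) "NA" else sprintf("%.2f", r$sd_bits[i])
      lines <- c(lines, sprintf("%-28s %-10s %-4d %.2f ± %s bits",
                                r$method[i], r$measurand[i], r$n_bins[i],
                                r$mean_bits[i], sd_txt))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
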