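#' Per-level sample sets
#'
#' A sample set holds the per-cell measured values for one biological
#' replicate, grouped by stimulus (input) level in ladder order. It is the
#' unit the discretization operations work on.
#'
#' @param values_by_input named list of numeric vectors, one per input
#'   level, in increasing stimulus order. Every level needs at least one
#'   cell; values must be finite (missing values are rejected rather than
#'   dropped, since silent drops would bias the per-level cell counts).
#' @return An object of class \code{"sample_set"}.
#' @export
sample_set <- function(values_by_input) {
  if (!is.list(values_by_input) || length(values_by_input) < 1L) {
    stop("values_by_input must be a non-empty list of numeric vectors", call. = FALSE)
  }
  for (j in seq_along(values_by_input)) {
    v <- values_by_input[[j]]
    if (!is.numeric(v) || length(v) < 1L) {
      stop(sprintf("input level %d has no cells", j), call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop(sprintf("input level %d contains missing or non-finite values", j), call. = FALSE)
    }
  }
  if (is.null(names(values_by_input))) {
    names(values_by_input) <- as.character(seq_along(values_by_input))
  }
  structure(list(values_by_input = values_by_input,
                 n_cells = vapply(values_by_input, length, integer(1))),
            class = "sample_set")
}

pooled_values <- function(s) unlist(s$values_by_input, use.names = FALSE)

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("Sample set: %d input levels, %d cells total\n",
              length(x$values_by_input), sum(x$n_cells)))
  invisible(x)
}

#' Freedman-Diaconis bin width
#'
#' Returns \code{2 * IQR(values) / n^(1/3)} with the interquartile range
#' computed by linear interpolation between order statistics
#' (\code{stats::quantile} type 7). When the IQR is zero but the values are
#' not all identical, falls back to \code{2 * (max - min) / n^(1/3)}.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return Positive bin width on the scale of \code{values}.
#' @export
freedman_diaconis_width <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("need at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values contain missing or non-finite entries", call. = FALSE)
  rng <- diff(range(values))
  if (rng == 0) stop("all values are identical; bin width is undefined", call. = FALSE)
  n <- length(values)
  iqr <- unname(diff(stats::quantile(values, c(0.25, 0.75), type = 7)))
  if (iqr > 0) 2 * iqr / n^(1 / 3) else 2 * rng / n^(1 / 3)
}

#' Equal-width bin edges spanning the observed range
#'
#' Edges run from the minimum to the maximum of the supplied values (pooled
#' across input levels), divided into \code{n_bins} equal-width bins.
#' Interior bins are half-open \code{[low, high)}; the rightmost bin is
#' closed so the maximum value is counted.
#'
#' @param values numeric vector (pooled across all input levels).
#' @param n_bins number of bins, at least 2.
#' @return An object of class \code{"binning_spec"} with fields
#'   \code{n_bins}, \code{low_edge}, \code{high_edge} and \code{edges}
#'   (length \code{n_bins + 1}).
#' @export
make_edges <- function(values, n_bins) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2L || n_bins != round(n_bins)) {
    stop("n_bins must be an integer >= 2", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values contain missing or non-finite entries", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) stop("degenerate range: all values identical", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), low_edge = lo, high_edge = hi,
                 edges = seq(lo, hi, length.out = n_bins + 1)),
            class = "binning_spec")
}

#' Empirical transition matrix from binned per-cell measurements
#'
#' Counts, for each input level j, the cells whose measured value falls in
#' each bin and normalizes by the level's cell count:
#' \eqn{Q_{k|j} = n_{k|j} / N_j}. Columns therefore sum to 1 exactly.
#'
#' @param sample a \code{\link{sample_set}}.
#' @param spec a \code{\link{binning_spec}}; every value must lie within
#'   its range.
#' @return K x J transition matrix (K = number of bins, J = number of input
#'   levels), suitable for \code{\link{blahut_arimoto}}.
#' @export
empirical_transition_matrix <- function(sample, spec) {
  stopifnot(inherits(sample, "sample_set"), inherits(spec, "binning_spec"))
  J <- length(sample$values_by_input)
  K <- spec$n_bins
  Q <- matrix(0, nrow = K, ncol = J,
              dimnames = list(NULL, names(sample$values_by_input)))
  for (j in seq_len(J)) {
    v <- sample$values_by_input[[j]]
    out <- v < spec$low_edge | v > spec$high_edge
    if (any(out)) {
      stop(sprintf("input level %s has value %.6g outside the bin range [%.6g, %.6g]",
                   names(sample$values_by_input)[j], v[which(out)[1L]],
                   spec$low_edge, spec$high_edge), call. = FALSE)
    }
    idx <- findInterval(v, spec$edges, rightmost.closed = TRUE)
    counts <- tabulate(idx, nbins = K)
    Q[, j] <- counts / length(v)
  }
  Q
}

#' Initial bin count from the Freedman-Diaconis seed
#'
#' For each replicate, the Freedman-Diaconis width is computed on the
#' values pooled across all input levels; the initial bin width is 10 times
#' the mean of those widths, and the bin count is the overall pooled range
#' divided by that width, rounded up (minimum 2).
#'
#' @param replicate_samples list of \code{\link{sample_set}} objects, one
#'   per biological replicate.
#' @param width_factor multiplier applied to the mean recommended width
#'   (default 10).
#' @return Integer bin count.
#' @export
initial_bin_count <- function(replicate_samples, width_factor = 10) {
  if (!is.list(replicate_samples) || length(replicate_samples) < 1L) {
    stop("need at least one replicate", call. = FALSE)
  }
  widths <- vapply(replicate_samples,
                   function(s) freedman_diaconis_width(pooled_values(s)),
                   numeric(1))
  init_width <- width_factor * mean(widths)
  all_vals <- unlist(lapply(replicate_samples, pooled_values), use.names = FALSE)
  rng <- diff(range(all_vals))
  max(2L, as.integer(ceiling(rng / init_width)))
}

# Capacity of each replicate at a fixed bin count. Edges are computed per
# replicate from its own pooled range; the bin count is shared across
# replicates of a method.
replicate_capacities <- function(replicate_samples, n_bins, eps = 1e-4, ...) {
  vapply(replicate_samples, function(s) {
    spec <- make_edges(pooled_values(s), n_bins)
    Q <- empirical_transition_matrix(s, spec)
    blahut_arimoto(Q, eps = eps, ...)$capacity_bits
  }, numeric(1))
}

# cap_matrix is replicates x bin-counts
new_bin_sweep <- function(bin_counts, cap_matrix, selected, flagged) {
  if (is.null(rownames(cap_matrix))) {
    rownames(cap_matrix) <- paste0("rep", seq_len(nrow(cap_matrix)))
  }
  means <- colMeans(cap_matrix)
  tab <- data.frame(n_bins = bin_counts, t(cap_matrix), mean_bits = means,
                    row.names = NULL, check.names = FALSE)
  structure(list(table = tab,
                 replicate_capacities = cap_matrix,
                 selected_n_bins = selected,
                 flagged = flagged),
            class = "bin_sweep")
}

#' @export
print.bin_sweep <- function(x, ...) {
  cat("Capacity vs. number of bins:\n")
  print(round(x$table, 4))
  if (!is.na(x$selected_n_bins)) {
    cat(sprintf("Selected N_B = %d%s\n", x$selected_n_bins,
                if (isTRUE(x$flagged)) " (doubling stopped by cell-count safeguard)" else ""))
  }
  invisible(x)
}

# The doubling decision rule, factored out so it can be exercised directly:
# capacity_fn(n) returns the per-replicate capacities at n bins. Doubling
# continues while the mean capacity rises by more than threshold_bits; the
# previous (smaller) bin count is then selected. max_bins caps the search.
run_doubling_rule <- function(capacity_fn, n0, threshold_bits, max_bins = Inf) {
  n <- as.integer(n0)
  caps <- list(capacity_fn(n))
  ns <- n
  flagged <- FALSE
  repeat {
    if (2L * n > max_bins) {
      flagged <- TRUE
      break
    }
    nxt <- capacity_fn(2L * n)
    ns <- c(ns, 2L * n)
    caps <- c(caps, list(nxt))
    if (mean(nxt) - mean(caps[[length(caps) - 1L]]) <= threshold_bits) break
    n <- 2L * n
  }
  cap_matrix <- matrix(unlist(caps), nrow = length(ns), byrow = TRUE)
  # selected = the last bin count whose doubling failed to add threshold
  # bits (i.e. the next-to-last row), or the last row if the safeguard hit
  selected <- if (flagged) ns[length(ns)] else ns[max(1L, length(ns) - 1L)]
  new_bin_sweep(ns, t(cap_matrix), selected, flagged)
}

#' Choose the number of bins by capacity-stability doubling
#'
#' Starting from the Freedman-Diaconis-seeded count
#' (\code{\link{initial_bin_count}}), the bin width is halved (bin count
#' doubled) while the mean channel capacity across replicates rises by more
#' than \code{threshold_bits}; when a doubling adds no more than that, the
#' previous (smaller) bin count is selected and its per-replicate
#' capacities are reported. Too few bins underestimate capacity and too
#' many overestimate it, so the rule looks for the plateau between the two
#' regimes. As a safeguard the search stops, with a flag, if the bin count
#' would exceed the cell count of the smallest replicate.
#'
#' @param replicate_samples list of \code{\link{sample_set}} objects.
#' @param eps Blahut-Arimoto convergence threshold in bits.
#' @param threshold_bits plateau threshold in bits (default 0.1).
#' @param width_factor initial-width multiplier (default 10), see
#'   \code{\link{initial_bin_count}}.
#' @return An object of class \code{"bin_sweep"}: the sweep table
#'   (\code{n_bins}, per-replicate capacities, \code{mean_bits}), the
#'   selected bin count, and a safeguard flag.
#' @export
select_bin_count <- function(replicate_samples, eps = 1e-4, threshold_bits = 0.1,
                             width_factor = 10) {
  if (!is.numeric(threshold_bits) || threshold_bits <= 0) {
    stop("threshold_bits must be positive", call. = FALSE)
  }
  n0 <- initial_bin_count(replicate_samples, width_factor = width_factor)
  max_bins <- min(vapply(replicate_samples, function(s) sum(s$n_cells), numeric(1)))
  run_doubling_rule(function(n) replicate_capacities(replicate_samples, n, eps = eps),
                    n0, threshold_bits, max_bins = max_bins)
}

#' Capacity at a user-chosen ladder of bin counts
#'
#' Computes per-replicate and mean capacities at every requested bin count,
#' for diagnostic tables or capacity-vs-bins plots. Deterministic: the same
#' inputs always produce the same sweep.
#'
#' @param replicate_samples list of \code{\link{sample_set}} objects.
#' @param bin_counts non-empty vector of bin counts.
#' @param eps Blahut-Arimoto convergence threshold in bits.
#' @return A \code{"bin_sweep"} object (no selection is made;
#'   \code{selected_n_bins} is \code{NA}).
#' @export
capacity_bin_sweep <- function(replicate_samples, bin_counts, eps = 1e-4) {
  if (length(bin_counts) < 1L) stop("bin_counts must be non-empty", call. = FALSE)
  caps <- t(vapply(as.integer(bin_counts),
                   function(n) replicate_capacities(replicate_samples, n, eps = eps),
                   numeric(length(replicate_samples))))
  if (length(replicate_samples) == 1L) caps <- matrix(caps, ncol = 1L)
  new_bin_sweep(as.integer(bin_counts), t(caps), NA_integer_, FALSE)
}
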