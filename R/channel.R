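# Internal validators for the two probability objects used throughout:
# an input distribution p (length J) and a transition matrix Q (K x J,
# columns are conditional output distributions).

validate_input_distribution <- function(p, tol = 1e-12) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("input distribution must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(p))) stop("input distribution has non-finite entries", call. = FALSE)
  if (any(p < 0)) stop("input distribution has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("input distribution sums to %.15g, not 1", sum(p)), call. = FALSE)
  }
  invisible(p)
}

validate_transition_matrix <- function(Q, tol = 1e-12) {
  if (!is.matrix(Q) || !is.numeric(Q)) {
    stop("transition matrix must be a numeric matrix", call. = FALSE)
  }
  if (nrow(Q) < 1L || ncol(Q) < 1L) stop("transition matrix must be at least 1 x 1", call. = FALSE)
  if (any(!is.finite(Q))) stop("transition matrix has non-finite entries", call. = FALSE)
  if (any(Q < 0)) stop("transition matrix has negative entries", call. = FALSE)
  cs <- colSums(Q)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad) > 0L) {
    stop(sprintf("transition matrix column %d sums to %.15g, not 1", bad[1L], cs[bad[1L]]),
         call. = FALSE)
  }
  invisible(Q)
}

check_dims <- function(p, Q) {
  if (length(p) != ncol(Q)) {
    stop(sprintf("length of input distribution (%d) does not match number of channel inputs (%d)",
                 length(p), ncol(Q)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mutual information of a discrete memoryless channel
#'
#' Computes \eqn{I(p, Q) = \sum_j \sum_k p_j Q_{k|j} \log_2(Q_{k|j} / q_k)}
#' with \eqn{q_k = \sum_j p_j Q_{k|j}}, in bits. Terms with
#' \eqn{Q_{k|j} = 0} or \eqn{p_j = 0} contribute zero (the usual
#' \eqn{0 \log 0 = 0} convention), which is required when \code{Q} is an
#' empirical histogram with empty bins.
#'
#' @param p numeric vector of input probabilities, one per input level
#'   (non-negative, summing to 1).
#' @param Q numeric matrix with one column per input level; column \code{j}
#'   is the conditional distribution of the output given input \code{j}
#'   (entries non-negative, each column summing to 1).
#' @return Mutual information in bits (non-negative scalar).
#' @examples
#' mutual_information(c(0.5, 0.5), diag(2))        # 1 bit
#' mutual_information(rep(1/8, 8), diag(8))        # 3 bits
#' @export
mutual_information <- function(p, Q) {
  validate_input_distribution(p)
  validate_transition_matrix(Q)
  check_dims(p, Q)
  q <- as.vector(Q %*% p)
  # ratio Q_{k|j} / q_k; where Q is 0 the term vanishes regardless of q,
  # and columns with p_j = 0 contribute nothing (0 log 0 = 0 throughout)
  lr <- Q
  pos <- Q > 0
  lr[pos] <- log2(Q[pos] / q[row(Q)[pos]])
  lr[!pos] <- 0
  per_input <- colSums(lr * Q)
  val <- sum(per_input[p > 0] * p[p > 0])
  max(val, 0)
}

#' Bayes-inverted (reverse) transition matrix
#'
#' For a fixed input distribution \code{p}, the reverse channel
#' \eqn{P^*_{j|k} = p_j Q_{k|j} / \sum_{j'} p_{j'} Q_{k|j'}} maximizes the
#' auxiliary functional in the alternating maximization that underlies the
#' Blahut-Arimoto iteration. Output bins with zero marginal probability get
#' a uniform column: any value is correct there because those terms are
#' annihilated downstream, and uniform avoids NaN propagation.
#'
#' @inheritParams mutual_information
#' @return A K x J matrix; entry (k, j) is the posterior probability of
#'   input j given output bin k.
#' @export
reverse_channel <- function(p, Q) {
  validate_input_distribution(p)
  validate_transition_matrix(Q)
  check_dims(p, Q)
  joint <- sweep(Q, 2L, p, `*`)      # K x J, entry p_j Q_{k|j}
  q <- rowSums(joint)
  P <- joint
  nz <- q > 0
  P[nz, ] <- joint[nz, , drop = FALSE] / q[nz]
  if (any(!nz)) P[!nz, ] <- 1 / ncol(Q)
  P
}

#' Capacity-achieving input-distribution update
#'
#' Given a reverse channel \code{P} and forward channel \code{Q}, returns
#' the input distribution \eqn{p_j \propto 2^{\sum_k Q_{k|j} \log_2 P_{j|k}}}
#' (normalized). Terms with \eqn{Q_{k|j} = 0} are skipped; if
#' \eqn{P_{j|k} = 0} while \eqn{Q_{k|j} > 0} the exponent is \eqn{-\infty}
#' and that input gets probability zero.
#'
#' @param P K x J reverse transition matrix (entry (k, j) is P_{j|k}).
#' @param Q K x J forward transition matrix.
#' @return numeric input distribution of length J.
#' @export
input_update <- function(P, Q) {
  validate_transition_matrix(Q)
  if (!is.matrix(P) || any(dim(P) != dim(Q))) {
    stop("reverse matrix dimensions do not match the forward channel", call. = FALSE)
  }
  if (any(P < 0)) stop("reverse matrix has negative entries", call. = FALSE)
  J <- ncol(Q)
  expo <- numeric(J)
  for (j in seq_len(J)) {
    qj <- Q[, j]
    pj <- P[, j]
    act <- qj > 0
    if (any(pj[act] == 0)) {
      expo[j] <- -Inf
    } else {
      expo[j] <- sum(qj[act] * log2(pj[act]))
    }
  }
  if (all(expo == -Inf)) stop("no feasible input: all update exponents are -Inf", call. = FALSE)
  # subtract the max for numerical stability before exponentiating
  w <- 2^(expo - max(expo[is.finite(expo)]))
  w[expo == -Inf] <- 0
  w / sum(w)
}

#' Channel capacity by the Blahut-Arimoto algorithm
#'
#' Iterates the alternating maximization over the reverse channel and the
#' input distribution for a discrete memoryless channel \code{Q}, starting
#' from a strictly positive input distribution (uniform by default). Each
#' iteration computes, for every input \code{j},
#' \eqn{c_j = \sum_k Q_{k|j} \log_2(Q_{k|j}/q_k)}; the current mutual
#' information \eqn{L = \sum_j p_j c_j} is a lower bound on capacity and
#' \eqn{U = \max_j c_j} an upper bound, so terminating at
#' \eqn{U - L < \epsilon} certifies the answer to within \eqn{\epsilon}
#' bits. A simpler stop on the change in \eqn{L} between iterations is
#' available via \code{stopping}. The lower bound is non-decreasing across
#' iterations, so the result does not depend sensitively on the start.
#'
#' @param Q K x J transition matrix (columns are conditional output
#'   distributions).
#' @param p0 strictly positive starting input distribution; default
#'   uniform, 1/J per level.
#' @param eps convergence threshold in bits (default \code{1e-4}).
#' @param max_iter iteration cap guarding pathological inputs
#'   (default 10000).
#' @param stopping \code{"gap"} for the certified bound gap
#'   \eqn{U - L < \epsilon}, or \code{"delta"} for
#'   \eqn{|L_t - L_{t-1}| < \epsilon}.
#' @return An object of class \code{"capacity_result"}: a list with
#'   \code{capacity_bits}, \code{optimal_input}, \code{iterations},
#'   \code{converged}, \code{final_gap_bits} (upper minus lower bound at
#'   termination), and \code{lower_bounds} (the per-iteration lower-bound
#'   trace, for diagnostics).
#' @examples
#' blahut_arimoto(diag(8))$capacity_bits   # log2(8) = 3 bits
#' @export
blahut_arimoto <- function(Q, p0 = NULL, eps = 1e-4, max_iter = 10000L,
                           stopping = c("gap", "delta")) {
  validate_transition_matrix(Q)
  stopping <- match.arg(stopping)
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0) {
    stop("eps must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(max_iter) || max_iter < 1L) stop("max_iter must be positive", call. = FALSE)
  J <- ncol(Q)
  if (is.null(p0)) p0 <- rep(1 / J, J)
  validate_input_distribution(p0)
  check_dims(p0, Q)
  if (any(p0 <= 0)) stop("p0 must be strictly positive", call. = FALSE)

  p <- p0
  pos <- Q > 0
  logQ <- Q
  logQ[pos] <- log2(Q[pos])
  rows <- row(Q)[pos]

  L_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  gap <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    q <- as.vector(Q %*% p)
    lr <- matrix(0, nrow(Q), J)
    lr[pos] <- Q[pos] * (logQ[pos] - log2(q[rows]))
    cj <- colSums(lr)
    L <- sum(p * cj)
    U <- max(cj)
    gap <- U - L
    trace <- c(trace, L)
    done <- if (stopping == "gap") gap < eps else abs(L - L_prev) < eps
    if (done) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    L_prev <- L
    # p_j <- p_j 2^{c_j} / normalizer: the composition of the reverse-channel
    # and input-update steps for the current p
    w <- p * 2^(cj - max(cj))
    p <- w / sum(w)
  }

  structure(list(
    capacity_bits = max(L, 0),
    optimal_input = p,
    iterations = iter,
    converged = converged,
    final_gap_bits = max(gap, 0),
    lower_bounds = trace
  ), class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("Channel capacity: %.6f bits (%s after %d iterations, bound gap %.3g bits)\n",
              x$capacity_bits,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_gap_bits))
  cat("Optimal input distribution:", paste(sprintf("%.4f", x$optimal_input), collapse = " "), "\n")
  invisible(x)
}

#' Brute-force capacity over a simplex grid (small channels only)
#'
#' Maximizes \code{\link{mutual_information}} over a regular grid on the
#' probability simplex. Deliberately restricted to channels with at most 3
#' inputs so it stays an honest, exhaustive check on
#' \code{\link{blahut_arimoto}} rather than a usable solver.
#'
#' @param Q transition matrix with at most 3 columns.
#' @param grid_step simplex grid resolution (e.g. 0.01).
#' @return Maximum mutual information found on the grid, in bits.
#' @export
capacity_bruteforce <- function(Q, grid_step = 0.01) {
  validate_transition_matrix(Q)
  J <- ncol(Q)
  if (J > 3L) stop("brute-force search is restricted to channels with at most 3 inputs", call. = FALSE)
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 1) {
    stop("grid_step must be in (0, 1]", call. = FALSE)
  }
  steps <- seq(0, 1, by = grid_step)
  best <- 0
  if (J == 1L) {
    return(mutual_information(1, Q))
  } else if (J == 2L) {
    for (a in steps) {
      best <- max(best, mutual_information(c(a, 1 - a), Q))
    }
  } else {
    for (a in steps) {
      for (b in steps[steps <= 1 - a + 1e-12]) {
        best <- max(best, mutual_information(c(a, b, max(1 - a - b, 0)), Q))
      }
    }
  }
  best
}
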