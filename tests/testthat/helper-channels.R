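# Closed-form binary entropy, in bits
h2 <- function(q) {
  stopifnot(q > 0, q < 1)
  -q * log2(q) - (1 - q) * log2(1 - q)
}

# Binary symmetric channel with crossover probability q
bsc <- function(q) matrix(c(1 - q, q, q, 1 - q), nrow = 2)

# Random column-stochastic K x J channel
random_channel <- function(K, J) {
  M <- matrix(stats::runif(K * J), nrow = K)
  sweep(M, 2L, colSums(M), `/`)
}

# Quick capacity at a fixed bin count for a single sample set
capacity_at_bins <- function(s, n_bins, eps = 1e-4) {
  Q <- empirical_transition_matrix(s, make_edges(unlist(s$values_by_input), n_bins))
  blahut_arimoto(Q, eps = eps)$capacity_bits
}
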