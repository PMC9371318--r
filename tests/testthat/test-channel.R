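test_that("mutual information matches closed forms on canonical channels", {
  expect_equal(mutual_information(c(0.5, 0.5), diag(2)), 1)
  expect_equal(mutual_information(rep(1 / 8, 8), diag(8)), 3)
  # output independent of input: identical columns carry no information
  Q_same <- matrix(c(0.3, 0.7, 0.3, 0.7), nrow = 2)
  expect_equal(mutual_information(c(0.5, 0.5), Q_same), 0)
  # binary symmetric channel at uniform input: 1 - H2(q)
  for (q in c(0.05, 0.25, 0.4)) {
    expect_equal(mutual_information(c(0.5, 0.5), bsc(q)), 1 - h2(q), tolerance = 1e-12)
  }
})

test_that("mutual information rejects malformed inputs", {
  expect_error(mutual_information(c(0.5, 0.5), diag(3)), "does not match")
  expect_error(mutual_information(c(0.5, 0.5), matrix(c(-0.1, 1.1, 0.5, 0.5), 2)),
               "negative")
  expect_error(mutual_information(c(0.6, 0.5), diag(2)), "sums to")
  expect_error(mutual_information(c(0.5, 0.5), matrix(c(0.4, 0.4, 0.5, 0.5), 2)),
               "sums to")
})

test_that("reverse channel is the Bayes inversion of the forward channel", {
  expect_equal(reverse_channel(c(0.5, 0.5), diag(2)), diag(2))
  # degenerate prior: all posterior mass on the supported input
  P <- reverse_channel(c(1, 0), bsc(0.25))
  expect_equal(P[, 1], c(1, 1))
  expect_equal(P[, 2], c(0, 0))
  # hand-evaluated BSC(0.25) posterior at uniform prior
  P <- reverse_channel(c(0.5, 0.5), bsc(0.25))
  expect_equal(P[1, 1], 0.75)
  expect_equal(P[1, 2], 0.25)
  # zero-weight output bins get a uniform (harmless) column
  Q <- matrix(c(1, 0, 1, 0), nrow = 2)
  expect_equal(reverse_channel(c(0.5, 0.5), Q)[2, ], c(0.5, 0.5))
})

test_that("input update recovers fixed points of the alternation", {
  expect_equal(input_update(diag(2), diag(2)), c(0.5, 0.5))
  # a single input has nowhere to move
  expect_equal(input_update(matrix(1, 3, 1), matrix(c(0.2, 0.3, 0.5), 3, 1)), 1)
  # the uniform distribution is a fixed point of a symmetric channel
  Q <- bsc(0.25)
  p <- c(0.5, 0.5)
  expect_equal(input_update(reverse_channel(p, Q), Q), p, tolerance = 1e-12)
})

test_that("Blahut-Arimoto reproduces closed-form capacities", {
  res <- blahut_arimoto(diag(8), eps = 1e-4)
  expect_true(res$converged)
  expect_equal(res$capacity_bits, 3, tolerance = 1e-4)
  expect_equal(res$optimal_input, rep(0.125, 8), tolerance = 1e-6)

  expect_equal(blahut_arimoto(matrix(c(0.3, 0.7, 0.3, 0.7), 2))$capacity_bits, 0,
               tolerance = 1e-9)

  for (q in c(0.05, 0.1, 0.11, 0.25, 0.4)) {
    expect_equal(blahut_arimoto(bsc(q), eps = 1e-6)$capacity_bits, 1 - h2(q),
                 tolerance = 1e-3)
  }
})

test_that("Blahut-Arimoto respects structural bounds and options", {
  expect_error(blahut_arimoto(bsc(0.2), eps = -1), "positive")
  expect_error(blahut_arimoto(bsc(0.2), p0 = c(1, 0)), "strictly positive")
  # any 2-input channel is capped at 1 bit
  set.seed(11)
  for (i in 1:20) {
    Q <- random_channel(sample(2:8, 1), 2)
    expect_lte(blahut_arimoto(Q)$capacity_bits, 1 + 1e-9)
  }
  # general bound: log2(min(J, K))
  set.seed(12)
  for (i in 1:20) {
    K <- sample(2:10, 1); J <- sample(2:6, 1)
    cap <- blahut_arimoto(random_channel(K, J))$capacity_bits
    expect_gte(cap, 0)
    expect_lte(cap, log2(min(J, K)) + 1e-9)
  }
  # delta-capacity stopping mode also converges to the same answer
  expect_equal(blahut_arimoto(bsc(0.11), eps = 1e-8, stopping = "delta")$capacity_bits,
               1 - h2(0.11), tolerance = 1e-3)
})

test_that("the lower bound is monotone and the start does not matter", {
  set.seed(21)
  for (i in 1:10) {
    Q <- random_channel(sample(3:8, 1), sample(2:5, 1))
    res <- blahut_arimoto(Q, eps = 1e-6)
    expect_true(all(diff(res$lower_bounds) >= -1e-12))
    # two strictly positive random starts agree within 10 * eps
    J <- ncol(Q)
    p0a <- {w <- stats::runif(J) + 0.05; w / sum(w)}
    p0b <- {w <- stats::runif(J) + 0.05; w / sum(w)}
    ca <- blahut_arimoto(Q, p0 = p0a, eps = 1e-6)$capacity_bits
    cb <- blahut_arimoto(Q, p0 = p0b, eps = 1e-6)$capacity_bits
    expect_lt(abs(ca - cb), 10 * 1e-6)
  }
})

test_that("capacity is invariant to output relabeling and empty output bins", {
  set.seed(31)
  for (i in 1:10) {
    Q <- random_channel(6, 3)
    cap <- blahut_arimoto(Q, eps = 1e-6)$capacity_bits
    perm <- sample(nrow(Q))
    expect_equal(blahut_arimoto(Q[perm, ], eps = 1e-6)$capacity_bits, cap,
                 tolerance = 1e-9)
    expect_equal(blahut_arimoto(rbind(Q, 0), eps = 1e-6)$capacity_bits, cap,
                 tolerance = 1e-9)
    # permuting inputs permutes the optimal input with it
    cperm <- sample(ncol(Q))
    res_p <- blahut_arimoto(Q[, cperm], eps = 1e-6)
    expect_equal(res_p$capacity_bits, cap, tolerance = 1e-9)
  }
})

test_that("brute-force simplex search agrees with Blahut-Arimoto on small channels", {
  expect_equal(capacity_bruteforce(diag(2), 0.01), 1)
  expect_equal(capacity_bruteforce(bsc(0.25), 0.001), 1 - h2(0.25), tolerance = 1e-5)
  expect_error(capacity_bruteforce(diag(4)), "at most 3")
  set.seed(41)
  for (i in 1:10) {
    J <- sample(2:3, 1)
    Q <- random_channel(sample(2:5, 1), J)
    ba <- blahut_arimoto(Q, eps = 1e-5)$capacity_bits
    bf <- capacity_bruteforce(Q, 0.01)
    expect_lt(abs(ba - bf), 1e-5 + 2 * 0.01)
  }
})
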