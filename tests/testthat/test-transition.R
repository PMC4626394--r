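test_that("transition probabilities are row-normalized pair counts", {
  # edges A->B, A->B, A->A, B->A
  fx <- grouped_edges(data.frame(from = c("A", "A", "A", "B"),
                                 to   = c("B", "B", "A", "A")))
  tm <- estimate_transition_matrix(fx$forest, fx$partition)
  expect_equal(tm$S, matrix(c(1/3, 2/3, 1, 0), 2, 2, byrow = TRUE,
                            dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sum(tm$counts), 4)
})

test_that("perfect assortativity gives the identity matrix", {
  fx <- grouped_edges(data.frame(from = c("A", "A", "B", "B"),
                                 to   = c("A", "A", "B", "B")))
  tm <- estimate_transition_matrix(fx$forest, fx$partition)
  expect_equal(tm$S, diag(2), ignore_attr = TRUE)
})

test_that("zero-recruitment rows follow the chosen policy and are reported", {
  fx <- grouped_edges(data.frame(from = c("A", "A"), to = c("A", "B")))
  tm_u <- estimate_transition_matrix(fx$forest, fx$partition, "uniform")
  expect_equal(tm_u$S["B", ], c(A = 0.5, B = 0.5))
  expect_equal(tm_u$zero_rows, "B")
  tm_s <- estimate_transition_matrix(fx$forest, fx$partition, "self")
  expect_equal(tm_s$S["B", ], c(A = 0, B = 1))
})

test_that("reciprocity smoothing averages opposing counts", {
  fx <- grouped_edges(data.frame(from = c("A", "A", "A", "B"),
                                 to   = c("B", "B", "A", "A")))
  tm <- estimate_transition_matrix(fx$forest, fx$partition, smoothing = TRUE)
  # smoothed counts: AB = BA = 1.5, AA = 1, BB = 0
  expect_equal(tm$S["A", "B"], 1.5 / 2.5)
  expect_equal(tm$S["B", "A"], 1)
  expect_equal(tm$counts["A", "B"], 2)  # raw counts preserved
})

test_that("every estimated matrix is row-stochastic (random forests)", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    pairs <- data.frame(from = sample(c("A", "B", "C"), n, TRUE),
                        to = sample(c("A", "B", "C"), n, TRUE))
    fx <- grouped_edges(pairs)
    tm <- estimate_transition_matrix(fx$forest, fx$partition)
    expect_equal(rowSums(tm$S), c(A = 1, B = 1, C = 1), tolerance = 1e-12)
    expect_true(all(tm$S >= 0))
  }
})

test_that("a forest with no edges cannot yield a transition matrix", {
  recs <- data.frame(pid = "s", code = "F001-0000000000", degree = 2)
  f <- build_recruitment_forest(recs)
  part <- trait_partition(cbind(recs, `trait:x:lifetime` = 1), "trait:x:lifetime")
  expect_error(estimate_transition_matrix(f, part),
               class = "rds_insufficient_data")
})

test_that("stationary distributions satisfy pi S = pi and match closed forms", {
  S <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  expect_equal(unname(equilibrium_distribution(S)), c(0.5, 0.5))

  S2 <- matrix(c(2/3, 1/3, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(unname(equilibrium_distribution(S2)), c(0.75, 0.25))

  # k = 2 closed form pi_A = S_BA / (S_AB + S_BA) over random matrices
  set.seed(31)
  for (i in 1:50) {
    S <- random_stochastic(2)
    pi <- equilibrium_distribution(S)
    expect_equal(unname(pi[1]), S[2, 1] / (S[1, 2] + S[2, 1]), tolerance = 1e-12)
    resid <- max(abs(as.numeric(pi %*% S) - pi))
    expect_lt(resid, 1e-10)
  }
})

test_that("chains without a unique stationary vector raise a degeneracy error", {
  err <- expect_error(equilibrium_distribution(diag(2)),
                      class = "rds_degenerate_chain")
  expect_match(conditionMessage(err), "absorbing")
  # reducible with a single recurrent class is fine: transient group drains
  S <- matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(unname(equilibrium_distribution(S)), c(0, 1))
})

test_that("waves_to_equilibrium matches direct matrix powering", {
  S <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  expect_equal(waves_to_equilibrium(S, c(1, 0)), 1L)
  expect_equal(waves_to_equilibrium(S, c(0.5, 0.5)), 0L)

  S2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  pi <- equilibrium_distribution(S2)
  # brute-force oracle: count powering steps directly
  v <- c(1, 0); t_oracle <- 0
  while (max(abs(v - pi)) >= 0.02) { v <- as.numeric(v %*% S2); t_oracle <- t_oracle + 1 }
  expect_equal(waves_to_equilibrium(S2, c(1, 0), 0.02), t_oracle)
  expect_gt(t_oracle, 0)

  # monotone in tolerance
  expect_lte(waves_to_equilibrium(S2, c(1, 0), 0.05),
             waves_to_equilibrium(S2, c(1, 0), 0.02))
  expect_error(waves_to_equilibrium(S2, c(1, 0), 1e-20, max_iter = 5),
               class = "rds_nonconvergence")
})
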