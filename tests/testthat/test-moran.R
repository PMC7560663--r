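test_that("self-interaction objective adds K self-play payoffs", {
  # all-cooperate: 3 against the cooperator plus 3 in self-play
  expect_equal(self_objective(c(1, 1, 1, 1), c(1, 1, 1, 1), K = 1), 6,
               tolerance = 1e-4)
  # defector: 5 against the cooperator plus mutual-defection self-play of 1
  expect_equal(self_objective(c(0, 0, 0, 0), c(1, 1, 1, 1), K = 1), 6,
               tolerance = 1e-4)
  set.seed(501)
  p <- runif(4, 0.1, 0.9); opp <- matrix(runif(8, 0.1, 0.9), 2, 4)
  expect_equal(self_objective(p, opp, K = 0), mean_utility(p, opp))
})

test_that("composition payoff matrix collects the four pairwise utilities", {
  A <- composition_payoffs(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(c(A$A11, A$A12, A$A21, A$A22), c(1, 5, 0, 3), tolerance = 1e-4)
  set.seed(502)
  p <- runif(4, 0.1, 0.9); q <- runif(4, 0.1, 0.9)
  A <- composition_payoffs(p, q)
  expect_equal(A$A12, utility_quadratic(p, q))
  expect_equal(A$A21, utility_quadratic(q, p))
  Aeq <- composition_payoffs(p, p)
  expect_equal(Aeq$A11, Aeq$A12, tolerance = 1e-9)
  expect_equal(Aeq$A21, Aeq$A22, tolerance = 1e-9)
  po <- pd_payoffs()
  expect_true(all(unlist(A[c("A11", "A12", "A21", "A22")]) >= po$S - 1e-9))
  expect_true(all(unlist(A[c("A11", "A12", "A21", "A22")]) <= po$T + 1e-9))
})

test_that("fitnesses weight the composition payoffs correctly", {
  A <- list(A11 = 1, A12 = 5, A21 = 0, A22 = 3)
  expect_equal(unname(fitnesses(A, K = 2, n = 4)), c(11, 3))
  expect_equal(unname(fitnesses(A, K = 1, n = 2)), c(A$A12, A$A21))
  Aeq <- list(A11 = 2, A12 = 2, A21 = 2, A22 = 2)
  for (K in 1:3) {
    f <- fitnesses(Aeq, K, 4)
    expect_equal(f[["f1"]], f[["f2"]])
  }
})

test_that("neutral drift fixes with probability K/n", {
  set.seed(503)
  p <- runif(4, 0.1, 0.9)
  A <- composition_payoffs(p, p)
  for (n in c(2, 4, 7)) {
    for (K in 0:n) {
      expect_equal(fixation_probability(A, n, K), K / n, tolerance = 1e-12)
    }
  }
})

test_that("gamma-product fixation formula matches the absorption linear solve", {
  # n = 2 closed form: x_1 = 1 / (1 + gamma_1)
  set.seed(504)
  p <- runif(4, 0.1, 0.9); q <- runif(4, 0.1, 0.9)
  A <- composition_payoffs(p, q)
  f <- fitnesses(A, 1, 2)
  expect_equal(fixation_probability(A, 2, 1),
               1 / (1 + f[["f2"]] / f[["f1"]]), tolerance = 1e-12)

  for (i in 1:20) {
    n <- sample(3:6, 1)
    A_by_K <- lapply(seq_len(n - 1), function(K)
      composition_payoffs(runif(4, 0.05, 0.95), runif(4, 0.05, 0.95)))
    K0 <- sample(seq_len(n - 1), 1)
    expect_equal(fixation_probability(A_by_K, n, K0),
                 absorption_oracle(A_by_K, n, K0), tolerance = 1e-10)
  }
})

test_that("fixation probability is monotone in the starting count", {
  set.seed(505)
  for (i in 1:10) {
    n <- 5
    A_by_K <- lapply(seq_len(n - 1), function(K)
      composition_payoffs(runif(4, 0.05, 0.95), runif(4, 0.05, 0.95)))
    x <- vapply(0:n, function(K) fixation_probability(A_by_K, n, K), numeric(1))
    expect_true(all(diff(x) >= -1e-12))
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("best-response dynamics is seeded and reaches a fixed point", {
  a <- best_response_dynamics(c(1, 1, 1, 1), K = 0, seed = 11, n_starts = 8)
  b <- best_response_dynamics(c(1, 1, 1, 1), K = 0, seed = 11, n_starts = 8)
  expect_identical(as.numeric(a), as.numeric(b))
  # against a cooperator with no self-interaction: utility-5 best response
  expect_equal(attr(a, "objective"), 5, tolerance = 1e-6)

  set.seed(506)
  q <- runif(4, 0.1, 0.9)
  p <- best_response_dynamics(q, K = 1, seed = 12, n_starts = 8, tol = 1e-4)
  if (attr(p, "converged")) {
    # one more re-optimisation against the frozen result barely moves the
    # objective
    env <- rbind(matrix(q, 1), perturb_strategy(as.numeric(p)))
    step <- memone:::argmax_weighted(env, c(1, 1), pd_payoffs(), n_starts = 8,
                                     warm = as.numeric(p))
    expect_lt(abs(step$objective - attr(p, "objective")), 10 * 1e-4 * 50)
    expect_lt(max(abs(step$p - as.numeric(p))), 10 * 1e-4)
  }
})

test_that("dynamic Moran experiment returns coherent fixation tables", {
  set.seed(507)
  q <- runif(4, 0.2, 0.8)
  res <- dynamic_moran_experiment(q, n = 4, seed = 21, n_starts = 8)
  expect_equal(res$table$K, 1:3)
  expect_true(all(res$table$x_dynamic >= 0 & res$table$x_dynamic <= 1))
  expect_true(all(res$table$x_static >= 0 & res$table$x_static <= 1))
  expect_true(all(res$table$ratio > 0))
  # static comparator at K0 = 1 uses the K = 1 strategy
  expect_equal(res$static_strategy, res$strategies[[1]])
})
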