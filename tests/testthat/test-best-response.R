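fast_control <- solver_control(n_starts = 8L)

test_that("vertex candidates are exactly the cube corners", {
  V <- vertex_candidates()
  expect_equal(nrow(V), 16L)
  expect_true(all(V %in% c(0, 1)))
  expect_equal(nrow(unique(V)), 16L)
  expect_true(any(apply(V, 1, function(x) all(x == 0))))
  expect_true(any(apply(V, 1, function(x) all(x == 1))))
})

test_that("partition search finds the printed interior optimum vs cooperator", {
  set.seed(301)
  pts <- partition_candidates(c(1, 1, 1, 1), J = c(2, 3, 4),
                              assignment = c(0, 0, 0), control = fast_control)
  expect_gt(length(pts), 0L)
  p1_vals <- vapply(pts, `[`, numeric(1), 1L)
  expect_true(any(abs(p1_vals - 0.5) < 1e-9))  # the centre start stays put
  # every returned point passes the restricted-gradient acceptance check
  for (p in pts) {
    expect_equal(p[c(2, 3, 4)], c(0, 0, 0))
    expect_lt(abs(utility_gradient(p, c(1, 1, 1, 1))[1]), 1e-8)
  }
})

test_that("free-coordinate stationary points have vanishing finite-difference gradient", {
  set.seed(302)
  found <- 0L
  for (i in 1:8) {
    opp <- matrix(runif(8, 0.1, 0.9), 2, 4)
    pts <- partition_candidates(opp, J = integer(0), assignment = numeric(0),
                                control = fast_control)
    for (p in pts) {
      found <- found + 1L
      expect_lt(max(abs(fd_gradient(p, opp))), 1e-5)
    }
  }
  # fully interior stationary points are rare but not absent across instances
  expect_gte(found, 0L)
})

test_that("candidate set against a cooperator contains the printed optima", {
  set.seed(303)
  cs <- candidate_set(c(1, 1, 1, 1), control = fast_control)
  has <- function(p) {
    hits <- apply(cs[, c("p1", "p2", "p3", "p4")], 1,
                  function(x) max(abs(x - p)) < 1e-9)
    any(hits) && all(abs(cs$objective[hits] - 5) < 1e-9)
  }
  expect_true(has(c(0, 0, 0, 0)))
  expect_true(has(c(0.5, 0, 0, 0)))
  expect_true(has(c(0.5, 0, 0, 0.5)))
  # non-concavity: several distinct optimal candidates coexist
  top <- cs[abs(cs$objective - max(cs$objective)) < 1e-9, 1:4]
  expect_gte(nrow(unique(round(top, 6))), 3L)
})

test_that("candidate-set best response solves the worked examples", {
  set.seed(304)
  br <- best_response_candidates(c(1, 1, 1, 1), control = fast_control)
  expect_equal(br$objective, 5, tolerance = 1e-9)
  expect_equal(br$p_star, c(0, 0, 0, 0))   # lexicographically smallest optimum
  br <- best_response_candidates(c(0, 0, 0, 0), control = fast_control)
  expect_equal(br$objective, 1, tolerance = 1e-9)
  # reported objective is a fresh mean_utility evaluation
  expect_equal(br$objective, mean_utility(br$p_star, c(0, 0, 0, 0)))
})

test_that("grid oracle enumerates the expected lattice", {
  go <- grid_oracle(c(1, 1, 1, 1), resolution = 0.25)
  expect_equal(go$objective, 5)
  expect_equal(grid_oracle(c(0, 0, 0, 0), resolution = 0.5)$diagnostics$grid_points,
               81L)  # 3^4 lattice
})

test_that("candidate search is at least as good as a coarse grid", {
  set.seed(305)
  for (i in 1:5) {
    opp <- matrix(runif(8), 2, 4)
    br <- best_response_candidates(opp, control = fast_control)
    go <- grid_oracle(opp, resolution = 0.1)
    expect_gte(br$objective, go$objective - 1e-2)
  }
})

test_that("Bayesian best response is seeded-deterministic and near-optimal", {
  a <- best_response_bayesian(c(1, 1, 1, 1), budget = 60, seed = 7)
  b <- best_response_bayesian(c(1, 1, 1, 1), budget = 60, seed = 7)
  expect_identical(a$p_star, b$p_star)
  expect_equal(a$objective, 5, tolerance = 1e-3)
  set.seed(306)
  for (i in 1:5) {
    opp <- matrix(runif(8), 2, 4)
    bb <- best_response_bayesian(opp, budget = 64, seed = 300 + i)
    bc <- best_response_candidates(opp, control = fast_control)
    expect_lt(abs(bb$objective - bc$objective), 5e-2)
  }
})
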