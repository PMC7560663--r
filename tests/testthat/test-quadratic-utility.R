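test_that("coefficient objects have the printed structure", {
  co <- quadratic_coefficients(c(1, 1, 1, 1))
  expect_equal(co$a, 5)      # a = -P q2 + P + T q4 at q = (1,1,1,1)
  expect_equal(co$abar, 1)   # abar = -q2 + q4 + 1
  set.seed(201)
  for (i in 1:10) {
    co <- quadratic_coefficients(runif(4))
    expect_equal(diag(co$Q), rep(0, 4))
    expect_equal(diag(co$Qbar), rep(0, 4))
    expect_equal(co$Q, t(co$Q))
    expect_equal(co$Qbar, t(co$Qbar))
  }
})

test_that("quadratic-form utility equals the Markov steady-state utility", {
  expect_equal(utility_quadratic(c(0, 0, 0, 0), c(1, 1, 1, 1)), 5)
  expect_equal(utility_quadratic(c(0, 0, 0, 0), c(0, 0, 0, 0)), 1)
  set.seed(202)
  for (i in 1:300) {
    pq <- random_ergodic_pair()
    expect_equal(utility_quadratic(pq$p, pq$q), utility_markov(pq$p, pq$q),
                 tolerance = 1e-8)
  }
  # degenerate match: denominator vanishes
  expect_error(utility_quadratic(c(1, 0, 1, 0), c(1, 0, 1, 0)),
               class = "memone_undefined_utility")
})

test_that("utility stays within the payoff bounds where defined", {
  po <- pd_payoffs()
  set.seed(203)
  for (i in 1:200) {
    pq <- random_ergodic_pair()
    u <- utility_quadratic(pq$p, pq$q, po)
    expect_gte(u, po$S - 1e-9)
    expect_lte(u, po$T + 1e-9)
  }
})

test_that("the printed alternative best responses to a cooperator score 5", {
  q <- c(1, 1, 1, 1)
  for (p in list(c(0, 0, 0, 0), c(0.5, 0, 0, 0), c(0.5, 0, 0, 0.5))) {
    expect_equal(utility_quadratic(p, q), 5, tolerance = 1e-12)
  }
})

test_that("mean utility is the average of per-opponent utilities", {
  expect_equal(
    mean_utility(c(0, 0, 0, 0), rbind(c(1, 1, 1, 1), c(0, 0, 0, 0))), 3)
  set.seed(204)
  p <- runif(4, 0.05, 0.95)
  opp <- matrix(runif(12, 0.05, 0.95), 3, 4)
  expect_equal(mean_utility(p, opp),
               mean(apply(opp, 1, function(q) utility_quadratic(p, q))),
               tolerance = 1e-12)
  expect_equal(mean_utility(p, opp[1, ]), utility_quadratic(p, opp[1, ]))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(205)
  for (i in 1:20) {
    p <- runif(4, 0.05, 0.95)
    n_opp <- sample(1:3, 1)
    opp <- matrix(runif(4 * n_opp, 0.05, 0.95), n_opp, 4)
    expect_equal(utility_gradient(p, opp), fd_gradient(p, opp),
                 tolerance = 1e-5)
  }
})

test_that("stationarity residual clears the single-opponent gradient", {
  set.seed(206)
  po <- pd_payoffs()
  for (i in 1:20) {
    p <- runif(4, 0.05, 0.95)
    q <- runif(4, 0.05, 0.95)
    co <- quadratic_coefficients(q, po)
    den <- 0.5 * sum(p * (co$Qbar %*% p)) + sum(co$cbar * p) + co$abar
    # residual * den^2 reproduces the gradient numerator exactly (N = 1)
    expect_equal(stationarity_residual(p, q),
                 utility_gradient(p, q) * den^2, tolerance = 1e-8)
  }
  # along the flat optimum line against the cooperator the utility does not
  # change with p1, so the first residual component vanishes
  expect_lt(abs(stationarity_residual(c(0.5, 0, 0, 0), c(1, 1, 1, 1))[1]),
            1e-10)
  # a non-stationary vertex does not
  expect_gt(max(abs(stationarity_residual(c(1, 1, 1, 1), c(0.3, 0.6, 0.2, 0.8)))),
            1e-6)
})
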