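test_that("Gambler construction validates its 17 probabilities", {
  g <- gambler_strategy(rep(1, 17))
  expect_s3_class(g, "gambler")
  expect_length(g$table, 16L)
  expect_equal(g$opening, 1)
  expect_error(gambler_strategy(rep(0.5, 16)), "opening")
  expect_error(gambler_strategy(c(rep(0.5, 16), 1.2)), "\\[0, 1\\]")
})

test_that("Gambler decisions follow the lookup rules", {
  g <- gambler_strategy(c(runif(16), 0.42))
  expect_equal(gambler_decision(g, character(0), character(0)), 0.42)
  # second move: the first-two-moves key is still incomplete
  expect_equal(gambler_decision(g, "C", "D"), 0.42)
  # from move three the table entry applies
  expect_equal(gambler_decision(g, c("C", "D"), c("D", "C")),
               unname(g$table[memone:::gambler_index(3L, 1L, 0L)]))
  expect_error(gambler_decision(g, c("C"), c("C", "D")), "malformed")
  expect_error(gambler_decision(g, c("X"), c("C")), "malformed")

  ones <- gambler_strategy(rep(1, 17))
  hist_own <- c("C", "D", "C"); hist_opp <- c("D", "D", "C")
  expect_equal(gambler_decision(ones, hist_own, hist_opp), 1)
})

test_that("a copy-opponents-last-move Gambler behaves as Tit-for-Tat", {
  tab <- numeric(16)
  for (f2 in 1:4) for (sl in c(1L, 0L)) {
    tab[memone:::gambler_index(f2, 1L, sl)] <- 1  # cooperate iff they did
  }
  tft <- gambler_strategy(c(tab, 1))
  set.seed(601)
  for (i in 1:10) {
    len <- sample(2:8, 1)
    own <- sample(c("C", "D"), len, replace = TRUE)
    opp <- sample(c("C", "D"), len, replace = TRUE)
    expect_equal(gambler_decision(tft, own, opp),
                 as.numeric(opp[len] == "C"))
  }
})

test_that("the memory-one embedding reproduces the strategy's responses", {
  set.seed(602)
  p <- runif(4)
  g <- gambler_strategy(memone:::memone_as_gambler(p))
  for (i in 1:10) {
    len <- sample(2:6, 1)
    own <- sample(c("C", "D"), len, replace = TRUE)
    opp <- sample(c("C", "D"), len, replace = TRUE)
    state <- (own[len] == "D") * 2 + (opp[len] == "D") + 1
    expect_equal(gambler_decision(g, own, opp), p[state])
  }
})

test_that("match simulation reproduces degenerate and analytic payoffs", {
  m <- simulate_match(c(1, 1, 1, 1), c(1, 1, 1, 1), turns = 50,
                      repetitions = 5, seed = 1)
  expect_equal(m$player, 3)
  expect_equal(m$opponent, 3)

  m1 <- simulate_match(c(0.3, 0.6, 0.1, 0.9), c(0.2, 0.8, 0.5, 0.4),
                       turns = 100, repetitions = 10, seed = 9)
  m2 <- simulate_match(c(0.3, 0.6, 0.1, 0.9), c(0.2, 0.8, 0.5, 0.4),
                       turns = 100, repetitions = 10, seed = 9)
  expect_identical(m1$player, m2$player)

  set.seed(603)
  for (i in 1:5) {
    pq <- random_ergodic_pair()
    u <- utility_quadratic(pq$p, pq$q)
    m <- simulate_match(pq$p, pq$q, turns = 500, repetitions = 200,
                        seed = 600 + i)
    expect_lt(abs(m$player - u), 0.1)
    m <- simulate_match(pq$p, pq$q, turns = 2000, repetitions = 200,
                        seed = 700 + i)
    expect_lt(abs(m$player - u), 0.05)
  }
})

test_that("Gambler optimisation approaches the exploitation bound", {
  res <- optimise_gambler(c(1, 1, 1, 1), turns = 50, repetitions = 10,
                          budget = 25, seed = 4,
                          warm_starts = memone:::memone_as_gambler(c(0, 0, 0, 0)))
  # defecting against the cooperator yields T = 5 on all but the opening move
  expect_gte(res$objective, 4.9)
  expect_lte(res$objective, 5)
  res2 <- optimise_gambler(c(1, 1, 1, 1), turns = 50, repetitions = 10,
                           budget = 25, seed = 4,
                           warm_starts = memone:::memone_as_gambler(c(0, 0, 0, 0)))
  expect_identical(res$objective, res2$objective)
})

test_that("utility ratio against twin cooperators is near one", {
  res <- utility_ratio_trial(rbind(c(1, 1, 1, 1), c(1, 1, 1, 1)),
                             turns = 100, repetitions = 10, budget = 25,
                             seed = 5, control = solver_control(n_starts = 4))
  expect_gt(res$ratio, 0.98)
  expect_lt(res$ratio, 1.02)
  expect_true(is.finite(res$ratio) && res$ratio > 0)
})
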