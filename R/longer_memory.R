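#' Gambler lookup-table strategy
#'
#' A longer-memory strategy conditioning on the opponent's first two moves
#' (4 possibilities), the opponent's last move (2) and its own last move (2):
#' a lookup table of 16 cooperation probabilities plus an opening
#' probability, i.e. a point in the unit 17-cube.
#'
#' The table is ordered by (opponent's first two moves: CC, CD, DC, DD) x
#' (opponent's last move: C, D) x (own last move: C, D), own move fastest.
#' A 17-vector is read as the 16 table entries in that order followed by the
#' opening probability.
#'
#' @param x Either a numeric 17-vector, or a 16-vector `table` with `opening`
#'   given separately.
#' @param opening Opening cooperation probability (used when `x` has length
#'   16).
#' @return An object of class `gambler`: list with `table` (named length-16)
#'   and `opening`.
#' @examples
#' gambler_strategy(rep(1, 17))  # unconditional cooperator
#' @export
gambler_strategy <- function(x, opening = NULL) {
  x <- as.numeric(x)
  if (length(x) == 17L) {
    opening <- x[17L]
    x <- x[1:16]
  }
  if (length(x) != 16L || is.null(opening)) {
    stop("a Gambler needs 16 table probabilities plus an opening probability",
         call. = FALSE)
  }
  if (anyNA(c(x, opening)) || any(c(x, opening) < 0) || any(c(x, opening) > 1)) {
    stop("all 17 Gambler probabilities must lie in [0, 1]", call. = FALSE)
  }
  keys <- as.vector(outer(
    c("CC", "CD", "DC", "DD"),
    c("C.C", "C.D", "D.C", "D.D"),
    function(a, b) paste(a, b, sep = ".")))
  # outer() fills first argument fastest; reorder to first-two-major
  keys <- sort(keys)
  names(x) <- keys
  structure(list(table = x, opening = opening), class = "gambler")
}

#' @export
print.gambler <- function(x, ...) {
  cat("Gambler (2,1,1) lookup strategy; opening =", x$opening, "\n")
  print(round(x$table, 4))
  invisible(x)
}

# Table index for vectorised lookup: f2 in 1:4 (CC,CD,DC,DD), opponent and
# own last moves as 1 = C, 0 = D.
gambler_index <- function(f2, opp_last, own_last) {
  (f2 - 1L) * 4L + (1L - opp_last) * 2L + (1L - own_last) + 1L
}

# Embed a memory-one strategy as a Gambler: table depends only on
# (own last, opponent last), opening move cooperates.
memone_as_gambler <- function(p, opening = 1) {
  p <- as_strategy(p)
  tab <- numeric(16)
  for (f2 in 1:4) for (ol in c(1L, 0L)) for (sl in c(1L, 0L)) {
    state <- (1L - sl) * 2L + (1L - ol) + 1L   # own/opp last -> CC,CD,DC,DD
    tab[gambler_index(f2, ol, sl)] <- p[state]
  }
  c(tab, opening)
}

#' Gambler decision probability on a history
#'
#' Cooperation probability of a Gambler given the moves played so far. On the
#' first move the opening probability is used; while the opponent has fewer
#' than two recorded moves (i.e. also on the second move) the key on the
#' opponent's first two moves is incomplete and the opening probability is
#' used again; from the third move on the table entry for (opponent's first
#' two moves, opponent's last move, own last move) applies.
#'
#' @param f A [gambler_strategy()].
#' @param own_history,opp_history Character vectors of `"C"`/`"D"` moves of
#'   equal length (possibly empty).
#' @return A cooperation probability.
#' @export
gambler_decision <- function(f, own_history, opp_history) {
  stopifnot(inherits(f, "gambler"))
  if (length(own_history) != length(opp_history)) {
    stop("malformed history: players must have equally many moves",
         call. = FALSE)
  }
  moves <- c(own_history, opp_history)
  if (length(moves) > 0 && !all(moves %in% c("C", "D"))) {
    stop("malformed history: moves must be \"C\" or \"D\"", call. = FALSE)
  }
  t_now <- length(own_history)
  if (t_now < 2L) return(f$opening)
  f2 <- match(paste(opp_history[1:2], collapse = ""),
              c("CC", "CD", "DC", "DD"))
  ol <- as.integer(opp_history[t_now] == "C")
  sl <- as.integer(own_history[t_now] == "C")
  unname(f$table[gambler_index(f2, ol, sl)])
}

#' Simulate repeated matches
#'
#' Turn-by-turn simulation of a player (a Gambler or a memory-one strategy)
#' against a memory-one opponent: `repetitions` independent matches of
#' `turns` simultaneous moves, vectorised across repetitions. Memory-one
#' players cooperate on the first move; a Gambler uses its opening
#' probability (and again on the second move, while its first-two-moves key
#' is incomplete).
#'
#' @param player A [gambler_strategy()] or a memory-one strategy (numeric
#'   4-vector).
#' @param opponent Memory-one strategy.
#' @param turns Moves per match (default 500).
#' @param repetitions Independent matches (default 200).
#' @param payoffs A [pd_payoffs()] object.
#' @param seed Integer seed; the result is a deterministic function of it.
#' @return A list of class `match_result`: `player` and `opponent` mean
#'   payoffs per turn (averaged over repetitions), `turns`, `repetitions`,
#'   `seed`.
#' @examples
#' simulate_match(c(1, 1, 1, 1), c(1, 1, 1, 1), turns = 10, repetitions = 2,
#'                seed = 1)  # mutual cooperation: both score 3
#' @export
simulate_match <- function(player, opponent, turns = 500L, repetitions = 200L,
                           payoffs = pd_payoffs(), seed = 1L) {
  stopifnot(turns >= 1L, repetitions >= 1L)
  payoffs <- as_payoffs(payoffs)
  q <- as_strategy(opponent, "opponent")
  is_gambler <- inherits(player, "gambler")
  if (!is_gambler) player <- as_strategy(player, "player")
  pay <- payoffs$vec                     # (R, S, T, P) by (CC, CD, DC, DD)

  withr::with_seed(seed, {
    nrep <- repetitions
    own_last <- integer(nrep)            # 1 = C, 0 = D
    opp_last <- integer(nrep)
    opp_first1 <- integer(nrep)
    opp_first2 <- integer(nrep)
    tot1 <- numeric(nrep)
    tot2 <- numeric(nrep)
    for (t in seq_len(turns)) {
      if (t == 1L) {
        pr1 <- rep(if (is_gambler) player$opening else 1, nrep)
        pr2 <- rep(1, nrep)
      } else {
        state2 <- (1L - opp_last) * 2L + (1L - own_last) + 1L
        pr2 <- q[state2]
        if (is_gambler) {
          if (t == 2L) {
            pr1 <- rep(player$opening, nrep)
          } else {
            f2 <- (1L - opp_first1) * 2L + (1L - opp_first2) + 1L
            pr1 <- player$table[gambler_index(f2, opp_last, own_last)]
          }
        } else {
          state1 <- (1L - own_last) * 2L + (1L - opp_last) + 1L
          pr1 <- player[state1]
        }
      }
      own <- as.integer(stats::runif(nrep) < pr1)
      opp <- as.integer(stats::runif(nrep) < pr2)
      tot1 <- tot1 + pay[(1L - own) * 2L + (1L - opp) + 1L]
      tot2 <- tot2 + pay[(1L - opp) * 2L + (1L - own) + 1L]
      if (t == 1L) opp_first1 <- opp
      if (t == 2L) opp_first2 <- opp
      own_last <- own
      opp_last <- opp
    }
    structure(list(player = mean(tot1) / turns, opponent = mean(tot2) / turns,
                   turns = turns, repetitions = repetitions, seed = seed),
              class = "match_result")
  })
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match (%d turns x %d reps): player %.4f, opponent %.4f per turn\n",
              x$turns, x$repetitions, x$player, x$opponent))
  invisible(x)
}

#' Optimise a Gambler against a set of opponents
#'
#' Bayesian-optimisation estimate of the 17-parameter Gambler maximising the
#' mean simulated payoff per turn against a set of memory-one opponents.
#' Every candidate is evaluated with the same simulation seed (common random
#' numbers), so the objective is deterministic and the whole optimisation is
#' a function of `seed`. The initial design can be warm-started, e.g. with a
#' memory-one strategy embedded as a Gambler.
#'
#' @inheritParams mean_utility
#' @param turns,repetitions Simulation scale per evaluation (paper-scale
#'   defaults 500 x 200; use 100 x 20 for a fast profile).
#' @param budget Total objective evaluations (at least 20).
#' @param seed Integer seed.
#' @param warm_starts Optional matrix of 17-vectors added to the initial
#'   design.
#' @return A list with `gambler` (the best [gambler_strategy()]), `objective`
#'   (its mean simulated payoff), and `evaluations`.
#' @export
optimise_gambler <- function(opponents, payoffs = pd_payoffs(), turns = 500L,
                             repetitions = 200L, budget = 60L, seed = 1L,
                             warm_starts = NULL) {
  stopifnot(budget >= 20L)
  opponents <- as_opponent_matrix(opponents)
  sim_seed <- seed + 10007L
  objective <- function(x) {
    g <- gambler_strategy(x)
    mean(vapply(seq_len(nrow(opponents)), function(i)
      simulate_match(g, opponents[i, ], turns, repetitions, payoffs,
                     seed = sim_seed)$player, numeric(1)))
  }
  opt <- withr::with_seed(seed,
    gp_ei_optimise(objective, d = 17L, budget = budget, n_init = 16L,
                   init = warm_starts))
  list(gambler = gambler_strategy(opt$x), objective = opt$y,
       evaluations = opt$evaluations)
}

#' Gambler versus memory-one best response: one trial
#'
#' For one opponent set, computes the analytic memory-one best response and
#' an optimised Gambler (warm-started with that best response embedded as a
#' Gambler) and returns the ratio of the Gambler's simulated utility to the
#' memory-one best response's utility. Ratios at or above 1 indicate the
#' longer memory is not a handicap; values persistently above 1 show
#' one-round memory is limiting.
#'
#' @inheritParams optimise_gambler
#' @param control [solver_control()] for the memory-one best response.
#' @return A list with `ratio`, `gambler_objective`, `memory_one` (the
#'   `best_response` object), and `gambler`.
#' @export
utility_ratio_trial <- function(opponents, payoffs = pd_payoffs(),
                                turns = 100L, repetitions = 20L, budget = 60L,
                                seed = 1L, control = solver_control()) {
  opponents <- as_opponent_matrix(opponents)
  mo <- best_response_candidates(opponents, payoffs, control)
  warm <- matrix(memone_as_gambler(mo$p_star), nrow = 1)
  g <- optimise_gambler(opponents, payoffs, turns, repetitions, budget, seed,
                        warm_starts = warm)
  list(ratio = g$objective / mo$objective, gambler_objective = g$objective,
       memory_one = mo, gambler = g$gambler)
}
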