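# Self-play utility u_p(p); deterministic coordinates make the self-match
# chain degenerate, so fall back to the trembling-hand limit when asked.
# Near-vertex pairs can leave the perturbed denominator at the eps^2 scale,
# below the degeneracy tolerance, so the fallback widens eps progressively.
self_play_utility <- function(p, payoffs, perturb = TRUE, eps = 1e-6) {
  u <- tryCatch(utility_quadratic(p, p, payoffs),
                memone_undefined_utility = function(e) if (perturb) NULL else stop(e))
  for (e in c(eps, 1e-4, 1e-3, 1e-2)) {
    if (!is.null(u)) return(u)
    pp <- perturb_strategy(p, e)
    u <- tryCatch(utility_quadratic(pp, pp, payoffs),
                  memone_undefined_utility = function(e) NULL)
  }
  if (is.null(u)) undefined_utility("self-play utility undefined even after perturbation")
  u
}

# Pairwise utility with trembling-hand fallback for degenerate matches.
pair_utility <- function(p, q, payoffs, eps = 1e-6) {
  u <- tryCatch(utility_quadratic(p, q, payoffs),
                memone_undefined_utility = function(e) NULL)
  for (e in c(eps, 1e-4, 1e-3, 1e-2)) {
    if (!is.null(u)) return(u)
    u <- tryCatch(
      utility_quadratic(perturb_strategy(p, e), perturb_strategy(q, e), payoffs),
      memone_undefined_utility = function(e) NULL)
  }
  if (is.null(u)) undefined_utility("pair utility undefined even after perturbation")
  u
}

#' Objective with self-interactions
#'
#' The payoff of a strategy that meets each of `N` opponents and `K` copies
#' of itself: `1/N * sum_i u_{q^(i)}(p) + K * u_p(p)`. This is the objective
#' a best-response player in a finite population must maximise, since its own
#' copies are part of its environment.
#'
#' @inheritParams mean_utility
#' @param K Number of self-interactions (a nonnegative number).
#' @param perturb Apply the trembling-hand fallback when the self-play chain
#'   is degenerate (default `TRUE`; with `FALSE` a degenerate self-match is
#'   an error).
#' @param eps Perturbation size for the fallback.
#' @return The objective value.
#' @examples
#' self_objective(c(1, 1, 1, 1), c(1, 1, 1, 1), K = 1)  # 3 + 3 = 6
#' @export
self_objective <- function(p, opponents, K, payoffs = pd_payoffs(),
                           perturb = TRUE, eps = 1e-6) {
  p <- as_strategy(p, "p")
  stopifnot(K >= 0)
  opponents <- as_opponent_matrix(opponents)
  # some strategies (e.g. repeat-own-last-move) are degenerate against every
  # opponent, so the opponent term gets the trembling-hand fallback as well
  opp_term <- if (perturb) {
    mean(vapply(seq_len(nrow(opponents)), function(i)
      pair_utility(p, opponents[i, ], payoffs, eps), numeric(1)))
  } else {
    mean_utility(p, opponents, payoffs)
  }
  opp_term + K * self_play_utility(p, payoffs, perturb, eps)
}

# Argmax over the cube of sum_i w_i u_{q^(i)}(p) by multi-start projected
# quasi-Newton ascent plus vertex enumeration. Fast inner solver for the
# best-response dynamics loop; consumes the caller's RNG stream.
argmax_weighted <- function(opponents, weights, payoffs,
                            n_starts = 16L, warm = NULL, eps = 1e-6) {
  coefs <- precompute_coefs(opponents, payoffs)
  safe_eval <- function(f, p) {
    v <- tryCatch(f(p), memone_undefined_utility = function(e) NULL)
    for (e in c(eps, 1e-4, 1e-3, 1e-2)) {
      if (!is.null(v)) return(v)
      v <- tryCatch(f(perturb_strategy(p, e)),
                    memone_undefined_utility = function(e) NULL)
    }
    stop("utility undefined even after perturbation", call. = FALSE)
  }
  safe_u <- function(p) safe_eval(function(x) weighted_utility(x, coefs, weights), p)
  gr <- function(p) safe_eval(function(x) weighted_gradient(x, coefs, weights), p)
  V <- vertex_candidates()
  vvals <- apply(V, 1, safe_u)
  best_p <- V[which.max(vvals), ]
  best_v <- max(vvals)
  starts <- rbind(lhs::randomLHS(n_starts, 4L), best_p, warm)
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], safe_u, gr, method = "L-BFGS-B",
                   lower = rep(0, 4), upper = rep(1, 4),
                   control = list(fnscale = -1, maxit = 200L,
                                  factr = 10, pgtol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value > best_v) {
      best_v <- fit$value
      best_p <- fit$par
    }
  }
  list(p = pmin(pmax(best_p, 0), 1), objective = best_v)
}

#' Best-response dynamics with self-interactions
#'
#' Fixed-point iteration for the self-interaction objective: starting from a
#' seeded uniform draw, repeatedly replace the current strategy by the best
#' response to the opponents plus `K` frozen copies of the current strategy,
#' until successive iterates differ by less than `tol` in sup norm. The
#' returned strategy is (numerically) a fixed point: re-optimising against
#' itself does not move it.
#'
#' @inheritParams mean_utility
#' @param K Number of self-interactions in the objective (weight on the
#'   frozen self-copy).
#' @param tol Convergence tolerance on successive iterates. Default `1e-4`.
#' @param max_iter Maximum iterations. Default 50.
#' @param seed Integer seed (initial draw and optimiser starts).
#' @param n_starts Ascent starts per inner optimisation.
#' @return The final strategy (numeric 4-vector) with attributes `converged`
#'   (logical), `iterations` and `objective`.
#' @export
best_response_dynamics <- function(opponents, K, payoffs = pd_payoffs(),
                                   tol = 1e-4, max_iter = 50L, seed = 1L,
                                   n_starts = 16L) {
  stopifnot(max_iter >= 1L, K >= 0)
  opponents <- as_opponent_matrix(opponents)
  N <- nrow(opponents)
  withr::with_seed(seed, {
    p <- stats::runif(4)
    converged <- FALSE
    iter <- 0L
    iterates <- list()
    while (iter < max_iter) {
      iter <- iter + 1L
      if (K > 0) {
        env <- rbind(opponents, perturb_strategy(p))
        w <- c(rep(1 / N, N), K)
      } else {
        env <- opponents
        w <- rep(1 / N, N)
      }
      step <- argmax_weighted(env, w, payoffs, n_starts = n_starts, warm = p)
      delta <- max(abs(step$p - p))
      p <- step$p
      iterates[[iter]] <- p
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    # Best-response cycling can occur (exploit-self / cooperate-with-self
    # oscillation); without convergence, return the visited iterate with the
    # highest self-interaction objective.
    objs <- vapply(iterates, function(x)
      self_objective(x, opponents, K, payoffs), numeric(1))
    if (!converged) p <- iterates[[which.max(objs)]]
    structure(p, converged = converged, iterations = iter,
              objective = if (converged) objs[[iter]] else max(objs))
  })
}

#' Per-composition payoff matrix of a two-type population
#'
#' The four long-run pairwise utilities that drive a Moran process between a
#' best-response type `p` and a resident type `q`: `A11 = u_p(p)` (self-play
#' of the best-response type), `A12 = u_q(p)`, `A21 = u_p(q)`,
#' `A22 = u_q(q)`. Degenerate matches are evaluated in the trembling-hand
#' limit.
#'
#' @param p Best-response (first-type) strategy.
#' @param q Resident (second-type) strategy.
#' @param payoffs A [pd_payoffs()] object.
#' @param eps Perturbation size for degenerate matches.
#' @return Named list with `A11`, `A12`, `A21`, `A22` and the strategy `p`.
#' @examples
#' composition_payoffs(c(0, 0, 0, 0), c(1, 1, 1, 1))  # (1, 5, 0, 3)
#' @export
composition_payoffs <- function(p, q, payoffs = pd_payoffs(), eps = 1e-6) {
  p <- as_strategy(p, "p")
  q <- as_strategy(q, "q")
  list(A11 = self_play_utility(p, payoffs, TRUE, eps),
       A12 = pair_utility(p, q, payoffs, eps),
       A21 = pair_utility(q, p, payoffs, eps),
       A22 = self_play_utility(q, payoffs, TRUE, eps),
       p = p)
}

#' Total fitnesses at a population composition
#'
#' With `K` individuals of the first type in a population of `n`, each first-
#' type individual meets `K - 1` copies of itself and `n - K` residents:
#' `f1 = (K-1) A11 + (n-K) A12`; each resident meets `K` first-type players
#' and `n - K - 1` other residents: `f2 = K A21 + (n-K-1) A22`.
#'
#' @param A A [composition_payoffs()] list.
#' @param K Number of first-type individuals, `1 <= K <= n - 1`.
#' @param n Population size.
#' @return Named vector `c(f1, f2)`.
#' @export
fitnesses <- function(A, K, n) {
  stopifnot(n >= 2, K >= 1, K <= n - 1)
  c(f1 = (K - 1) * A$A11 + (n - K) * A$A12,
    f2 = K * A$A21 + (n - K - 1) * A$A22)
}

# Moran birth-death transition probabilities at composition K.
moran_transitions <- function(A, K, n) {
  f <- fitnesses(A, K, n)
  tot <- K * f[["f1"]] + (n - K) * f[["f2"]]
  c(down = (n - K) * f[["f2"]] / tot * K / n,
    up   = K * f[["f1"]] / tot * (n - K) / n)
}

#' Fixation probability of the first type
#'
#' Exact fixation probability of `K0` first-type individuals in a Moran
#' process whose payoff matrix may change with the composition: with
#' `gamma_i = p_{i,i-1} / p_{i,i+1}` computed from the composition-`i` payoff
#' matrix,
#' \deqn{x_{K_0} = \frac{1 + \sum_{j=1}^{K_0-1} \prod_{i=1}^j \gamma_i}
#'   {1 + \sum_{j=1}^{n-1} \prod_{i=1}^j \gamma_i}.}
#'
#' @param A_by_K List of [composition_payoffs()] indexed by composition
#'   `K = 1, ..., n-1` (a single list is recycled for a composition-
#'   independent, i.e. static, player).
#' @param n Population size.
#' @param K0 Starting number of first-type individuals (0..n allowed; 0 and
#'   `n` return 0 and 1 by convention).
#' @return Fixation probability in `[0, 1]`.
#' @examples
#' A <- composition_payoffs(c(0, 0, 0, 0), c(1, 1, 1, 1))
#' fixation_probability(list(A, A, A), n = 4, K0 = 1)
#' @export
fixation_probability <- function(A_by_K, n, K0) {
  stopifnot(n >= 2, K0 >= 0, K0 <= n)
  if (K0 == 0) return(0)
  if (K0 == n) return(1)
  if (!is.null(A_by_K$A11)) A_by_K <- rep(list(A_by_K), n - 1L)
  stopifnot(length(A_by_K) == n - 1L)
  gam <- vapply(seq_len(n - 1L), function(i) {
    tr <- moran_transitions(A_by_K[[i]], i, n)
    if (tr[["up"]] <= 0) {
      stop("absorbing boundary: upward transition probability is zero",
           call. = FALSE)
    }
    tr[["down"]] / tr[["up"]]
  }, numeric(1))
  cp <- cumprod(gam)
  (1 + sum(cp[seq_len(K0 - 1L)])) / (1 + sum(cp))
}

#' Dynamic versus static best-response player in a Moran process
#'
#' For each composition `K = 1, ..., n-1`, the dynamic player re-solves its
#' best response to the resident `q` with self-interaction weight `K - 1`
#' (each first-type individual meets `K - 1` copies of itself) by
#' [best_response_dynamics()], and the resulting per-composition payoff
#' matrices give its fixation probabilities `x_K`. The static comparator
#' freezes the strategy computed at composition `K0` and reuses it at every
#' composition, giving `x_tilde_K`. The ratio `x_K / x_tilde_K` measures the
#' value of adapting to the population density.
#'
#' @param q Resident memory-one strategy.
#' @param n Population size (default 4, the smallest exposing `K = 1, 2, 3`).
#' @param payoffs A [pd_payoffs()] object.
#' @param K0 Composition at which the static player's strategy is computed.
#' @param seed Integer seed for the best-response dynamics.
#' @param tol,max_iter,n_starts Passed to [best_response_dynamics()].
#' @return A list with `table` (data.frame of `K`, `x_dynamic`, `x_static`,
#'   `ratio`), `strategies` (the per-composition dynamic strategies) and
#'   `static_strategy`.
#' @export
dynamic_moran_experiment <- function(q, n = 4L, payoffs = pd_payoffs(),
                                     K0 = 1L, seed = 1L, tol = 1e-4,
                                     max_iter = 50L, n_starts = 16L) {
  stopifnot(n >= 2L, K0 >= 1L, K0 <= n - 1L)
  q <- as_strategy(q, "q")
  strategies <- lapply(seq_len(n - 1L), function(K) {
    best_response_dynamics(q, K = K - 1L, payoffs, tol = tol,
                           max_iter = max_iter, seed = seed + K,
                           n_starts = n_starts)
  })
  A_dyn <- lapply(strategies, function(p)
    composition_payoffs(as.numeric(p), q, payoffs))
  p_static <- as.numeric(strategies[[K0]])
  A_stat <- composition_payoffs(p_static, q, payoffs)
  x_dyn <- vapply(seq_len(n - 1L), function(K)
    fixation_probability(A_dyn, n, K), numeric(1))
  x_stat <- vapply(seq_len(n - 1L), function(K)
    fixation_probability(A_stat, n, K), numeric(1))
  list(
    table = data.frame(K = seq_len(n - 1L), x_dynamic = x_dyn,
                       x_static = x_stat, ratio = x_dyn / x_stat),
    strategies = lapply(strategies, as.numeric),
    static_strategy = p_static
  )
}
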