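#' Quadratic-form coefficients of the long-run utility
#'
#' The long-run utility of a memory-one strategy `p` against a fixed
#' memory-one opponent `q` is a ratio of two quadratic forms in `p`:
#' \deqn{u_q(p) = \frac{\tfrac12 p Q p^T + c p + a}{\tfrac12 p \bar Q p^T +
#'   \bar c p + \bar a},}
#' where the matrices `Q`, `Qbar` (symmetric, zero diagonal), vectors `c`,
#' `cbar` and scalars `a`, `abar` are polynomial in the opponent's cooperation
#' probabilities and the payoffs. This function evaluates those closed forms.
#'
#' @param q Opponent memory-one strategy.
#' @param payoffs A [pd_payoffs()] object.
#' @return An object of class `quad_coefs`: list with elements `Q`, `c`, `a`
#'   (numerator) and `Qbar`, `cbar`, `abar` (denominator).
#' @examples
#' co <- quadratic_coefficients(c(1, 1, 1, 1))
#' co$a     # 5 with default payoffs
#' co$abar  # 1
#' @export
quadratic_coefficients <- function(q, payoffs = pd_payoffs()) {
  payoffs <- as_payoffs(payoffs)
  q <- as_strategy(q, "q")
  R <- payoffs$R; S <- payoffs$S; T <- payoffs$T; P <- payoffs$P
  q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]

  Q <- matrix(0, 4, 4)
  Q[1, 2] <- -(q1 - q3) * (P * q2 - P - T * q4)
  Q[1, 3] <- (q1 - q2) * (P * q3 - S * q4)
  Q[1, 4] <- (q1 - q4) * (S * q2 - S - T * q3)
  Q[2, 3] <- (q2 - q3) * (P * q1 - P - R * q4)
  Q[2, 4] <- -(q3 - q4) * (R * q2 - R - T * q1 + T)
  Q[3, 4] <- (q2 - q4) * (R * q3 - S * q1 + S)
  Q <- Q + t(Q)

  Qbar <- matrix(0, 4, 4)
  Qbar[1, 2] <- -(q1 - q3) * (q2 - q4 - 1)
  Qbar[1, 3] <- (q1 - q2) * (q3 - q4)
  Qbar[1, 4] <- (q1 - q4) * (q2 - q3 - 1)
  Qbar[2, 3] <- (q2 - q3) * (q1 - q4 - 1)
  Qbar[2, 4] <- (q1 - q2) * (q3 - q4)
  Qbar[3, 4] <- -(q2 - q4) * (q1 - q3 - 1)
  Qbar <- Qbar + t(Qbar)

  cc <- c(
    q1 * (P * q2 - P - T * q4),
    -(q3 - 1) * (P * q2 - P - T * q4),
    -P * q1 * q2 + P * q2 * q3 + P * q2 - P * q3 + R * q2 * q4 -
      S * q2 * q4 + S * q4,
    -R * q2 * q4 + R * q4 + S * q2 * q4 - S * q2 - S * q4 + S +
      T * q1 * q4 - T * q3 * q4 + T * q3 - T * q4
  )

  cbar <- c(
    q1 * (q2 - q4 - 1),
    -(q3 - 1) * (q2 - q4 - 1),
    -q1 * q2 + q2 * q3 + q2 - q3 + q4,
    q1 * q4 - q2 - q3 * q4 + q3 - q4 + 1
  )

  a <- -P * q2 + P + T * q4
  abar <- -q2 + q4 + 1

  structure(list(Q = Q, c = cc, a = a, Qbar = Qbar, cbar = cbar, abar = abar),
            class = "quad_coefs")
}

# Numerator and denominator values of u_q(p) given precomputed coefficients.
quad_parts <- function(p, co) {
  num <- 0.5 * sum(p * (co$Q %*% p)) + sum(co$c * p) + co$a
  den <- 0.5 * sum(p * (co$Qbar %*% p)) + sum(co$cbar * p) + co$abar
  c(num = num, den = den)
}

undefined_utility <- function(msg) {
  stop(structure(
    class = c("memone_undefined_utility", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Long-run utility via the quadratic-form closed form
#'
#' Evaluates the ratio of quadratic forms of [quadratic_coefficients()]. The
#' result equals [utility_markov()] wherever the match chain is ergodic; the
#' denominator vanishes exactly when the chain is degenerate.
#'
#' @inheritParams utility_markov
#' @param denom_tol Matches with denominator magnitude at or below this are
#'   treated as degenerate (default `1e-12`).
#' @return The long-run mean payoff per round.
#' @examples
#' utility_quadratic(c(0, 0, 0, 0), c(1, 1, 1, 1))  # 5
#' @export
utility_quadratic <- function(p, q, payoffs = pd_payoffs(), denom_tol = 1e-12) {
  p <- as_strategy(p, "p")
  co <- quadratic_coefficients(q, payoffs)
  parts <- quad_parts(p, co)
  if (abs(parts["den"]) <= denom_tol) {
    undefined_utility("undefined utility: quadratic-form denominator vanishes (degenerate match)")
  }
  unname(parts["num"] / parts["den"])
}

# ---- weighted multi-opponent machinery (internal) --------------------------
#
# All multi-opponent operations reduce to the weighted objective
#   U(p) = sum_i w_i u_{q^(i)}(p),
# with w_i = 1/N for the tournament mean and an extra frozen-self opponent
# with weight K for the Moran objective.

precompute_coefs <- function(opponents, payoffs) {
  opponents <- as_opponent_matrix(opponents)
  lapply(seq_len(nrow(opponents)), function(i) {
    quadratic_coefficients(opponents[i, ], payoffs)
  })
}

weighted_utility <- function(p, coefs, weights, denom_tol = 1e-12) {
  total <- 0
  for (i in seq_along(coefs)) {
    parts <- quad_parts(p, coefs[[i]])
    if (abs(parts["den"]) <= denom_tol) {
      undefined_utility(sprintf(
        "undefined utility against opponent %d: denominator vanishes", i))
    }
    total <- total + weights[i] * parts["num"] / parts["den"]
  }
  unname(total)
}

weighted_gradient <- function(p, coefs, weights, denom_tol = 1e-12) {
  g <- numeric(4)
  for (i in seq_along(coefs)) {
    co <- coefs[[i]]
    num <- 0.5 * sum(p * (co$Q %*% p)) + sum(co$c * p) + co$a
    den <- 0.5 * sum(p * (co$Qbar %*% p)) + sum(co$cbar * p) + co$abar
    if (abs(den) <= denom_tol) {
      undefined_utility(sprintf(
        "undefined gradient against opponent %d: denominator vanishes", i))
    }
    dnum <- drop(co$Q %*% p) + co$c
    dden <- drop(co$Qbar %*% p) + co$cbar
    g <- g + weights[i] * (dnum * den - dden * num) / den^2
  }
  g
}

#' Mean utility against a set of opponents
#'
#' Average long-run payoff of `p` over a set of `N` memory-one opponents,
#' `1/N * sum_i u_{q^(i)}(p)`, the tournament objective.
#'
#' @param p Memory-one strategy.
#' @param opponents One strategy (numeric 4-vector), a list of strategies, or
#'   an `N x 4` matrix with one opponent per row.
#' @param payoffs A [pd_payoffs()] object.
#' @param denom_tol Degeneracy tolerance per opponent; see
#'   [utility_quadratic()].
#' @return Mean long-run payoff, a number in `[S, T]`.
#' @examples
#' mean_utility(c(0, 0, 0, 0), rbind(c(1, 1, 1, 1), c(0, 0, 0, 0)))  # (5+1)/2
#' @export
mean_utility <- function(p, opponents, payoffs = pd_payoffs(),
                         denom_tol = 1e-12) {
  p <- as_strategy(p, "p")
  coefs <- precompute_coefs(opponents, payoffs)
  weighted_utility(p, coefs, rep(1 / length(coefs), length(coefs)), denom_tol)
}

#' Gradient of the summed utility
#'
#' Quotient-rule gradient of `sum_i u_{q^(i)}(p)` with respect to the four
#' coordinates of `p`. Divide by `N` for the gradient of [mean_utility()]
#' (the argmax is unaffected).
#'
#' @inheritParams mean_utility
#' @return Numeric gradient of length 4.
#' @export
utility_gradient <- function(p, opponents, payoffs = pd_payoffs(),
                             denom_tol = 1e-12) {
  p <- as_strategy(p, "p")
  coefs <- precompute_coefs(opponents, payoffs)
  weighted_gradient(p, coefs, rep(1, length(coefs)), denom_tol)
}

#' Cleared-denominator stationarity residual
#'
#' The polynomial 4-vector
#' \deqn{\sum_i (pQ^{(i)} + c^{(i)}) D_i(p) - (p\bar Q^{(i)} + \bar c^{(i)})
#'   N_i(p),}
#' where `N_i`, `D_i` are the numerator and denominator quadratics of opponent
#' `i`. For a single opponent this is the utility gradient with the (positive)
#' squared denominator cleared, so it vanishes exactly at the stationary
#' points where the denominator is nonzero; unlike the gradient it is defined
#' everywhere. For several opponents each term clears only its own
#' denominator, so the residual is a per-opponent identity check rather than
#' the exact first-order condition.
#'
#' @inheritParams mean_utility
#' @return Numeric vector of length 4.
#' @export
stationarity_residual <- function(p, opponents, payoffs = pd_payoffs()) {
  p <- as_strategy(p, "p")
  coefs <- precompute_coefs(opponents, payoffs)
  r <- numeric(4)
  for (co in coefs) {
    num <- 0.5 * sum(p * (co$Q %*% p)) + sum(co$c * p) + co$a
    den <- 0.5 * sum(p * (co$Qbar %*% p)) + sum(co$cbar * p) + co$abar
    dnum <- drop(co$Q %*% p) + co$c
    dden <- drop(co$Qbar %*% p) + co$cbar
    r <- r + dnum * den - dden * num
  }
  r
}
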