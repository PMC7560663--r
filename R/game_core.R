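#' Prisoner's Dilemma payoff values
#'
#' Container for the four payoffs of the Prisoner's Dilemma: `R` (reward for
#' mutual cooperation), `S` (sucker's payoff), `T` (temptation to defect) and
#' `P` (punishment for mutual defection). The constructor enforces the usual
#' dilemma ordering `T > R > P > S` and the iterated-game condition
#' `2R > T + S` (so that alternating exploitation does not beat mutual
#' cooperation).
#'
#' @param R Reward for mutual cooperation. Default 3.
#' @param P Punishment for mutual defection. Default 1.
#' @param S Sucker's payoff. Default 0.
#' @param T Temptation payoff. Default 5.
#'
#' @return An object of class `pd_payoffs`: a named list with elements
#'   `R`, `S`, `T`, `P` and `vec`, the payoff vector `(R, S, T, P)` ordered by
#'   the states (CC, CD, DC, DD) of the focal player.
#' @examples
#' pd_payoffs()            # the conventional (R, P, S, T) = (3, 1, 0, 5)
#' pd_payoffs(R = 4, T = 6)
#' @export
pd_payoffs <- function(R = 3, P = 1, S = 0, T = 5) {
  vals <- c(R = R, P = P, S = S, T = T)
  if (!all(is.finite(vals))) {
    stop("payoff values must be finite numbers", call. = FALSE)
  }
  if (!(T > R && R > P && P > S)) {
    stop("invalid payoffs: the ordering T > R > P > S must hold", call. = FALSE)
  }
  if (!(2 * R > T + S)) {
    stop("invalid payoffs: 2R > T + S must hold", call. = FALSE)
  }
  structure(
    list(R = R, S = S, T = T, P = P, vec = c(R, S, T, P)),
    class = "pd_payoffs"
  )
}

#' @export
print.pd_payoffs <- function(x, ...) {
  cat(sprintf("PD payoffs: R = %g, S = %g, T = %g, P = %g\n", x$R, x$S, x$T, x$P))
  invisible(x)
}

as_payoffs <- function(payoffs) {
  if (inherits(payoffs, "pd_payoffs")) return(payoffs)
  if (is.numeric(payoffs) && length(payoffs) == 4L) {
    # accept (R, P, S, T) in the conventional printing order
    return(pd_payoffs(R = payoffs[[1]], P = payoffs[[2]],
                      S = payoffs[[3]], T = payoffs[[4]]))
  }
  stop("payoffs must be a pd_payoffs object or a numeric (R, P, S, T) vector",
       call. = FALSE)
}

#' Validate a memory-one strategy vector
#'
#' A memory-one strategy is a point in the unit 4-cube: the probability of
#' cooperating after each of the four outcomes of the previous round, ordered
#' (CC, CD, DC, DD) from the focal player's perspective.
#'
#' @param p Numeric vector of length 4.
#' @param arg Name used in error messages.
#' @return The validated strategy as a plain numeric vector of length 4.
#' @examples
#' as_strategy(c(1, 0, 1, 0))  # Tit-for-Tat
#' @export
as_strategy <- function(p, arg = "p") {
  p <- as.numeric(p)
  if (length(p) != 4L || anyNA(p)) {
    stop(sprintf("invalid strategy '%s': need 4 non-missing probabilities", arg),
         call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    stop(sprintf("invalid strategy '%s': coordinates must lie in [0, 1]", arg),
         call. = FALSE)
  }
  p
}

# Coerce an opponent set (4-vector, list of 4-vectors, or N x 4 matrix /
# data.frame) into an N x 4 matrix with validated rows.
as_opponent_matrix <- function(opponents) {
  if (is.numeric(opponents) && is.null(dim(opponents))) {
    opponents <- matrix(as_strategy(opponents, "opponent"), nrow = 1L)
  } else if (is.list(opponents) && !is.data.frame(opponents)) {
    opponents <- do.call(rbind, lapply(opponents, as_strategy, arg = "opponent"))
  } else {
    opponents <- as.matrix(opponents)
  }
  if (ncol(opponents) != 4L) {
    stop("opponents must have 4 columns (one memory-one strategy per row)",
         call. = FALSE)
  }
  for (i in seq_len(nrow(opponents))) {
    as_strategy(opponents[i, ], sprintf("opponent %d", i))
  }
  unname(opponents)
}

#' Trembling-hand perturbation of a strategy
#'
#' Maps every coordinate `x` to `x * (1 - 2 * eps) + eps`, pulling the strategy
#' off the boundary of the cube. Deterministic strategy pairs induce reducible
#' Markov chains with no unique stationary distribution; this standard
#' perturbation yields the trembling-hand limit of their long-run payoffs.
#'
#' @param p Memory-one strategy.
#' @param eps Perturbation size, default `1e-6`.
#' @return The perturbed strategy.
#' @export
perturb_strategy <- function(p, eps = 1e-6) {
  p <- as_strategy(p)
  p * (1 - 2 * eps) + eps
}

#' Transition matrix of a memory-one match
#'
#' The play of two memory-one strategies is a Markov chain on the four states
#' (CC, CD, DC, DD), labelled from the focal player's perspective. Row `s`
#' gives the distribution of the next state following state `s`. The
#' opponent's view of states CD and DC is transposed, so its second and third
#' coordinates enter the second and third rows swapped.
#'
#' @param p Focal player's memory-one strategy.
#' @param q Opponent's memory-one strategy.
#' @return A 4x4 row-stochastic matrix with rows and columns named
#'   (CC, CD, DC, DD).
#' @examples
#' transition_matrix(c(1, 0, 1, 0), c(1, 1, 1, 1))
#' @export
transition_matrix <- function(p, q) {
  p <- as_strategy(p, "p")
  q <- as_strategy(q, "q")
  # opponent reacts to its own state labels: its CD is our DC and vice versa
  qq <- c(q[1], q[3], q[2], q[4])
  M <- cbind(
    p * qq,
    p * (1 - qq),
    (1 - p) * qq,
    (1 - p) * (1 - qq)
  )
  dimnames(M) <- list(c("CC", "CD", "DC", "DD"), c("CC", "CD", "DC", "DD"))
  M
}

#' Stationary distribution of a match transition matrix
#'
#' Solves `v M = v`, `sum(v) = 1` by replacing one equation of the singular
#' system with the normalisation row. A chain whose stationary eigenspace has
#' dimension greater than one (e.g. two deterministic strategies locking into
#' different absorbing states depending on the opening) has no unique
#' long-run distribution and raises a `memone_degenerate_chain` error, so that
#' callers can fall back to [perturb_strategy()].
#'
#' @param M A 4x4 row-stochastic matrix, e.g. from [transition_matrix()].
#' @param tol Singular-value tolerance used to detect a multi-dimensional
#'   stationary eigenspace. Default `1e-8`.
#' @return Stationary probability vector of length 4 over (CC, CD, DC, DD).
#' @export
steady_state <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == 4L, ncol(M) == 4L)
  rs <- rowSums(M)
  if (any(M < -1e-12) || any(M > 1 + 1e-12) || any(abs(rs - 1) > 1e-10)) {
    stop("M is not row-stochastic", call. = FALSE)
  }
  A <- t(M) - diag(4)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sum(sv < tol) > 1L) {
    stop(structure(
      class = c("memone_degenerate_chain", "error", "condition"),
      list(message = "degenerate chain: stationary distribution is not unique",
           call = sys.call(-1))
    ))
  }
  B <- A
  B[4, ] <- 1                       # replace one redundant equation
  v <- solve(B, c(0, 0, 0, 1))
  v[v < 0 & v > -1e-12] <- 0        # clip tiny negative round-off
  v <- v / sum(v)
  names(v) <- c("CC", "CD", "DC", "DD")
  v
}

#' Long-run utility via the Markov chain
#'
#' Expected payoff per round of strategy `p` against memory-one opponent `q`:
#' the stationary distribution of the match chain dotted with the focal
#' player's payoff vector `(R, S, T, P)`.
#'
#' @inheritParams transition_matrix
#' @param payoffs A [pd_payoffs()] object (or `(R, P, S, T)` numeric vector).
#' @param perturb If `TRUE`, apply [perturb_strategy()] with `eps` to both
#'   players before solving, so that deterministic pairs get their
#'   trembling-hand limit instead of an error. Default `FALSE`.
#' @param eps Perturbation size used when `perturb = TRUE`.
#' @return The long-run mean payoff per round, a number in `[S, T]`.
#' @examples
#' utility_markov(c(0, 0, 0, 0), c(1, 1, 1, 1))  # defector vs cooperator: 5
#' @export
utility_markov <- function(p, q, payoffs = pd_payoffs(), perturb = FALSE,
                           eps = 1e-6) {
  payoffs <- as_payoffs(payoffs)
  p <- as_strategy(p, "p")
  q <- as_strategy(q, "q")
  if (perturb) {
    p <- perturb_strategy(p, eps)
    q <- perturb_strategy(q, eps)
  }
  v <- steady_state(transition_matrix(p, q))
  sum(v * payoffs$vec)
}
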