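#' Solver settings for the candidate-set best response
#'
#' @param n_starts Latin-hypercube start points per face of the cube (a
#'   deterministic centre start is always added). Default 32.
#' @param merge_tol Stationary points closer than this (sup norm) are merged.
#' @param grad_tol Acceptance threshold on the sup norm of the restricted
#'   gradient at a returned stationary point.
#' @param denom_tol Degeneracy tolerance on per-opponent denominators.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(n_starts = 32L, merge_tol = 1e-6, grad_tol = 1e-8,
                           denom_tol = 1e-12) {
  structure(list(n_starts = as.integer(n_starts), merge_tol = merge_tol,
                 grad_tol = grad_tol, denom_tol = denom_tol),
            class = "solver_control")
}

#' The 16 vertices of the strategy cube
#'
#' Deterministic memory-one strategies: every 0/1 assignment of the four
#' cooperation probabilities.
#'
#' @return A 16 x 4 matrix, one vertex per row.
#' @export
vertex_candidates <- function() {
  as.matrix(expand.grid(p1 = c(0, 1), p2 = c(0, 1),
                        p3 = c(0, 1), p4 = c(0, 1)))
}

# Maximise the weighted utility restricted to one face of the cube
# (coordinates in J pinned at `assignment`, the rest free in (0,1)),
# from multiple seeded starts. Returns accepted interior stationary points.
face_stationary_points <- function(coefs, weights, J, assignment, control) {
  K <- setdiff(1:4, J)
  if (length(K) == 0L) return(list())
  d <- length(K)

  embed <- function(x) {
    p <- numeric(4)
    p[J] <- assignment
    p[K] <- x
    p
  }
  fn <- function(x) {
    tryCatch(weighted_utility(embed(x), coefs, weights, control$denom_tol),
             memone_undefined_utility = function(e) -1e6)
  }
  gr <- function(x) {
    tryCatch(weighted_gradient(embed(x), coefs, weights, control$denom_tol)[K],
             memone_undefined_utility = function(e) numeric(d))
  }

  starts <- rbind(rep(0.5, d),
                  if (control$n_starts > 0L) lhs::randomLHS(control$n_starts, d))
  found <- list()
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], fn, gr, method = "L-BFGS-B",
                   lower = rep(0, d), upper = rep(1, d),
                   control = list(fnscale = -1, maxit = 200L,
                                  factr = 10, pgtol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next                       # non-convergence: drop start
    x <- fit$par
    if (any(x < 1e-9) || any(x > 1 - 1e-9)) next # boundary: finer face owns it
    g <- gr(x)
    if (max(abs(g)) >= control$grad_tol) next
    dup <- any(vapply(found, function(f) max(abs(f - x)) < control$merge_tol,
                      logical(1)))
    if (!dup) found[[length(found) + 1L]] <- x
  }
  lapply(found, embed)
}

# Weighted candidate set shared by the public tournament interface and the
# Moran self-interaction objective. Returns a data.frame of candidates with
# objectives; candidates whose utility is undefined against any opponent are
# excluded.
candidate_set_weighted <- function(opponents, weights, payoffs, control) {
  opponents <- as_opponent_matrix(opponents)
  coefs <- precompute_coefs(opponents, payoffs)

  rows <- list()
  add <- function(p, prov) {
    obj <- tryCatch(weighted_utility(p, coefs, weights, control$denom_tol),
                    memone_undefined_utility = function(e) NA_real_)
    if (is.na(obj)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
      objective = obj, provenance = prov, stringsAsFactors = FALSE)
  }

  V <- vertex_candidates()
  for (i in seq_len(nrow(V))) add(V[i, ], "vertex")

  subsets <- unlist(lapply(0:3, function(k) utils::combn(4, k, simplify = FALSE)),
                    recursive = FALSE)
  for (J in subsets) {
    assigns <- if (length(J) == 0L) {
      list(numeric(0))
    } else {
      asplit(as.matrix(expand.grid(rep(list(c(0, 1)), length(J)))), 1)
    }
    for (a in assigns) {
      prov <- if (length(J) == 0L) "interior" else
        sprintf("J={%s};a=(%s)", paste(J, collapse = ","),
                paste(a, collapse = ","))
      pts <- face_stationary_points(coefs, weights, J, as.numeric(a), control)
      for (p in pts) add(p, prov)
    }
  }
  do.call(rbind, rows)
}

#' Interior stationary points on one face of the cube
#'
#' Pins the coordinates in `J` at a 0/1 `assignment` and finds the strategies
#' in the open face `(0,1)^|K|` (with `K` the complement of `J`) at which the
#' restricted gradient of the mean utility vanishes, by multi-start bounded
#' quasi-Newton ascent. Start points that fail to converge, converge to the
#' face boundary, or land where the gradient is not numerically zero are
#' dropped; near-duplicate solutions are merged.
#'
#' @inheritParams mean_utility
#' @param J Integer subset of `1:4`: coordinates to pin.
#' @param assignment 0/1 values for the pinned coordinates (same length as
#'   `J`).
#' @param control A [solver_control()] list.
#' @return List of full strategies (length-4 vectors) with the pinned values
#'   held exactly.
#' @export
partition_candidates <- function(opponents, J, assignment,
                                 payoffs = pd_payoffs(),
                                 control = solver_control()) {
  stopifnot(length(J) == length(assignment), all(J %in% 1:4),
            all(assignment %in% c(0, 1)), length(J) < 4L)
  opponents <- as_opponent_matrix(opponents)
  coefs <- precompute_coefs(opponents, payoffs)
  weights <- rep(1 / length(coefs), length(coefs))
  face_stationary_points(coefs, weights, J, assignment, control)
}

#' Discrete candidate set for the best-response search
#'
#' The candidate set containing every possible best response to a set of
#' memory-one opponents: the 16 vertices of the cube together with, for every
#' proper subset `J` of coordinates and every 0/1 assignment on `J`, the
#' interior stationary points of the mean utility on that face. The optimum
#' of the (non-concave) mean utility over the cube always lies in this set.
#'
#' @inheritParams partition_candidates
#' @return A data.frame with columns `p1..p4`, `objective` (mean utility) and
#'   `provenance` (`"vertex"`, `"interior"`, or the pinned face).
#' @examples
#' cs <- candidate_set(c(1, 1, 1, 1), control = solver_control(n_starts = 4))
#' max(cs$objective)  # 5: defect against a cooperator
#' @export
candidate_set <- function(opponents, payoffs = pd_payoffs(),
                          control = solver_control()) {
  opponents <- as_opponent_matrix(opponents)
  weights <- rep(1 / nrow(opponents), nrow(opponents))
  candidate_set_weighted(opponents, weights, payoffs, control)
}

new_best_response <- function(p_star, objective, method, examined, diagnostics) {
  structure(list(p_star = as.numeric(p_star), objective = objective,
                 method = method, candidates_examined = examined,
                 diagnostics = diagnostics),
            class = "best_response")
}

#' @export
print.best_response <- function(x, ...) {
  cat(sprintf("Best response (%s): p* = (%s), mean utility %.6f\n",
              x$method, paste(signif(x$p_star, 6), collapse = ", "),
              x$objective))
  invisible(x)
}

# Pick the maximal-objective row; ties within tol broken by lexicographically
# smallest strategy vector.
argmax_candidates <- function(cands, tol = 1e-9) {
  best <- max(cands$objective)
  top <- cands[cands$objective >= best - tol, , drop = FALSE]
  ord <- do.call(order, as.list(top[, c("p1", "p2", "p3", "p4")]))
  top[ord[1L], ]
}

#' Best response by candidate-set enumeration
#'
#' Builds [candidate_set()] and returns the candidate with maximal mean
#' utility; ties (within 1e-9) are broken toward the lexicographically
#' smallest strategy vector. The reported objective is re-evaluated through
#' [mean_utility()].
#'
#' @inheritParams partition_candidates
#' @return A `best_response` object with elements `p_star`, `objective`,
#'   `method = "candidates"`, `candidates_examined` and `diagnostics`.
#' @examples
#' best_response_candidates(c(1, 1, 1, 1),
#'                          control = solver_control(n_starts = 4))
#' @export
best_response_candidates <- function(opponents, payoffs = pd_payoffs(),
                                     control = solver_control()) {
  opponents <- as_opponent_matrix(opponents)
  cands <- candidate_set(opponents, payoffs, control)
  if (is.null(cands) || nrow(cands) == 0L) {
    stop("degenerate problem: empty candidate set after degeneracy filtering",
         call. = FALSE)
  }
  top <- argmax_candidates(cands)
  p_star <- as.numeric(top[1, c("p1", "p2", "p3", "p4")])
  new_best_response(
    p_star,
    mean_utility(p_star, opponents, payoffs),
    "candidates", nrow(cands),
    list(provenance = top$provenance, n_starts = control$n_starts))
}

#' Best response by seeded Bayesian optimisation
#'
#' Global-optimisation estimate of the best-response strategy over the cube:
#' Gaussian-process expected-improvement search on [mean_utility()], followed
#' by a projected-gradient polish of the incumbent using the analytic
#' gradient. Points where the utility is undefined (degenerate matches) are
#' evaluated in the trembling-hand limit via [perturb_strategy()].
#'
#' @inheritParams partition_candidates
#' @param budget Total number of objective evaluations (must be at least 20).
#' @param seed Integer seed; the result is a deterministic function of it.
#' @param n_init Size of the initial Latin-hypercube design.
#' @return A `best_response` object with `method = "bayesian"`.
#' @export
best_response_bayesian <- function(opponents, payoffs = pd_payoffs(),
                                   budget = 64L, seed = 1L, n_init = 16L) {
  stopifnot(budget >= 20L)
  opponents <- as_opponent_matrix(opponents)
  coefs <- precompute_coefs(opponents, payoffs)
  weights <- rep(1 / length(coefs), length(coefs))
  safe_u <- function(p) {
    tryCatch(weighted_utility(p, coefs, weights),
             memone_undefined_utility = function(e)
               weighted_utility(perturb_strategy(p), coefs, weights))
  }
  res <- withr::with_seed(seed, {
    opt <- gp_ei_optimise(safe_u, d = 4L, budget = budget, n_init = n_init)
    gr <- function(p) {
      tryCatch(weighted_gradient(p, coefs, weights),
               memone_undefined_utility = function(e) numeric(4))
    }
    polish <- tryCatch(
      stats::optim(opt$x, safe_u, gr, method = "L-BFGS-B",
                   lower = rep(0, 4), upper = rep(1, 4),
                   control = list(fnscale = -1, factr = 10, pgtol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value > opt$y) {
      list(x = polish$par, evaluations = opt$evaluations)
    } else {
      list(x = opt$x, evaluations = opt$evaluations)
    }
  })
  p_star <- pmin(pmax(res$x, 0), 1)
  obj <- tryCatch(mean_utility(p_star, opponents, payoffs),
                  memone_undefined_utility = function(e)
                    mean_utility(perturb_strategy(p_star), opponents, payoffs))
  new_best_response(p_star, obj, "bayesian", res$evaluations,
                    list(seed = seed, budget = budget))
}

#' Exhaustive grid search (test oracle)
#'
#' Evaluates the mean utility on the regular grid `{0, r, 2r, ..., 1}^4` and
#' returns the maximising point. Vectorised; intended as an independent check
#' on the candidate-set search, not for production use.
#'
#' @inheritParams partition_candidates
#' @param resolution Grid step `r` in `(0, 0.5]`.
#' @return A `best_response` object with `method = "grid"`.
#' @export
grid_oracle <- function(opponents, payoffs = pd_payoffs(), resolution = 0.05) {
  stopifnot(resolution > 0, resolution <= 0.5)
  opponents <- as_opponent_matrix(opponents)
  payoffs <- as_payoffs(payoffs)
  vals <- seq(0, 1, by = resolution)
  if (vals[length(vals)] < 1) vals <- c(vals, 1)
  G <- as.matrix(expand.grid(vals, vals, vals, vals))
  total <- numeric(nrow(G))
  ok <- rep(TRUE, nrow(G))
  for (i in seq_len(nrow(opponents))) {
    co <- quadratic_coefficients(opponents[i, ], payoffs)
    num <- 0.5 * rowSums((G %*% co$Q) * G) + drop(G %*% co$c) + co$a
    den <- 0.5 * rowSums((G %*% co$Qbar) * G) + drop(G %*% co$cbar) + co$abar
    ok <- ok & abs(den) > 1e-12
    total <- total + ifelse(ok, num / den, NA_real_)
  }
  total <- total / nrow(opponents)
  idx <- which.max(ifelse(ok, total, -Inf))
  new_best_response(G[idx, ], total[idx], "grid", sum(ok),
                    list(resolution = resolution, grid_points = nrow(G)))
}
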