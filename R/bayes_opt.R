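# Compact Gaussian-process expected-improvement optimiser over the unit box.
#
# Maximises a deterministic black-box objective with a small evaluation
# budget: squared-exponential kernel with a median-distance lengthscale,
# expected improvement maximised over a seeded candidate pool (fresh Latin
# hypercube draws plus local jitter around the incumbent). Used for the
# best-response and Gambler optimisation problems; consumes the caller's RNG
# stream, so wrap calls in a seed for reproducibility.

gp_ei_optimise <- function(fn, d, budget = 64L, n_init = 16L,
                           init = NULL, pool_n = 256L, xi = 0.01) {
  stopifnot(budget >= n_init + 1L)
  X <- lhs::randomLHS(n_init, d)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    X <- rbind(X, init)
  }
  y <- apply(X, 1, fn)

  sqdist <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }

  while (nrow(X) < budget) {
    ys <- stats::sd(y)
    if (!is.finite(ys) || ys < 1e-12) {
      x_new <- stats::runif(d)                 # flat so far: explore
    } else {
      yn <- (y - mean(y)) / ys
      D2 <- sqdist(X, X)
      ell <- sqrt(stats::median(D2[upper.tri(D2)]))
      if (!is.finite(ell) || ell < 1e-6) ell <- 0.5
      K <- exp(-D2 / (2 * ell^2)) + diag(1e-8, nrow(X))
      cK <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(cK)) {
        x_new <- stats::runif(d)
      } else {
        alpha <- backsolve(cK, forwardsolve(t(cK), yn))
        best_idx <- which.max(y)
        jitter <- matrix(
          pmin(pmax(rep(X[best_idx, ], each = 32L) +
                      stats::rnorm(32L * d, sd = 0.05), 0), 1),
          nrow = 32L)
        cand <- rbind(lhs::randomLHS(pool_n, d), jitter)
        Ks <- exp(-sqdist(cand, X) / (2 * ell^2))
        mu <- drop(Ks %*% alpha)
        V <- forwardsolve(t(cK), t(Ks))
        s2 <- pmax(1 - colSums(V^2), 1e-12)
        s <- sqrt(s2)
        imp <- mu - max(yn) - xi
        z <- imp / s
        ei <- imp * stats::pnorm(z) + s * stats::dnorm(z)
        x_new <- cand[which.max(ei), ]
      }
    }
    X <- rbind(X, x_new)
    y <- c(y, fn(x_new))
  }

  best <- which.max(y)
  list(x = X[best, ], y = y[best], X = X, y_all = y, evaluations = nrow(X))
}
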