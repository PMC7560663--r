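# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Central finite differences of sum_i u_{q^(i)}(p).
fd_gradient <- function(p, opponents, payoffs = pd_payoffs(), h = 1e-6) {
  opponents <- rbind(opponents)
  vapply(1:4, function(k) {
    e <- numeric(4); e[k] <- h
    up <- sum(apply(opponents, 1, function(q)
      utility_quadratic(p + e, q, payoffs)))
    dn <- sum(apply(opponents, 1, function(q)
      utility_quadratic(p - e, q, payoffs)))
    (up - dn) / (2 * h)
  }, numeric(1))
}

# Absorption probability of the birth-death Moran chain on states 0..n,
# solved as a linear system (first-step analysis), not via the gamma-product
# closed form.
absorption_oracle <- function(A_by_K, n, K0) {
  if (K0 == 0) return(0)
  if (K0 == n) return(1)
  P <- diag(n + 1)
  for (K in 1:(n - 1)) {
    A <- A_by_K[[K]]
    f1 <- (K - 1) * A$A11 + (n - K) * A$A12
    f2 <- K * A$A21 + (n - K - 1) * A$A22
    tot <- K * f1 + (n - K) * f2
    up <- (K * f1 / tot) * (n - K) / n
    down <- ((n - K) * f2 / tot) * K / n
    P[K + 1, K] <- down
    P[K + 1, K + 2] <- up
    P[K + 1, K + 1] <- 1 - up - down
  }
  idx <- 2:n
  x <- solve(diag(n - 1) - P[idx, idx, drop = FALSE], P[idx, n + 1])
  x[K0]
}

# Draw a strategy pair whose match chain is ergodic (interior coordinates).
random_ergodic_pair <- function() {
  list(p = runif(4, 0.02, 0.98), q = runif(4, 0.02, 0.98))
}
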