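#' Projection matrix onto the zero-determinant subspace
#'
#' Zero-determinant (ZD) memory-one strategies enforce a linear relation
#' between the two players' long-run scores. In the transformed coordinates
#' `pbar = (p1 - 1, p2 - 1, p3, p4)`, the ZD-consistent strategies form the
#' column space of a 4x2 matrix of payoff differences:
#' rows `(R-P, R-P)`, `(S-P, T-P)`, `(T-P, S-P)`, `(0, 0)`.
#'
#' @param payoffs A [pd_payoffs()] object.
#' @return A 4x2 numeric matrix of full column rank.
#' @examples
#' zd_projection_matrix()  # rows (2,2), (-1,4), (4,-1), (0,0)
#' @export
zd_projection_matrix <- function(payoffs = pd_payoffs()) {
  payoffs <- as_payoffs(payoffs)
  R <- payoffs$R; S <- payoffs$S; T <- payoffs$T; P <- payoffs$P
  matrix(c(R - P, R - P,
           S - P, T - P,
           T - P, S - P,
           0,     0),
         nrow = 4, byrow = TRUE)
}

#' Nearest zero-determinant strategy
#'
#' Least-squares projection of the transformed strategy vector `pbar` onto
#' the ZD subspace: `x* = (C'C)^{-1} C' pbar`, computed via a QR
#' factorisation rather than the explicit inverse. The squared residual of
#' the projection is the SSE statistic: zero exactly when the strategy is a
#' ZD strategy, large when its behaviour cannot be extortionate.
#'
#' @param p Memory-one strategy.
#' @param payoffs A [pd_payoffs()] object.
#' @return A list of class `zd_projection` with elements `pbar`, `C`,
#'   `x_star` (the nearest ZD coordinates), and `sse`.
#' @examples
#' nearest_zd(c(1, 0, 1, 0))$sse  # Tit-for-Tat is a ZD strategy: 0
#' @export
nearest_zd <- function(p, payoffs = pd_payoffs()) {
  p <- as_strategy(p, "p")
  C <- zd_projection_matrix(payoffs)
  qrC <- qr(C)
  if (qrC$rank < 2L) {
    stop("invalid payoffs: ZD projection matrix is rank deficient",
         call. = FALSE)
  }
  pbar <- c(p[1] - 1, p[2] - 1, p[3], p[4])
  x_star <- qr.coef(qrC, pbar)
  resid <- pbar - drop(C %*% x_star)
  structure(list(pbar = pbar, C = C, x_star = unname(x_star),
                 sse = sum(resid^2)),
            class = "zd_projection")
}

#' @export
print.zd_projection <- function(x, ...) {
  cat(sprintf("nearest ZD: x* = (%s), SSE = %.6g\n",
              paste(signif(x$x_star, 6), collapse = ", "), x$sse))
  invisible(x)
}

#' Squared distance from zero-determinant behaviour (SSE)
#'
#' The sum of squared errors of prediction: `pbar' pbar - pbar' C x*`, the
#' squared norm of the component of `pbar` outside the ZD subspace. A high
#' SSE implies non-extortionate behaviour.
#'
#' @inheritParams nearest_zd
#' @return A nonnegative number.
#' @examples
#' sse(c(1, 1, 0, 0))  # 0: pbar is the zero vector
#' sse(c(0, 1, 0, 1))
#' @export
sse <- function(p, payoffs = pd_payoffs()) {
  proj <- nearest_zd(p, payoffs)
  # matrix form of the statistic; equals the residual norm in `proj$sse`
  val <- sum(proj$pbar^2) - sum(proj$pbar * drop(proj$C %*% proj$x_star))
  max(val, 0)
}
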