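# Shared numerical helpers. Kept base-R and dependency-free because they sit
# under the likelihood hot path.

#' Log-density of a multivariate normal
#'
#' Evaluates rows of `x` under N(mu, sigma) via a Cholesky factor. Used by the
#' FIML engine and by test oracles; deliberately minimal.
#'
#' @param x numeric matrix (rows are observations) or a vector (one row).
#' @param mu mean vector, or a matrix of per-row means.
#' @param sigma covariance matrix.
#' @return numeric vector of log-densities.
#' @keywords internal
dmvnorm_log <- function(x, mu, sigma) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  p <- ncol(x)
  L <- chol(sigma)
  if (is.matrix(mu)) {
    ctr <- x - mu
  } else {
    ctr <- sweep(x, 2L, mu, "-")
  }
  z <- backsolve(L, t(ctr), transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(z^2)
}

#' Draw from a multivariate normal
#' @keywords internal
rmvnorm_chol <- function(n, mu, sigma) {
  p <- length(mu)
  L <- chol(sigma)  # upper triangular, sigma = t(L) %*% L
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% L, 2L, mu, "+")
}

#' Nudge a symmetric matrix onto the PD cone by flooring eigenvalues
#' @keywords internal
make_pd <- function(S, eps = 1e-8) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, eps * max(abs(ev$values), 1))
  ev$vectors %*% (lam * t(ev$vectors))
}

is_binary01 <- function(x) {
  !is.na(x) & (x == 0 | x == 1)
}

#' Central finite-difference gradient (test/verification helper)
#' @keywords internal
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    hi <- h * max(1, abs(x[i]))
    xp[i] <- xp[i] + hi
    xm[i] <- xm[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

`%||%` <- rlang::`%||%`
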