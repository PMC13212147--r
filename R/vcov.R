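# sem_fiml: sandwich variance with cluster-summed scores.

# Observed information (negative Hessian of the log-likelihood) at theta,
# by forward differences of the analytic gradient.
observed_information <- function(fit, h = 1e-6) {
  theta <- fit$theta
  K <- length(theta)
  g0 <- fiml_gradient_internal(theta, fit$map, fit$dat)
  H <- matrix(0, K, K)
  for (k in seq_len(K)) {
    th <- theta
    hk <- h * max(1, abs(theta[k]))
    th[k] <- th[k] + hk
    H[, k] <- (fiml_gradient_internal(th, fit$map, fit$dat) - g0) / hk
  }
  A <- -(H + t(H)) / 2
  dimnames(A) <- list(fit$map$labels, fit$map$labels)
  A
}

#' Cluster-robust sandwich covariance of the FIML estimates
#'
#' Computes `A^-1 B A^-1` where `A` is the observed information at the
#' estimates and `B` sums, over clusters, the outer products of
#' within-cluster summed score vectors. This is the variance that accounts
#' for within-settlement correlation. Setting every row to its own cluster
#' gives the heteroskedasticity-robust (iid-score) sandwich.
#'
#' @param fit a converged `path_fit`.
#' @param cluster_ids vector assigning each analysis row to a cluster, in
#'   the row order of the data passed to [fit_path_model()].
#' @param small_sample apply the `G/(G-1)` cluster correction?
#' @return covariance matrix with parameter labels as dimnames; the naive
#'   inverse-information matrix is attached as attribute `"naive"`.
#' @export
cluster_robust_vcov <- function(fit, cluster_ids, small_sample = FALSE) {
  stopifnot(inherits(fit, "path_fit"))
  if (!fit$convergence$converged) {
    warn("sandwich variance requested for a non-converged fit.")
  }
  if (length(cluster_ids) != fit$n) {
    abort("cluster_ids must assign every analysis row to a cluster.")
  }
  A <- observed_information(fit)
  cn <- rcond(A)
  if (cn < 1e-14) {
    abort(sprintf("observed information is numerically singular (rcond = %.2e).", cn))
  }
  groups <- split(seq_len(fit$n), cluster_ids)
  G <- length(groups)
  S <- vapply(groups, function(rows)
    fiml_gradient_internal(fit$theta, fit$map, fit$dat, rows = rows),
    numeric(length(fit$theta)))
  B <- tcrossprod(S)              # sum over clusters of s_g s_g'
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  if (isTRUE(small_sample)) V <- V * G / (G - 1)
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(A)
  attr(V, "naive") <- Ainv
  attr(V, "n_clusters") <- G
  V
}
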