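# sem_fiml: chi-square and incremental/absolute fit indices.
#
# The target model's joint log-likelihood is compared against a saturated
# normal model (free mean vector and covariance matrix over all modeled
# variables, fitted to the same missing-data patterns by EM) and against an
# independence baseline (free means and variances, all covariances zero,
# which under missingness still separates into per-variable univariate ML
# problems).

# EM for the unstructured multivariate normal with missing data.
em_mvnorm <- function(V, max_iter = 1000L, tol = 1e-10) {
  n <- nrow(V); p <- ncol(V)
  obs <- !is.na(V)
  if (any(rowSums(obs) == 0)) abort("rows with no observed variable.")
  pat <- as.integer(factor(apply(obs, 1, paste0, collapse = "")))
  groups <- split(seq_len(n), pat)

  V0 <- V
  for (j in seq_len(p)) V0[is.na(V0[, j]), j] <- mean(V[, j], na.rm = TRUE)
  mu <- colMeans(V0)
  Sigma <- make_pd(cov(V0) * (n - 1) / n, eps = 1e-8)

  ll_of <- function(mu, Sigma) {
    ll <- 0
    for (g in groups) {
      ob <- which(obs[g[1], ])
      ll <- ll + sum(dmvnorm_log(V[g, ob, drop = FALSE], mu[ob],
                                 Sigma[ob, ob, drop = FALSE]))
    }
    ll
  }

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sum_v <- numeric(p)
    sum_vv <- matrix(0, p, p)
    for (g in groups) {
      ob <- which(obs[g[1], ])
      ms <- setdiff(seq_len(p), ob)
      Vg <- V[g, ob, drop = FALSE]
      if (length(ms) == 0) {
        sum_v <- sum_v + colSums(Vg)
        sum_vv <- sum_vv + crossprod(Vg)
        next
      }
      Soo <- Sigma[ob, ob, drop = FALSE]
      Smo <- Sigma[ms, ob, drop = FALSE]
      K <- Smo %*% solve(Soo)                      # regression of miss on obs
      Emis <- sweep(Vg, 2L, mu[ob], "-") %*% t(K)
      Emis <- sweep(Emis, 2L, mu[ms], "+")
      Cond <- Sigma[ms, ms, drop = FALSE] - K %*% t(Smo)
      E <- matrix(0, length(g), p)
      E[, ob] <- Vg
      E[, ms] <- Emis
      sum_v <- sum_v + colSums(E)
      CP <- crossprod(E)
      CP[ms, ms] <- CP[ms, ms] + length(g) * Cond
      sum_vv <- sum_vv + CP
    }
    mu <- sum_v / n
    Sigma <- sum_vv / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- ll_of(mu, Sigma)
    if (abs(ll - ll_old) < tol * (abs(ll) + tol)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = Sigma, loglik = ll, iterations = it)
}

# Independence model: per-variable univariate ML over observed entries.
indep_loglik <- function(V) {
  sum(vapply(seq_len(ncol(V)), function(j) {
    x <- V[, j]; x <- x[!is.na(x)]
    nj <- length(x)
    v <- mean((x - mean(x))^2)
    -0.5 * nj * (log(2 * pi) + log(v) + 1)
  }, numeric(1)))
}

# Joint log-likelihood of the fitted model over (endo, exo). In fixed mode
# the conditional likelihood is completed with the saturated Gaussian
# likelihood of the complete exogenous block, which is also its ML value.
model_joint_loglik <- function(fit) {
  if (fit$mode == "saturated") return(fit$loglik)
  X <- fit$dat$X
  n <- nrow(X); q <- ncol(X)
  S <- cov(X) * (n - 1) / n
  llx <- -0.5 * n * (q * log(2 * pi) + determinant(S)$modulus[1] + q)
  fit$loglik + llx
}

# Total free-parameter count on the joint-variable scale (exogenous moments
# count as free in either mode, so df does not depend on the mode).
model_joint_npar <- function(fit) {
  q <- fit$map$q
  if (fit$mode == "saturated") fit$map$K else fit$map$K + q + q * (q + 1) / 2
}

#' Chi-square and fit indices for a fitted path model
#'
#' Likelihood-ratio chi-square against the saturated model, with CFI and
#' TLI relative to the independence baseline (free means and variances,
#' zero covariances, same missing-data patterns) and RMSEA. With zero
#' degrees of freedom the model is saturated: CFI is 1 and TLI/RMSEA are
#' not applicable.
#'
#' @param fit a `path_fit`.
#' @return tibble with `chisq`, `df`, `p.value`, `cfi`, `tli`, `rmsea`,
#'   `loglik`, `npar`, `n`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  V <- cbind(fit$dat$Y, fit$dat$X)
  n <- nrow(V); p <- ncol(V)
  sat <- em_mvnorm(V)
  ll_m <- model_joint_loglik(fit)
  ll_b <- indep_loglik(V)

  npar_sat <- p + p * (p + 1) / 2
  npar_m <- model_joint_npar(fit)
  npar_b <- 2 * p
  chisq_m <- max(2 * (sat$loglik - ll_m), 0)
  chisq_b <- max(2 * (sat$loglik - ll_b), 0)
  df_m <- npar_sat - npar_m
  df_b <- npar_sat - npar_b
  if (df_m < 0) abort("model has more free parameters than the saturated model.")

  if (df_m == 0) {
    # saturated: no testable restrictions; TLI undefined, RMSEA 0 by convention
    cfi <- 1; tli <- NA_real_; rmsea <- 0; pval <- NA_real_
  } else {
    pval <- pchisq(chisq_m, df_m, lower.tail = FALSE)
    num <- max(chisq_m - df_m, 0)
    den <- max(chisq_b - df_b, chisq_m - df_m, 0)
    cfi <- if (den == 0) 1 else 1 - num / den
    rb <- chisq_b / df_b
    rm <- chisq_m / df_m
    tli <- if (rb == 1) NA_real_ else (rb - rm) / (rb - 1)
    rmsea <- sqrt(max(chisq_m - df_m, 0) / (df_m * n))
  }
  tibble(chisq = chisq_m, df = df_m, p.value = pval,
         cfi = cfi, tli = tli, rmsea = rmsea,
         baseline_chisq = chisq_b, baseline_df = df_b,
         loglik = ll_m, npar = npar_m, n = n)
}
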