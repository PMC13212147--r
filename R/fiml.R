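# sem_fiml: full-information maximum likelihood engine.
#
# Free parameters are packed into an unconstrained vector theta:
#   - intercepts alpha (one per endogenous variable),
#   - endogenous-on-endogenous coefficients B (strictly lower triangular
#     under the topological order; holds the b and d paths),
#   - exogenous coefficients Gamma (holds the a paths, the direct effect,
#     and covariate loadings),
#   - residual covariance Psi, parameterized blockwise by the log-Cholesky
#     factor (log-diagonal), which keeps every proposal positive definite,
#   - in "saturated" mode additionally the exogenous means and the
#     log-Cholesky of the exogenous covariance.
# The casewise likelihood is evaluated per missing-data pattern; the
# analytic gradient follows from the chain rule through the reduced form
# eta = (I - B)^-1 (alpha + Gamma x + zeta).

param_map <- function(spec, mode = c("fixed", "saturated")) {
  mode <- match.arg(mode)
  endo <- spec$endo; exo <- spec$exo
  m <- length(endo); q <- length(exo)
  mB <- matrix(FALSE, m, m, dimnames = list(endo, endo))
  mG <- matrix(FALSE, m, q, dimnames = list(endo, exo))
  for (v in endo) {
    regs <- spec$eqs[[v]]
    mB[v, intersect(regs, endo)] <- TRUE
    mG[v, intersect(regs, exo)] <- TRUE
  }
  # residual blocks: declared multi-variable blocks plus implicit singletons
  covered <- unlist(spec$residual_blocks)
  blocks <- c(spec$residual_blocks, as.list(setdiff(endo, covered)))
  blocks <- lapply(blocks, function(b) endo[endo %in% b])  # canonical order

  lab_alpha <- paste0(endo, "~1")
  idxB <- which(mB)                     # column-major over the mask
  lab_B <- if (length(idxB))
    paste0(endo[row(mB)[idxB]], "~", endo[col(mB)[idxB]]) else character(0)
  idxG <- which(mG)
  lab_G <- if (length(idxG))
    paste0(endo[row(mG)[idxG]], "~", exo[col(mG)[idxG]]) else character(0)
  lab_psi <- unlist(lapply(blocks, function(b) {
    s <- length(b)
    il <- which(lower.tri(diag(s), diag = TRUE))
    paste0("chol(", b[row(diag(s))[il]], ",", b[col(diag(s))[il]], ")")
  }))

  k_alpha <- m; k_B <- length(idxB); k_G <- length(idxG)
  k_psi <- sum(vapply(blocks, function(b) length(b) * (length(b) + 1) / 2, numeric(1)))
  i_alpha <- seq_len(k_alpha)
  i_B <- k_alpha + seq_len(k_B)
  i_G <- k_alpha + k_B + seq_len(k_G)
  i_psi <- k_alpha + k_B + k_G + seq_len(k_psi)
  K <- k_alpha + k_B + k_G + k_psi
  labels <- c(lab_alpha, lab_B, lab_G, lab_psi)

  i_mux <- integer(0); i_sxx <- integer(0)
  if (mode == "saturated") {
    i_mux <- K + seq_len(q)
    i_sxx <- K + q + seq_len(q * (q + 1) / 2)
    K <- K + q + q * (q + 1) / 2
    labels <- c(labels, paste0(exo, "~1"),
                paste0("cholx_", seq_len(q * (q + 1) / 2)))
  }
  list(spec = spec, mode = mode, endo = endo, exo = exo, m = m, q = q,
       mB = mB, mG = mG, blocks = blocks,
       i_alpha = i_alpha, i_B = i_B, i_G = i_G, i_psi = i_psi,
       i_mux = i_mux, i_sxx = i_sxx, K = K, labels = labels)
}

chol_to_cov <- function(vals, s) {
  L <- matrix(0, s, s)
  L[lower.tri(L, diag = TRUE)] <- vals
  diag(L) <- exp(diag(L))
  list(L = L, S = L %*% t(L))
}

cov_to_chol <- function(S) {
  L <- t(chol(S))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

unpack_theta <- function(theta, map) {
  m <- map$m
  alpha <- theta[map$i_alpha]
  B <- matrix(0, m, m, dimnames = dimnames(map$mB))
  B[map$mB] <- theta[map$i_B]
  Gamma <- matrix(0, m, map$q, dimnames = dimnames(map$mG))
  Gamma[map$mG] <- theta[map$i_G]
  Psi <- matrix(0, m, m, dimnames = list(map$endo, map$endo))
  Ls <- list()
  off <- 0
  psi_vals <- theta[map$i_psi]
  for (bi in seq_along(map$blocks)) {
    b <- map$blocks[[bi]]
    s <- length(b)
    nv <- s * (s + 1) / 2
    cb <- chol_to_cov(psi_vals[off + seq_len(nv)], s)
    Psi[b, b] <- cb$S
    Ls[[bi]] <- cb$L
    off <- off + nv
  }
  out <- list(alpha = alpha, B = B, Gamma = Gamma, Psi = Psi, Ls = Ls)
  if (map$mode == "saturated") {
    out$mux <- theta[map$i_mux]
    cx <- chol_to_cov(theta[map$i_sxx], map$q)
    out$Sxx <- cx$S
    out$Lx <- cx$L
  }
  out
}

pack_theta <- function(map, alpha, B, Gamma, Psi, mux = NULL, Sxx = NULL) {
  if (is.null(dimnames(Psi))) dimnames(Psi) <- list(map$endo, map$endo)
  theta <- numeric(map$K)
  theta[map$i_alpha] <- alpha
  theta[map$i_B] <- B[map$mB]
  theta[map$i_G] <- Gamma[map$mG]
  psi_vals <- numeric(0)
  for (b in map$blocks) psi_vals <- c(psi_vals, cov_to_chol(Psi[b, b, drop = FALSE]))
  theta[map$i_psi] <- psi_vals
  if (map$mode == "saturated") {
    theta[map$i_mux] <- mux
    theta[map$i_sxx] <- cov_to_chol(Sxx)
  }
  theta
}

# Reduced-form quantities for the conditional (eta | x) distribution.
reduced_form <- function(par) {
  m <- length(par$alpha)
  A <- solve(diag(m) - par$B)
  list(A = A,
       C0 = drop(A %*% par$alpha),
       C1 = A %*% par$Gamma,
       S = A %*% par$Psi %*% t(A))
}

# ---- data preparation -----------------------------------------------------

prep_fiml_data <- function(spec, data, mode) {
  data <- as.data.frame(data)
  need <- c(spec$endo, spec$exo)
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("data lacks model variable(s):",
                                paste(miss, collapse = ", ")))
  Y <- as.matrix(data[spec$endo])
  X <- as.matrix(data[spec$exo])
  storage.mode(Y) <- "double"; storage.mode(X) <- "double"
  n <- nrow(Y)
  if (mode == "fixed") {
    if (anyNA(X)) {
      abort("exogenous variables have missing values; use mode = \"saturated\".")
    }
    obs <- !is.na(Y)
    if (any(rowSums(obs) == 0)) {
      abort("rows with no observed endogenous variable are not allowed; drop them explicitly.")
    }
    pat_id <- as.integer(factor(apply(obs, 1, paste0, collapse = "")))
  } else {
    V <- cbind(Y, X)
    obs <- !is.na(V)
    if (any(rowSums(obs) == 0)) {
      abort("rows with no observed modeled variable are not allowed; drop them explicitly.")
    }
    pat_id <- as.integer(factor(apply(obs, 1, paste0, collapse = "")))
  }
  list(Y = Y, X = X, n = n, obs = obs, pat_id = pat_id, mode = mode)
}

pattern_groups <- function(dat, rows = NULL) {
  rows <- rows %||% seq_len(dat$n)
  split(rows, dat$pat_id[rows])
}

# ---- conditional-mode likelihood and gradient -----------------------------

loglik_cond <- function(theta, map, dat, rows = NULL) {
  par <- unpack_theta(theta, map)
  rf <- reduced_form(par)
  groups <- pattern_groups(dat, rows)
  ll <- 0
  for (g in groups) {
    ob <- which(dat$obs[g[1], ])
    k <- length(ob)
    Sp <- rf$S[ob, ob, drop = FALSE]
    Lp <- tryCatch(chol(Sp), error = function(e) NULL)
    if (is.null(Lp)) return(-Inf)
    Mu <- dat$X[g, , drop = FALSE] %*% t(rf$C1[ob, , drop = FALSE])
    Mu <- sweep(Mu, 2L, rf$C0[ob], "+")
    R <- dat$Y[g, ob, drop = FALSE] - Mu
    Z <- backsolve(Lp, t(R), transpose = TRUE)
    ll <- ll - 0.5 * length(g) * k * log(2 * pi) -
      length(g) * sum(log(diag(Lp))) - 0.5 * sum(Z * Z)
  }
  ll
}

gradient_cond <- function(theta, map, dat, rows = NULL) {
  par <- unpack_theta(theta, map)
  rf <- reduced_form(par)
  m <- map$m
  groups <- pattern_groups(dat, rows)
  gC0 <- numeric(m)
  gC1 <- matrix(0, m, map$q)
  GS <- matrix(0, m, m)
  for (g in groups) {
    ob <- which(dat$obs[g[1], ])
    Sp <- rf$S[ob, ob, drop = FALSE]
    Lp <- chol(Sp)
    W <- chol2inv(Lp)
    Xg <- dat$X[g, , drop = FALSE]
    Mu <- sweep(Xg %*% t(rf$C1[ob, , drop = FALSE]), 2L, rf$C0[ob], "+")
    R <- dat$Y[g, ob, drop = FALSE] - Mu
    U <- R %*% W
    gC0[ob] <- gC0[ob] + colSums(U)
    gC1[ob, ] <- gC1[ob, , drop = FALSE] + crossprod(U, Xg)
    GS[ob, ob] <- GS[ob, ob] + 0.5 * (crossprod(U) - length(g) * W)
  }
  chain_structural(gC0, gC1, GS, par, rf, map)
}

# Chain rule from gradients wrt (C0 = A alpha, C1 = A Gamma, S = A Psi A')
# to the packed parameter vector (structural part).
chain_structural <- function(gC0, gC1, GS, par, rf, map) {
  A <- rf$A
  At <- t(A)
  gAlpha <- drop(At %*% gC0)
  gGamma <- At %*% gC1
  gB_full <- At %*% (outer(gC0, rf$C0) + gC1 %*% t(rf$C1) + 2 * GS %*% rf$S)
  gPsi_full <- At %*% GS %*% A
  g <- numeric(map$K)
  g[map$i_alpha] <- gAlpha
  g[map$i_B] <- gB_full[map$mB]
  g[map$i_G] <- gGamma[map$mG]
  psi_g <- numeric(0)
  for (bi in seq_along(map$blocks)) {
    b <- map$blocks[[bi]]
    L <- par$Ls[[bi]]
    Gb <- gPsi_full[b, b, drop = FALSE]
    Gb <- Gb + t(Gb)            # d Psi / d L with Psi = L L'
    gL <- Gb %*% L
    diag(gL) <- diag(gL) * diag(L)   # log-diagonal coordinates
    psi_g <- c(psi_g, gL[lower.tri(gL, diag = TRUE)])
  }
  g[map$i_psi] <- psi_g
  g
}

# ---- saturated-mode likelihood and gradient -------------------------------

# Joint moments over (endo, exo) implied by theta.
joint_moments <- function(par, rf = reduced_form(par), mux = par$mux,
                          Sxx = par$Sxx) {
  mu <- c(rf$C0 + drop(rf$C1 %*% mux), mux)
  CS <- rf$C1 %*% Sxx
  Sigma <- rbind(cbind(rf$C1 %*% t(CS) + rf$S, CS),
                 cbind(t(CS), Sxx))
  list(mu = mu, sigma = (Sigma + t(Sigma)) / 2)
}

loglik_sat <- function(theta, map, dat, rows = NULL) {
  par <- unpack_theta(theta, map)
  mom <- joint_moments(par)
  V <- cbind(dat$Y, dat$X)
  groups <- pattern_groups(dat, rows)
  ll <- 0
  for (g in groups) {
    ob <- which(dat$obs[g[1], ])
    k <- length(ob)
    Lp <- tryCatch(chol(mom$sigma[ob, ob, drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(Lp)) return(-Inf)
    R <- sweep(V[g, ob, drop = FALSE], 2L, mom$mu[ob], "-")
    Z <- backsolve(Lp, t(R), transpose = TRUE)
    ll <- ll - 0.5 * length(g) * k * log(2 * pi) -
      length(g) * sum(log(diag(Lp))) - 0.5 * sum(Z * Z)
  }
  ll
}

# Gradient wrt full (mu, Sigma), then chained to theta by forward finite
# differences of the cheap moment map (the data pass is analytic).
gradient_sat <- function(theta, map, dat, rows = NULL) {
  par <- unpack_theta(theta, map)
  mom <- joint_moments(par)
  V <- cbind(dat$Y, dat$X)
  p <- length(mom$mu)
  gmu <- numeric(p)
  GS <- matrix(0, p, p)
  groups <- pattern_groups(dat, rows)
  for (g in groups) {
    ob <- which(dat$obs[g[1], ])
    Lp <- chol(mom$sigma[ob, ob, drop = FALSE])
    W <- chol2inv(Lp)
    R <- sweep(V[g, ob, drop = FALSE], 2L, mom$mu[ob], "-")
    U <- R %*% W
    gmu[ob] <- gmu[ob] + colSums(U)
    GS[ob, ob] <- GS[ob, ob] + 0.5 * (crossprod(U) - length(g) * W)
  }
  g <- numeric(map$K)
  h <- 1e-7
  for (k in seq_len(map$K)) {
    th <- theta
    hk <- h * max(1, abs(th[k]))
    th[k] <- th[k] + hk
    momk <- joint_moments(unpack_theta(th, map))
    g[k] <- sum(gmu * (momk$mu - mom$mu)) / hk +
      sum(GS * (momk$sigma - mom$sigma)) / hk
  }
  g
}

fiml_loglik_internal <- function(theta, map, dat, rows = NULL) {
  if (map$mode == "fixed") loglik_cond(theta, map, dat, rows)
  else loglik_sat(theta, map, dat, rows)
}

fiml_gradient_internal <- function(theta, map, dat, rows = NULL) {
  if (map$mode == "fixed") gradient_cond(theta, map, dat, rows)
  else gradient_sat(theta, map, dat, rows)
}

#' Casewise FIML log-likelihood of a path model
#'
#' Sum over rows of the log-density of each row's observed sub-vector under
#' the model-implied multivariate normal. In `"fixed"` mode the likelihood
#' is conditional on the (complete) exogenous variables; in `"saturated"`
#' mode the exogenous variables are modeled jointly normal with free
#' moments, which permits missing covariate values.
#'
#' @param spec a `path_model_spec`.
#' @param theta packed parameter vector (see [fit_path_model()], element
#'   `theta`), or a `path_fit` whose parameters should be used.
#' @param data data frame holding every model variable.
#' @param mode `"fixed"` or `"saturated"`.
#' @return scalar log-likelihood.
#' @export
fiml_loglik <- function(spec, theta, data, mode = c("fixed", "saturated")) {
  mode <- match.arg(mode)
  if (inherits(theta, "path_fit")) theta <- theta$theta
  map <- param_map(spec, mode)
  if (length(theta) != map$K) {
    abort(sprintf("theta has %d entries; the %s-mode parameterization needs %d.",
                  length(theta), mode, map$K))
  }
  dat <- prep_fiml_data(spec, data, mode)
  fiml_loglik_internal(theta, map, dat)
}
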