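# sem_fiml: model fitting.

start_values <- function(map, dat) {
  spec <- map$spec
  endo <- map$endo
  m <- map$m
  Y <- dat$Y; X <- dat$X
  alpha <- numeric(m); names(alpha) <- endo
  B <- matrix(0, m, m, dimnames = dimnames(map$mB))
  Gamma <- matrix(0, m, map$q, dimnames = dimnames(map$mG))
  res <- matrix(NA_real_, dat$n, m, dimnames = list(NULL, endo))
  for (v in endo) {
    regs <- spec$eqs[[v]]
    D <- cbind(`(Intercept)` = 1,
               Y[, intersect(regs, endo), drop = FALSE],
               X[, intersect(regs, map$exo), drop = FALSE])
    cc <- complete.cases(cbind(Y[, v], D))
    if (sum(cc) <= ncol(D)) {
      # too few jointly complete rows (heavy per-variable missingness on a
      # small sample): mean-impute regressors for the starting values only;
      # the FIML iterations take it from there
      inform(sprintf("only %d complete cases for the %s equation; using mean-imputed starting values.",
                     sum(cc), v))
      Dimp <- apply(D, 2L, function(col) {
        col[is.na(col)] <- mean(col, na.rm = TRUE); col
      })
      cc <- !is.na(Y[, v])
      D <- Dimp
    }
    f <- lm.fit(D[cc, , drop = FALSE], Y[cc, v])
    if (f$rank < ncol(D)) {
      bad <- colnames(D)[is.na(f$coefficients)]
      abort(sprintf("rank-deficient design in equation for %s (column %s).",
                    v, paste(bad, collapse = ", ")))
    }
    cf <- f$coefficients
    alpha[v] <- cf[["(Intercept)"]]
    for (r in intersect(regs, endo)) B[v, r] <- cf[[r]]
    for (r in intersect(regs, map$exo)) Gamma[v, r] <- cf[[r]]
    res[cc, v] <- f$residuals
  }
  Psi <- matrix(0, m, m, dimnames = list(endo, endo))
  for (b in map$blocks) {
    if (length(b) == 1) {
      Psi[b, b] <- mean(res[, b]^2, na.rm = TRUE)
    } else {
      S <- cov(res[, b, drop = FALSE], use = "pairwise.complete.obs")
      ns <- colSums(!is.na(res[, b, drop = FALSE]))
      S <- S * mean((ns - 1) / ns)   # ML-flavoured rescale
      Psi[b, b] <- make_pd(S, eps = 1e-6)
    }
  }
  out <- list(alpha = alpha, B = B, Gamma = Gamma, Psi = Psi)
  if (map$mode == "saturated") {
    out$mux <- colMeans(X, na.rm = TRUE)
    nsx <- colSums(!is.na(X))
    Sx <- cov(X, use = "pairwise.complete.obs") * mean((nsx - 1) / nsx)
    if (map$q == 1) Sx <- matrix(Sx, 1, 1)
    out$Sxx <- make_pd(Sx, eps = 1e-6)
  }
  out
}

#' Fit a recursive path model by full-information maximum likelihood
#'
#' Maximizes the casewise (missing-pattern) Gaussian log-likelihood by
#' quasi-Newton iteration with an analytic gradient, starting from
#' equation-wise complete-case least squares. With complete data the
#' starting values already solve the likelihood equations (the system is
#' block-recursive with shared regressors per residual block), so the
#' optimizer serves to confirm stationarity; with missing data it performs
#' the genuine FIML fit.
#'
#' @param spec a `path_model_spec` from [build_model_spec()] or
#'   [parse_model_syntax()].
#' @param data data frame with one row per woman containing every model
#'   variable; `NA`s allowed in endogenous variables (and in exogenous ones
#'   under `mode = "saturated"`).
#' @param mode exogenous-variable handling: `"auto"` picks `"fixed"`
#'   (conditional on complete covariates) when possible, `"saturated"`
#'   (jointly normal exogenous with free moments) otherwise.
#' @param control list: `maxit` (per BFGS run), `restarts`, `reltol`,
#'   `grad_tol` (convergence threshold on the per-row mean score,
#'   `max|gradient|/n`).
#' @return a `path_fit` object; see [tidy()] / [glance()] methods.
#' @export
fit_path_model <- function(spec, data,
                           mode = c("auto", "fixed", "saturated"),
                           control = list()) {
  mode <- match.arg(mode)
  ctl <- modifyList(list(maxit = 1000L, restarts = 4L, reltol = 1e-12,
                         grad_tol = 1e-5), control)
  data <- as.data.frame(data)
  if (mode == "auto") {
    mode <- if (anyNA(data[spec$exo])) "saturated" else "fixed"
  }
  map <- param_map(spec, mode)
  dat <- prep_fiml_data(spec, data, mode)
  sv <- start_values(map, dat)
  theta <- pack_theta(map, sv$alpha, sv$B, sv$Gamma, sv$Psi, sv$mux, sv$Sxx)

  negll <- function(th) -fiml_loglik_internal(th, map, dat)
  neggr <- function(th) -fiml_gradient_internal(th, map, dat)

  grad_ok <- function(th) {
    max(abs(fiml_gradient_internal(th, map, dat))) / dat$n < ctl$grad_tol
  }
  best_theta <- theta
  best_ll <- -negll(theta)
  ll_prev <- best_ll
  it_total <- 0L
  for (r in seq_len(ctl$restarts + 1L)) {
    opt <- optim(theta, negll, neggr, method = "BFGS",
                 control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    it_total <- it_total + opt$counts[["function"]]
    theta <- opt$par
    ll_now <- -opt$value
    if (ll_now > best_ll) {
      best_ll <- ll_now
      best_theta <- theta
    }
    if (grad_ok(theta)) break
    if (abs(ll_now - ll_prev) < 1e-9 * (abs(ll_now) + 1e-9) && r > 1L) break
    ll_prev <- ll_now
  }
  theta <- best_theta
  grad <- fiml_gradient_internal(theta, map, dat)
  ll <- -negll(theta)
  converged <- max(abs(grad)) / dat$n < ctl$grad_tol
  if (!converged) {
    warn(sprintf("FIML optimizer did not meet the gradient tolerance (max score/n = %.2e); returning best-found parameters flagged as non-converged.",
                 max(abs(grad)) / dat$n))
  }

  par <- unpack_theta(theta, map)
  if (mode == "fixed") {
    nx <- nrow(dat$X)
    exo_mu <- colMeans(dat$X)
    exo_sigma <- cov(dat$X) * (nx - 1) / nx
  } else {
    exo_mu <- par$mux
    exo_sigma <- par$Sxx
  }
  dimnames(exo_sigma) <- list(map$exo, map$exo)
  names(exo_mu) <- map$exo

  coef_idx <- c(map$i_alpha, map$i_B, map$i_G)
  est <- setNames(theta, map$labels)
  structure(list(
    spec = spec, map = map, dat = dat, mode = mode,
    theta = theta, estimates = est,
    alpha = par$alpha, B = par$B, Gamma = par$Gamma, Psi = par$Psi,
    exo_mu = exo_mu, exo_sigma = exo_sigma,
    loglik = ll, n = dat$n, npar = map$K,
    coef_idx = coef_idx,
    convergence = list(converged = converged,
                       grad_max = max(abs(grad)),
                       grad_max_per_row = max(abs(grad)) / dat$n,
                       iterations = it_total)
  ), class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model fit by FIML (%s exogenous mode)\n", x$mode))
  cat(sprintf("  n = %d, free parameters = %d, logLik = %.3f\n",
              x$n, x$npar, x$loglik))
  cat(sprintf("  converged: %s (max score/n = %.2e)\n",
              x$convergence$converged, x$convergence$grad_max_per_row))
  invisible(x)
}

#' Model-implied moments of all modeled variables
#'
#' Mean vector and covariance matrix over the endogenous and exogenous
#' variables implied by the fitted (or supplied) parameters; exogenous
#' moments are the sample maximum-likelihood moments in `"fixed"` mode and
#' estimated parameters in `"saturated"` mode.
#'
#' @param fit a `path_fit`, or a `path_model_spec` combined with `theta`.
#' @param theta packed parameter vector (only when `fit` is a spec).
#' @param mode parameterization mode (only when `fit` is a spec);
#'   `"saturated"` thetas carry their own exogenous moments, `"fixed"`
#'   thetas need `exo_mu`/`exo_sigma`.
#' @param exo_mu,exo_sigma exogenous moments for `"fixed"`-mode thetas.
#' @return list with `mu` (named vector) and `sigma` (named matrix).
#' @export
implied_moments <- function(fit, theta = NULL, mode = "fixed",
                            exo_mu = NULL, exo_sigma = NULL) {
  if (inherits(fit, "path_fit")) {
    par <- unpack_theta(fit$theta, fit$map)
    mux <- fit$exo_mu; Sxx <- fit$exo_sigma
    vars <- c(fit$map$endo, fit$map$exo)
  } else {
    stopifnot(inherits(fit, "path_model_spec"), !is.null(theta))
    map <- param_map(fit, mode)
    par <- unpack_theta(theta, map)
    if (mode == "saturated") {
      mux <- par$mux; Sxx <- par$Sxx
    } else {
      if (is.null(exo_mu) || is.null(exo_sigma)) {
        abort("fixed-mode implied moments need `exo_mu` and `exo_sigma`.")
      }
      mux <- exo_mu; Sxx <- exo_sigma
    }
    vars <- c(map$endo, map$exo)
  }
  mom <- joint_moments(par, mux = mux, Sxx = Sxx)
  ev <- eigen(mom$sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort("implied covariance is not positive semi-definite.")
  }
  names(mom$mu) <- vars
  dimnames(mom$sigma) <- list(vars, vars)
  mom
}

#' Standardized path coefficients
#'
#' Each regression coefficient is multiplied by the model-implied standard
#' deviation of its regressor and divided by that of its dependent
#' variable.
#'
#' @param fit a `path_fit`.
#' @return tibble with `term`, `estimate`, `std_estimate`.
#' @export
standardized_paths <- function(fit) {
  mom <- implied_moments(fit)
  sds <- sqrt(diag(mom$sigma))
  if (any(sds <= 0)) {
    abort(paste("zero implied variance for:",
                paste(names(sds)[sds <= 0], collapse = ", ")))
  }
  idx <- c(fit$map$i_B, fit$map$i_G)
  terms <- fit$map$labels[idx]
  parts <- strsplit(terms, "~", fixed = TRUE)
  dep <- vapply(parts, `[[`, "", 1L)
  reg <- vapply(parts, `[[`, "", 2L)
  tibble(term = terms,
         estimate = unname(fit$theta[idx]),
         std_estimate = unname(fit$theta[idx] * sds[reg] / sds[dep]))
}

#' Two-sided Wald tests for coefficients
#'
#' @param estimates named numeric vector of estimates.
#' @param V covariance matrix of the estimates (conformable, in the same
#'   order).
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`; zero standard errors yield `NA` statistics with a warning.
#' @export
wald_tests <- function(estimates, V) {
  se <- sqrt(pmax(diag(V), 0))
  if (length(se) != length(estimates)) abort("V is not conformable with estimates.")
  zero <- se == 0
  if (any(zero)) warn("zero standard error(s); Wald statistics undefined there.")
  z <- ifelse(zero, NA_real_, estimates / se)
  tibble(term = names(estimates) %||% paste0("par", seq_along(estimates)),
         estimate = unname(estimates), std.error = unname(se),
         statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}
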