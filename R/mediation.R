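# mediation: effect decomposition and Monte Carlo confidence intervals.

# Map the decomposition's path names onto fitted coefficient labels.
path_labels <- function(domains, via_market, market, outcome = "dds",
                        treatment = "trt") {
  meds <- unlist(domains, use.names = FALSE)
  lab <- c(setNames(paste0(meds, "~", treatment), paste0("a_", meds)),
           setNames(paste0(outcome, "~", meds), paste0("b_", meds)),
           direct = paste0(outcome, "~", treatment))
  if (!is.null(market)) {
    lab <- c(lab,
             setNames(paste0(market, "~", treatment), paste0("a_", market)),
             setNames(paste0(outcome, "~", market), paste0("b_", market)))
  }
  if (length(via_market)) {
    lab <- c(lab, setNames(paste0(market, "~", via_market),
                           paste0("d_", via_market)))
  }
  lab
}

extract_path_coefs <- function(fit, labels) {
  absent <- setdiff(labels, names(fit$estimates))
  if (length(absent)) {
    abort(paste("fitted model has no path(s):", paste(absent, collapse = ", ")))
  }
  setNames(fit$estimates[labels], names(labels))
}

#' Decompose the intervention effect through the fitted mediators
#'
#' Computes every mediator-specific product of coefficients (`a x b`), the
#' sequential products through market activity (`a x d x b_market`), the
#' market-alone product, domain sums with and without market legs, and the
#' direct, total indirect and total effects. The total effect is also
#' cross-computed as the reduced-form treatment coefficient implied by path
#' tracing through `(I - B)^-1 Gamma` and asserted equal.
#'
#' @param fit a converged `path_fit` containing all `a`, `b`, `d` and
#'   direct paths.
#' @param domains named list grouping non-market mediators into domains.
#' @param via_market mediators with a `d` path into `market`.
#' @param market market mediator name (`NULL` if not modeled).
#' @param outcome,treatment variable names in the fitted model.
#' @return an `effect_decomposition` tibble: `effect`, `label`, `type`,
#'   `domain`, `estimate`.
#' @export
decompose_effects <- function(fit, domains = default_domains(),
                              via_market = unlist(domains, use.names = FALSE),
                              market = "market", outcome = "dds",
                              treatment = "trt") {
  labels <- path_labels(domains, via_market, market, outcome, treatment)
  coefs <- extract_path_coefs(fit, labels)
  out <- effect_algebra(coefs, domains, via_market, market) |>
    dplyr::rename(estimate = "value")

  # cross-check: reduced-form treatment coefficient equals direct + indirect
  A <- solve(diag(fit$map$m) - fit$B)
  rf_total <- (A %*% fit$Gamma)[outcome, treatment]
  tot <- out$estimate[out$effect == "total"]
  if (abs(rf_total - tot) > 1e-8 * max(1, abs(tot))) {
    abort(sprintf("decomposition does not reproduce the reduced-form total effect (%.6g vs %.6g); are all mediators included in `domains`?",
                  tot, rf_total))
  }
  structure(out, class = c("effect_decomposition", class(out)),
            coefs = coefs, domains = domains, via_market = via_market,
            market = market, outcome = outcome, treatment = treatment)
}

#' Monte Carlo percentile confidence intervals for the decomposition
#'
#' Samples coefficient vectors from a multivariate normal centered at the
#' estimated paths with the supplied (cluster-robust) covariance restricted
#' to the involved coefficients, evaluates every effect expression per
#' draw, and reports percentile intervals. Percentile (not symmetric
#' normal) intervals are used because products of normals are skewed.
#'
#' @param fit a converged `path_fit`.
#' @param V coefficient covariance with labeled dimnames, e.g. from
#'   [cluster_robust_vcov()].
#' @param n_reps number of Monte Carlo repetitions (default 10,000).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param level confidence level.
#' @inheritParams decompose_effects
#' @return tibble: `effect`, `label`, `type`, `domain`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
monte_carlo_ci <- function(fit, V, n_reps = 10000L, seed = 1L, level = 0.95,
                           domains = default_domains(),
                           via_market = unlist(domains, use.names = FALSE),
                           market = "market", outcome = "dds",
                           treatment = "trt") {
  if (n_reps < 1000L) abort("n_reps must be at least 1000.")
  labels <- path_labels(domains, via_market, market, outcome, treatment)
  coefs <- extract_path_coefs(fit, labels)
  absent <- setdiff(unname(labels), colnames(V))
  if (length(absent)) {
    abort(paste("V lacks coefficient(s):", paste(absent, collapse = ", ")))
  }
  Vs <- V[labels, labels, drop = FALSE]
  Vs <- (Vs + t(Vs)) / 2
  ev <- eigen(Vs, symmetric = TRUE)
  tol <- 1e-10 * max(abs(ev$values), 1e-300)
  if (min(ev$values) < -tol) {
    abort(sprintf("coefficient covariance is not positive semi-definite (min eigenvalue %.3e); consider projecting to the nearest PSD matrix before calling.",
                  min(ev$values)))
  }
  set.seed(seed)
  k <- length(coefs)
  Z <- matrix(rnorm(n_reps * k), n_reps, k)
  draws <- sweep(Z %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors)), 2L,
                 coefs, "+")
  colnames(draws) <- names(labels)
  E <- effect_values(draws, domains, via_market, market)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(E, 2L, quantile, probs = probs, names = FALSE)
  meta <- effect_meta(domains, via_market, market)
  est <- drop(effect_values(matrix(coefs, 1,
                                   dimnames = list(NULL, names(coefs))),
                            domains, via_market, market))
  dplyr::mutate(meta, estimate = unname(est[meta$effect]),
                conf.low = unname(qs[1, ][meta$effect]),
                conf.high = unname(qs[2, ][meta$effect]))
}

#' Proportions mediated
#'
#' Each reported effect divided by the total effect, as a percentage,
#' computed from unrounded estimates. When the total effect is numerically
#' near zero the proportions are unstable and are returned as `NA` with a
#' warning rather than emitted.
#'
#' @param decomp an `effect_decomposition` (or any tibble with `effect` and
#'   `estimate` columns including a `total` row).
#' @param tol instability threshold on `|total|`.
#' @return the input with a `prop_mediated` column (percent) on the total
#'   indirect and domain rows.
#' @export
summarize_proportions <- function(decomp, tol = 1e-8) {
  total <- decomp$estimate[decomp$effect == "total"]
  if (length(total) != 1) abort("decomposition lacks a unique `total` row.")
  show <- decomp$effect == "total_indirect" | decomp$type == "domain"
  if (abs(total) < tol) {
    warn("total effect is numerically zero; proportions mediated are unstable and not emitted.")
    return(dplyr::mutate(decomp, prop_mediated = NA_real_))
  }
  dplyr::mutate(decomp,
                prop_mediated = ifelse(show, 100 * .data$estimate / total,
                                       NA_real_))
}
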