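# broom-style tidiers and plotting.

#' Tidy a fitted path model
#'
#' One row per free regression coefficient (intercepts, endogenous and
#' exogenous paths). Supplying a coefficient covariance (e.g. from
#' [cluster_robust_vcov()]) adds Wald columns.
#'
#' @param x a `path_fit`.
#' @param vcov optional labeled covariance matrix of the estimates.
#' @param ... unused.
#' @return tibble with `term`, `estimate` and, given `vcov`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy path_fit
#' @export
tidy.path_fit <- function(x, vcov = NULL, ...) {
  idx <- x$coef_idx
  est <- setNames(x$theta[idx], x$map$labels[idx])
  if (is.null(vcov)) {
    return(tibble(term = names(est), estimate = unname(est)))
  }
  wald_tests(est, vcov[names(est), names(est), drop = FALSE])
}

#' Glance at a fitted path model
#' @param x a `path_fit`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance path_fit
#' @export
glance.path_fit <- function(x, ...) {
  tibble(logLik = x$loglik, npar = x$npar, nobs = x$n,
         mode = x$mode, converged = x$convergence$converged,
         grad_max = x$convergence$grad_max)
}

#' Tidy a random-intercept fit
#' @param x an `ri_fit`.
#' @param ... unused.
#' @return tibble of fixed effects.
#' @method tidy ri_fit
#' @export
tidy.ri_fit <- function(x, ...) x$fixed

#' Glance at a random-intercept fit
#' @param x an `ri_fit`.
#' @param ... unused.
#' @return one-row tibble with variance components and ICC.
#' @method glance ri_fit
#' @export
glance.ri_fit <- function(x, ...) {
  tibble(sigma_u2 = x$sigma_u2, sigma_e2 = x$sigma_e2, icc = x$icc,
         logLik = x$loglik, nobs = x$n, n_clusters = x$n_clusters,
         boundary = x$boundary, method = x$method)
}

#' Forest plot of an effect decomposition
#'
#' Point estimates (with Monte Carlo intervals when present) for the
#' individual products, domain sums and the direct/indirect/total effects.
#'
#' @param object decomposition tibble from [decompose_effects()] (joined
#'   with [monte_carlo_ci()] columns for intervals).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot effect_decomposition
#' @export
autoplot.effect_decomposition <- function(object, ...) {
  d <- dplyr::mutate(object, label = factor(.data$label,
                                            levels = rev(.data$label)))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$type), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "Effect on outcome (food groups)", y = NULL)
  if (all(c("conf.low", "conf.high") %in% names(d))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2)
  }
  p
}

#' Text dump of the fitted path diagram
#'
#' One line per structural path with its estimate; a compact stand-in for a
#' graphical diagram.
#'
#' @param fit a `path_fit`.
#' @return character vector (invisibly printed).
#' @export
path_diagram <- function(fit) {
  terms <- fit$map$labels[c(fit$map$i_B, fit$map$i_G)]
  est <- fit$theta[c(fit$map$i_B, fit$map$i_G)]
  keep <- grepl("~trt$", terms) | terms %in% fit$map$labels[fit$map$i_B]
  lines <- sprintf("%-18s --> %-10s %8.3f",
                   sub("^.*~", "", terms[keep]),
                   sub("~.*$", "", terms[keep]), est[keep])
  cat(lines, sep = "\n")
  invisible(lines)
}
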