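# mixed_effects: random-intercept models for total intervention effects.
# Estimation is delegated to lme4::lmer behind this module surface.

#' Random-intercept linear model for a total intervention effect
#'
#' Fits `outcome ~ treatment + adjustments + (1 | cluster)` by maximum
#' likelihood (default; REML available), returning Wald tests and 95%
#' confidence intervals for the fixed effects together with the variance
#' components. ML is the default so log-likelihoods are comparable across
#' fixed-effect specifications.
#'
#' @param data analysis table (one row per woman).
#' @param outcome outcome column name.
#' @param fixed character vector of fixed-effect columns (first is usually
#'   the treatment indicator).
#' @param cluster cluster-id column name.
#' @param method `"ML"` or `"REML"`.
#' @param level confidence level for Wald intervals.
#' @return an `ri_fit` object; see [tidy()] / [glance()] methods.
#' @export
fit_random_intercept <- function(data, outcome, fixed, cluster = "cluster_id",
                                 method = c("ML", "REML"), level = 0.95) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  use <- complete.cases(data[c(outcome, fixed, cluster)])
  d <- data[use, , drop = FALSE]
  if (dplyr::n_distinct(d[[cluster]]) < 2) abort("need at least 2 clusters.")
  if (length(fixed)) {
    mm <- model.matrix(~., d[fixed])
    if (qr(mm)$rank < ncol(mm)) {
      bad <- fixed[colSums(abs(mm[, -1, drop = FALSE])) == 0]
      abort(sprintf("rank-deficient fixed-effect design (suspect column: %s).",
                    paste(if (length(bad)) bad else "unknown", collapse = ", ")))
    }
  }
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(outcome, "~", rhs,
                                 "+ (1 |", cluster, ")"))
  fit <- lme4::lmer(fml, data = d, REML = identical(method, "REML"),
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == cluster]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  boundary <- lme4::isSingular(fit)
  if (boundary) {
    inform(sprintf("cluster-intercept variance estimated at the boundary (0) for outcome %s.",
                   outcome))
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zq <- qnorm(1 - (1 - level) / 2)
  fixed_tab <- tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = unname(2 * pnorm(-abs(est / se))),
    conf.low = unname(est - zq * se), conf.high = unname(est + zq * se))
  structure(list(fixed = fixed_tab, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 icc = sigma_u2 / (sigma_u2 + sigma_e2),
                 n = nrow(d), n_clusters = dplyr::n_distinct(d[[cluster]]),
                 boundary = boundary, method = method,
                 loglik = as.numeric(logLik(fit)), outcome = outcome,
                 lmer_fit = fit),
            class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("Random-intercept model (%s): %s, n = %d, %d clusters\n",
              x$method, x$outcome, x$n, x$n_clusters))
  cat(sprintf("  sigma_u^2 = %.4f, sigma_e^2 = %.4f (ICC %.3f%s)\n",
              x$sigma_u2, x$sigma_e2, x$icc,
              if (x$boundary) ", boundary" else ""))
  print(x$fixed)
  invisible(x)
}

# Per-indicator baseline-adjustment sets for the total-effect table: the
# outcome models adjust for baseline dietary diversity, the crop model for
# baseline crop richness, the market model for baseline market score.
default_adjustments <- function() {
  list(dds_mean = "baseline_dds", mdd_prop = "baseline_dds",
       crop_richness_mean = "baseline_crop_richness",
       market_score = "baseline_market_score")
}

#' Total intervention effects on the outcome and every mediator
#'
#' One random-intercept model per indicator, reported with control and
#' intervention descriptive means, the treatment effect, its Wald interval
#' and p value.
#'
#' @param data analysis table.
#' @param indicators named character vector of indicator columns (names are
#'   display labels); defaults to both outcomes and the seven mediators.
#' @param treatment treatment column name.
#' @param cluster cluster-id column name.
#' @param adjustments named list mapping indicator columns to extra
#'   baseline covariates.
#' @param method `"ML"` or `"REML"`.
#' @return tibble, one row per indicator.
#' @export
total_effects_table <- function(data,
                                indicators = c(
                                  "Dietary diversity score" = "dds_mean",
                                  "Met minimum dietary diversity" = "mdd_prop",
                                  "Crop species richness" = "crop_richness_mean",
                                  "Garden practices score" = "garden_practices_score",
                                  "Number of poultry owned" = "poultry_mean",
                                  "Number of eggs produced" = "eggs_mean",
                                  "Food group knowledge score" = "fg_knowledge_score",
                                  "Diet diversity knowledge score" = "dd_knowledge_score",
                                  "Market score" = "market_score"),
                                treatment = "arm", cluster = "cluster_id",
                                adjustments = default_adjustments(),
                                method = "ML") {
  purrr::imap_dfr(indicators, function(col, label) {
    adj <- intersect(adjustments[[col]] %||% character(), names(data))
    f <- fit_random_intercept(data, col, c(treatment, adj), cluster,
                              method = method)
    ok <- !is.na(data[[col]])
    trt_row <- dplyr::filter(f$fixed, .data$term == treatment)
    tibble(indicator = label, column = col, n = f$n,
           mean_control = mean(data[[col]][ok & data[[treatment]] == 0]),
           mean_intervention = mean(data[[col]][ok & data[[treatment]] == 1]),
           estimate = trt_row$estimate, conf.low = trt_row$conf.low,
           conf.high = trt_row$conf.high, p.value = trt_row$p.value,
           sigma_u2 = f$sigma_u2, sigma_e2 = f$sigma_e2)
  })
}
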