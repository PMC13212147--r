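# pipeline_cli: end-to-end orchestration — simulate or ingest, score, fit,
# decompose, stratify, report.

#' Pipeline run configuration
#'
#' @param input `NULL` to simulate from `generator`, or a list with
#'   elements `panel` and `baseline` naming CSV paths (or holding data
#'   frames directly).
#' @param generator a [generator_config()] used when `input` is `NULL`.
#' @param outcome `"dds_mean"` (average dietary diversity score) or
#'   `"mdd_prop"` (proportion of rounds meeting minimum dietary diversity).
#' @param covariates baseline covariate columns entering every equation.
#' @param ramadan_exclusion drop survey rounds flagged as Ramadan from the
#'   diet aggregation.
#' @param mc_reps Monte Carlo confidence-interval repetitions.
#' @param seed integer seed controlling simulation and Monte Carlo draws.
#' @param mode exogenous-variable handling passed to [fit_path_model()].
#' @param naive_mc draw Monte Carlo intervals from the naive
#'   inverse-information covariance instead of the cluster-robust one.
#' @param small_sample apply the `G/(G-1)` cluster correction.
#' @param min_stratum smallest stratum size fitted by [run_stratified()].
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, generator = generator_config(),
                       outcome = c("dds_mean", "mdd_prop"),
                       covariates = default_covariates(),
                       ramadan_exclusion = FALSE, mc_reps = 10000L,
                       seed = 1L, mode = "auto", naive_mc = FALSE,
                       small_sample = FALSE, min_stratum = 200L,
                       output_dir = NULL) {
  structure(list(input = input, generator = generator,
                 outcome = match.arg(outcome), covariates = covariates,
                 ramadan_exclusion = ramadan_exclusion,
                 mc_reps = as.integer(mc_reps), seed = as.integer(seed),
                 mode = mode, naive_mc = naive_mc,
                 small_sample = small_sample,
                 min_stratum = as.integer(min_stratum),
                 output_dir = output_dir),
            class = c("run_config", "list"))
}

# Model-variable frame: short model names bound to analysis-table columns.
build_model_frame <- function(tab, outcome_col, covariates,
                              extra_mediator_cols = NULL) {
  med_cols <- c(MED_COLS, extra_mediator_cols)
  miss <- setdiff(c(outcome_col, unname(med_cols), covariates), names(tab))
  if (length(miss)) abort(paste("analysis table lacks:", paste(miss, collapse = ", ")))
  mf <- tibble(trt = as.numeric(tab$arm))
  for (k in names(med_cols)) mf[[k]] <- tab[[med_cols[[k]]]]
  mf$dds <- tab[[outcome_col]]
  dplyr::bind_cols(mf, tab[covariates])
}

# Core analysis on an assembled table: mixed-effects totals, FIML path
# model, cluster-robust variance, fit indices, decomposition with MC CIs.
run_on_table <- function(tab, config, label = "primary",
                         extra_mediators = NULL) {
  covariates <- intersect(config$covariates, names(tab))
  domains <- default_domains()
  blocks <- list(c("crop", "prac", "pltry", "egg"), c("fgknow", "ddknow"))
  extra_cols <- NULL
  if (!is.null(extra_mediators)) {
    extra_cols <- setNames(extra_mediators, extra_mediators)
    domains <- c(domains, list(empowerment = extra_mediators))
    blocks <- c(blocks, list(extra_mediators))
  }
  mf <- build_model_frame(tab, config$outcome, covariates, extra_cols)
  inform(sprintf("[%s] analysis sample: %d women, %d clusters, %d diet rounds",
                 label, nrow(tab), dplyr::n_distinct(tab$cluster_id),
                 sum(tab$n_diet_rounds)))

  mediators <- c(unlist(domains, use.names = FALSE), "market")
  spec <- build_model_spec(mediators, outcome = "dds", treatment = "trt",
                           covariates = covariates, market = "market",
                           via_market = unlist(default_domains(),
                                               use.names = FALSE),
                           residual_blocks = blocks)
  t0 <- Sys.time()
  fit <- fit_path_model(spec, mf, mode = config$mode)
  inform(sprintf("[%s] path model fitted in %.1f s (%d free parameters)",
                 label, as.numeric(Sys.time() - t0, units = "secs"),
                 fit$npar))
  V <- cluster_robust_vcov(fit, tab$cluster_id,
                           small_sample = config$small_sample)
  V_mc <- if (isTRUE(config$naive_mc)) attr(V, "naive") else V
  fi <- fit_indices(fit)
  via <- unlist(default_domains(), use.names = FALSE)
  decomp <- decompose_effects(fit, domains = domains, via_market = via)
  ci <- monte_carlo_ci(fit, V_mc, n_reps = config$mc_reps,
                       seed = config$seed + 104729L,
                       domains = domains, via_market = via)
  decomp <- dplyr::left_join(
    decomp, dplyr::select(ci, "effect", "conf.low", "conf.high"),
    by = "effect")
  decomp <- summarize_proportions(decomp)

  table2 <- total_effects_table(tab)
  list(label = label,
       n_women = nrow(tab),
       n_clusters = dplyr::n_distinct(tab$cluster_id),
       total_effects = table2,
       fit = fit, vcov_cluster = V, fit_indices = fi,
       decomposition = decomp)
}

config_hash_of <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL        # where results land must not change the hash
  rlang::hash(cfg)
}

#' Run the primary mediation analysis end to end
#'
#' Simulates (or ingests) the panel, assembles the woman-level analysis
#' table, fits the random-intercept total-effect models, the FIML path
#' model with cluster-robust variance and fit indices, and decomposes the
#' intervention effect with Monte Carlo confidence intervals.
#'
#' @param config a [run_config()].
#' @return a `mediation_report` list with the analysis table, total-effect
#'   table, fitted model, fit indices, decomposition and metadata (config
#'   hash, seed, sample sizes). Written to `config$output_dir` when set.
#' @export
run_primary <- function(config = run_config()) {
  dat <- pipeline_data(config)
  tab <- assemble_analysis_table(dat$panel, dat$baseline,
                                 drop_ramadan = config$ramadan_exclusion)
  res <- run_on_table(tab, config)
  report <- c(list(config_hash = config_hash_of(config),
                   seed = config$seed, outcome = config$outcome,
                   analysis_table = tab, truth = dat$truth), res)
  class(report) <- c("mediation_report", "list")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

pipeline_data <- function(config) {
  if (is.null(config$input)) {
    gen <- generate_dataset(config$generator, seed = config$seed)
    list(panel = gen$panel, baseline = gen$baseline, truth = gen$truth)
  } else {
    panel <- config$input$panel
    baseline <- config$input$baseline
    if (is.character(panel)) panel <- read_panel_csv(panel)
    if (is.character(baseline)) baseline <- read_baseline_csv(baseline)
    list(panel = panel, baseline = baseline, truth = NULL)
  }
}

stratum_definitions <- function() {
  list(
    religion = function(tab) factor(ifelse(tab$religion_muslim == 1,
                                           "muslim", "hindu")),
    wealth = function(tab) factor(ifelse(tab$wealth_quintile <= 2,
                                         "low", "high")),
    education = function(tab) factor(ifelse(tab$education <= 2,
                                            "low", "high"))
  )
}

# Covariates that index the stratifier are dropped inside strata.
stratifier_covariates <- function(stratifier) {
  switch(stratifier,
         religion = "religion_muslim",
         wealth = paste0("wealth_q", 2:5),
         education = "education",
         character())
}

#' Heterogeneity analysis: independent fits per stratum
#'
#' Splits the analysis table by religion, wealth (quintiles 1--2 vs 3--5)
#' or education (none/primary vs at least partial secondary), refits the
#' full path model independently per stratum (no pooling; the stratifier's
#' covariate columns are dropped), and tabulates domain proportions
#' mediated across strata.
#'
#' @param config a [run_config()].
#' @param stratifier `"religion"`, `"wealth"` or `"education"`.
#' @return list with per-stratum `mediation_report`s (`strata`) and a
#'   `comparison` tibble of domain proportions.
#' @export
run_stratified <- function(config = run_config(),
                           stratifier = c("religion", "wealth", "education")) {
  stratifier <- match.arg(stratifier)
  dat <- pipeline_data(config)
  tab <- assemble_analysis_table(dat$panel, dat$baseline,
                                 drop_ramadan = config$ramadan_exclusion)
  levels_fn <- stratum_definitions()[[stratifier]]
  strata <- levels_fn(tab)
  if (anyNA(strata)) abort("stratifier undefined for some women.")
  cfg <- config
  cfg$covariates <- setdiff(config$covariates,
                            stratifier_covariates(stratifier))
  out <- list()
  for (lv in levels(strata)) {
    sub <- tab[strata == lv, , drop = FALSE]
    if (nrow(sub) < config$min_stratum) {
      warn(sprintf("stratum %s = %s has %d women (< %d); skipped.",
                   stratifier, lv, nrow(sub), config$min_stratum))
      next
    }
    res <- run_on_table(sub, cfg, label = paste0(stratifier, ":", lv))
    res$analysis_table <- sub
    out[[lv]] <- res
  }
  comparison <- purrr::imap_dfr(out, function(res, lv) {
    d <- res$decomposition
    dplyr::filter(d, .data$type == "domain" | .data$effect == "total_indirect") |>
      dplyr::transmute(stratum = lv, effect = .data$effect,
                       estimate = .data$estimate,
                       prop_mediated = .data$prop_mediated)
  })
  list(stratifier = stratifier, strata = out, comparison = comparison,
       config_hash = config_hash_of(config))
}

#' Pre-specified analysis variants
#'
#' * `ramadan_sensitivity`: re-aggregates the outcome excluding survey
#'   rounds flagged as Ramadan.
#' * `mdd_outcome`: swaps the outcome to the proportion of rounds meeting
#'   minimum dietary diversity in the same path-model machinery.
#' * `empowerment_mediators`: extends the mediator set with the endline
#'   empowerment indicators (`empw*` columns) as an extra domain — direct
#'   paths only, no market legs, residual correlations allowed among them.
#'
#' @param config a [run_config()].
#' @param variant one of the names above.
#' @return a `mediation_report`.
#' @export
run_variant <- function(config = run_config(),
                        variant = c("ramadan_sensitivity", "mdd_outcome",
                                    "empowerment_mediators")) {
  variant <- tryCatch(match.arg(variant), error = function(e)
    abort(paste("unknown variant; valid:",
                "ramadan_sensitivity, mdd_outcome, empowerment_mediators")))
  if (variant == "ramadan_sensitivity") {
    cfg <- config; cfg$ramadan_exclusion <- TRUE
    return(run_primary(cfg))
  }
  if (variant == "mdd_outcome") {
    cfg <- config; cfg$outcome <- "mdd_prop"
    return(run_primary(cfg))
  }
  # empowerment_mediators
  dat <- pipeline_data(config)
  tab <- assemble_analysis_table(dat$panel, dat$baseline,
                                 drop_ramadan = config$ramadan_exclusion)
  emp <- grep("^empw", names(tab), value = TRUE)
  if (!length(emp)) abort("no empw* empowerment mediator columns available.")
  res <- run_on_table(tab, config, label = "empowerment",
                      extra_mediators = emp)
  report <- c(list(config_hash = config_hash_of(config),
                   seed = config$seed, outcome = config$outcome,
                   analysis_table = tab, truth = dat$truth), res)
  class(report) <- c("mediation_report", "list")
  report
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf("Mediation analysis report [%s]: %d women in %d clusters\n",
              x$label, x$n_women, x$n_clusters))
  cat(sprintf("  outcome: %s; config hash %s; seed %d\n",
              x$outcome, x$config_hash, x$seed))
  fi <- x$fit_indices
  cat(sprintf("  fit: chi2(%d) = %.1f, CFI %.3f, TLI %.3f, RMSEA %.3f\n",
              fi$df, fi$chisq, fi$cfi, fi$tli, fi$rmsea))
  print(format_decomposition(x$decomposition), n = 30)
  invisible(x)
}

#' Render a decomposition for display
#'
#' Rounds effects to 3 decimals and proportions to 1 decimal (display
#' only; stored estimates stay unrounded).
#' @param decomp decomposition tibble.
#' @return tibble.
#' @export
format_decomposition <- function(decomp) {
  out <- dplyr::transmute(
    decomp, label = .data$label, type = .data$type,
    estimate = round(.data$estimate, 3))
  if ("conf.low" %in% names(decomp)) {
    out$conf.low <- round(decomp$conf.low, 3)
    out$conf.high <- round(decomp$conf.high, 3)
  }
  if ("prop_mediated" %in% names(decomp)) {
    out$prop_mediated <- round(decomp$prop_mediated, 1)
  }
  out
}

# Fitted-parameter export: label, estimate, naive and cluster-robust SEs,
# Wald z and p (cluster-robust).
parameter_table <- function(fit, V) {
  idx <- fit$coef_idx
  est <- setNames(fit$theta[idx], fit$map$labels[idx])
  naive <- attr(V, "naive")
  w <- wald_tests(est, V[names(est), names(est), drop = FALSE])
  dplyr::mutate(w, se_naive = sqrt(diag(naive[names(est), names(est),
                                              drop = FALSE]))) |>
    dplyr::select("term", "estimate", "se_naive",
                  se_cluster = "std.error", z = "statistic",
                  p = "p.value")
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$analysis_table, file.path(dir, "analysis_table.csv"))
  readr::write_csv(parameter_table(report$fit, report$vcov_cluster),
                   file.path(dir, "parameters.csv"))
  readr::write_csv(format_decomposition(report$decomposition),
                   file.path(dir, "decomposition.csv"))
  readr::write_csv(report$total_effects, file.path(dir, "total_effects.csv"))
  json <- list(
    config_hash = report$config_hash, seed = report$seed,
    outcome = report$outcome, label = report$label,
    n_women = report$n_women, n_clusters = report$n_clusters,
    fit_indices = lapply(as.list(report$fit_indices), round, digits = 6),
    decomposition = format_decomposition(report$decomposition))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
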