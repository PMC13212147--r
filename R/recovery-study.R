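# Parameter-recovery and interval-coverage simulation study.

#' Scaled-down parameter-recovery study
#'
#' Repeatedly simulates a scaled-down trial (by default 40 settlements of
#' ~15 women) at the generator's default truth, fits the full path model
#' per replicate, and computes the Monte Carlo percentile interval for the
#' total indirect effect from the cluster-robust coefficient covariance.
#' The result supports two summaries: mean bias of the estimated total
#' indirect effect against the configured truth, and empirical coverage of
#' the nominal 95% interval.
#'
#' @param seeds integer vector; one replicate is generated, fitted and
#'   summarized per seed.
#' @param config generator configuration shared by all replicates.
#' @param covariates covariate set entering every equation.
#' @param mc_reps Monte Carlo repetitions per interval.
#' @param level interval level.
#' @return tibble with one row per replicate: `seed`, `estimate`,
#'   `conf.low`, `conf.high`, `covered`, `converged`, plus the scalar
#'   attribute `truth`.
#' @export
recovery_study <- function(seeds = 1:100,
                           config = generator_config(
                             n_clusters = 40, allocation = c(20, 20),
                             cluster_size_mean = 15),
                           covariates = default_covariates(),
                           mc_reps = 2000L, level = 0.95) {
  spec <- build_model_spec(c(MED_KEYS, "market"), covariates = covariates)
  truth_tab <- implied_true_effects(config)
  truth <- truth_tab$truth[truth_tab$effect == "total_indirect"]
  labels <- path_labels(default_domains(),
                        unlist(default_domains(), use.names = FALSE), "market")
  rows <- purrr::map_dfr(seeds, function(s) {
    gen <- generate_dataset(config, seed = s)
    tab <- suppressMessages(assemble_analysis_table(gen$panel, gen$baseline))
    mf <- build_model_frame(tab, "dds_mean", covariates)
    fit <- fit_path_model(spec, mf)
    V <- cluster_robust_vcov(fit, tab$cluster_id)
    ci <- monte_carlo_ci(fit, V, n_reps = mc_reps, seed = s, level = level)
    r <- ci[ci$effect == "total_indirect", ]
    dplyr::bind_cols(
      tibble(seed = s, estimate = r$estimate,
             conf.low = r$conf.low, conf.high = r$conf.high,
             covered = r$conf.low <= truth & truth <= r$conf.high,
             converged = fit$convergence$converged),
      as_tibble(as.list(extract_path_coefs(fit, labels))))
  })
  attr(rows, "truth") <- truth
  attr(rows, "truth_paths") <- c(
    setNames(unlist(config$paths$a), paste0("a_", names(config$paths$a))),
    setNames(unlist(config$paths$b), paste0("b_", names(config$paths$b))),
    setNames(unlist(config$paths$d), paste0("d_", names(config$paths$d))),
    direct = config$paths$direct)
  rows
}
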