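# Shared fixtures and oracle helpers. Everything is built in code at test
# time; no stored data.

quiet_assemble <- function(...) suppressMessages(assemble_analysis_table(...))

# Hand fixture: three women, two rounds each, granular columns.
toy_panel <- function() {
  tibble::tribble(
    ~woman_id, ~cluster_id, ~arm, ~round_index, ~ramadan,
    "w1", "c1", 0L, 1L, 0,
    "w1", "c1", 0L, 2L, 0,
    "w2", "c1", 0L, 1L, 0,
    "w2", "c1", 0L, 2L, 1,
    "w3", "c2", 1L, 1L, 0,
    "w3", "c2", 1L, 2L, 0
  ) |>
    dplyr::mutate(
      # w1: DDS 4 then 6; w2: DDS 5 then 7; w3: recall absent both rounds
      fg_01 = c(1, 1, 1, 1, NA, NA), fg_02 = c(1, 1, 1, 1, NA, NA),
      fg_03 = c(1, 1, 1, 1, NA, NA), fg_04 = c(1, 1, 1, 1, NA, NA),
      fg_05 = c(0, 1, 1, 1, NA, NA), fg_06 = c(0, 1, 0, 1, NA, NA),
      fg_07 = c(0, 0, 0, 1, NA, NA), fg_08 = c(0, 0, 0, 0, NA, NA),
      fg_09 = c(0, 0, 0, 0, NA, NA), fg_10 = c(0, 0, 0, 0, NA, NA),
      crop_species_harvested = c(4, 6, 3, NA, 8, 8),
      n_poultry = c(2, 2, 1, 1, 5, 5),
      n_eggs_week = c(3, 3, 0, 0, 7, 7),
      garden_practices_score = c(5, 5, 2, 2, 11, 11),
      dd_knowledge_score = c(3, 3, NA, NA, 4, 4),
      fg_knowledge_score = c(2, 2, NA, NA, 5, 5),
      market_bought = c(1, 1, 0, 0, 1, 1),
      market_sold = c(0, 0, 0, 0, 1, 1),
      market_went = c(1, 0, 0, 0, 1, 1)
    )
}

toy_baseline <- function() {
  tibble::tibble(woman_id = c("w1", "w2", "w3"),
                 baseline_dds = c(3.5, 4.0, 4.5),
                 religion_muslim = c(1, 0, 1))
}

# Small-trial generator settings used across estimation tests.
small_config <- function(...) {
  generator_config(n_clusters = 20, allocation = c(10, 10),
                   cluster_size_mean = 10, ...)
}

core_mediators <- c("crop", "prac", "pltry", "egg", "fgknow", "ddknow", "market")

full_covariates <- pathmediate:::default_covariates()

# Reduced covariate set for tests where estimation speed matters more than
# the full design.
slim_covariates <- c("religion_muslim", "education", "baseline_dds")

model_frame_of <- function(tab, outcome = "dds_mean", covs = full_covariates) {
  pathmediate:::build_model_frame(tab, outcome, covs)
}

spec_of <- function(covs = full_covariates) {
  build_model_spec(core_mediators, covariates = covs)
}

# Pack the generator's true parameters into the model's theta vector.
# Marginal residual covariance adds the independent cluster-effect
# variances to the diagonal and the per-round diet noise (spread over
# n_rounds) to the outcome.
config_true_theta <- function(config, spec, mode = "fixed",
                              n_rounds_obs = config$n_rounds) {
  map <- pathmediate:::param_map(spec, mode)
  endo <- map$endo
  stopifnot(identical(sort(endo), sort(pathmediate:::ENDO_KEYS)))
  alpha <- unlist(config$intercepts)[endo]
  B <- matrix(0, length(endo), length(endo), dimnames = list(endo, endo))
  for (k in pathmediate:::MED_KEYS) B["market", k] <- config$paths$d[[k]]
  for (k in pathmediate:::MED_KEYS) B["dds", k] <- config$paths$b[[k]]
  B["dds", "market"] <- config$paths$b$market
  G <- matrix(0, length(endo), map$q, dimnames = list(endo, map$exo))
  for (k in c(pathmediate:::MED_KEYS, "market")) G[k, "trt"] <- config$paths$a[[k]]
  G["dds", "trt"] <- config$paths$direct
  for (k in names(config$gamma)) {
    for (cv in names(config$gamma[[k]])) {
      if (cv %in% colnames(G)) G[k, cv] <- config$gamma[[k]][[cv]]
    }
  }
  Psi <- pathmediate:::config_psi(config)[endo, endo]
  sds <- unlist(config$residual_sd)[endo]
  diag(Psi) <- diag(Psi) + (config$cluster_sd_frac * sds)^2
  Psi["dds", "dds"] <- Psi["dds", "dds"] + config$round_sd^2 / n_rounds_obs
  pathmediate:::pack_theta(map, alpha, B, G, Psi)
}

fd_gradient_subset <- function(f, x, idx, h = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xm <- x
    hi <- h * max(1, abs(x[i]))
    xp[i] <- xp[i] + hi; xm[i] <- xm[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}

# Brute-force per-row FIML log-likelihood oracle: direct marginal normal
# density per row via solve() and determinant().
loglik_bruteforce <- function(Y, mu_rows, Sigma) {
  sum(vapply(seq_len(nrow(Y)), function(i) {
    ob <- which(!is.na(Y[i, ]))
    S <- Sigma[ob, ob, drop = FALSE]
    r <- Y[i, ob] - mu_rows[i, ob]
    -0.5 * (length(ob) * log(2 * pi) +
              as.numeric(determinant(S)$modulus) +
              drop(r %*% solve(S, r)))
  }, numeric(1)))
}
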