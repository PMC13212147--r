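# synthetic_data: cluster-randomized panel generator with linear-Gaussian
# mediator/outcome structure and known true path coefficients.

MED_KEYS <- c("crop", "prac", "pltry", "egg", "fgknow", "ddknow")
ENDO_KEYS <- c(MED_KEYS, "market", "dds")

# analysis-table column for each model variable
MED_COLS <- c(crop = "crop_richness_mean", prac = "garden_practices_score",
              pltry = "poultry_mean", egg = "eggs_mean",
              fgknow = "fg_knowledge_score", ddknow = "dd_knowledge_score",
              market = "market_score")

default_covariates <- function() {
  c("religion_muslim", paste0("wealth_q", 2:5), "log_homestead_land",
    "log_agri_land", "baseline_crop_richness", "baseline_market_score",
    "education", "emp_social_support", "emp_comm_husband",
    "emp_external_comm", "emp_decision", "emp_mobility", "emp_income",
    "baseline_dds")
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Synthetic-trial generator configuration
#'
#' Loads the packaged default configuration (96 settlements randomized 1:1,
#' ~27 women per settlement, covariate distributions matching the trial's
#' baseline table, true path coefficients mirroring the published effect
#' sizes) and applies any overrides. See
#' `system.file("extdata/default_generator_config.yaml", package = "pathmediate")`
#' for every field.
#'
#' @param ... named overrides, nested lists merged into the defaults
#'   (e.g. `n_clusters = 40`, `paths = list(direct = 0)`).
#' @param file optional YAML file to load instead of the packaged defaults.
#' @return a `generator_config` list.
#' @export
generator_config <- function(..., file = NULL) {
  path <- file %||% system.file("extdata", "default_generator_config.yaml",
                                package = "pathmediate")
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      abort("overrides must be named.")
    }
    cfg <- deep_merge(cfg, dots)
  }
  validate_generator_config(cfg)
  structure(cfg, class = c("generator_config", "list"))
}

validate_generator_config <- function(cfg) {
  if (sum(unlist(cfg$allocation)) != cfg$n_clusters) {
    abort("allocation must sum to n_clusters.")
  }
  sds <- unlist(cfg$residual_sd)
  if (any(sds <= 0)) abort("all residual sds must be > 0.")
  R <- gp_cor_matrix(cfg)
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("garden/poultry residual correlation matrix is not positive definite.")
  }
  if (abs(cfg$residual_cor$knowledge) >= 1) {
    abort("knowledge residual correlation must lie in (-1, 1).")
  }
  pat <- unlist(cfg$missingness$rounds_pattern)
  if (abs(sum(pat) - 1) > 1e-9) abort("rounds_pattern proportions must sum to 1.")
  invisible(cfg)
}

gp_cor_matrix <- function(cfg) {
  R <- do.call(rbind, lapply(cfg$residual_cor$garden_poultry, unlist))
  dimnames(R) <- list(c("crop", "prac", "pltry", "egg"),
                      c("crop", "prac", "pltry", "egg"))
  R
}

# Residual covariance of the 8 endogenous variables implied by the config
# (structural residuals only; no cluster effects, no round noise).
config_psi <- function(cfg) {
  sds <- unlist(cfg$residual_sd)[ENDO_KEYS]
  Psi <- diag(sds^2)
  dimnames(Psi) <- list(ENDO_KEYS, ENDO_KEYS)
  blk <- c("crop", "prac", "pltry", "egg")
  R <- gp_cor_matrix(cfg)[blk, blk]
  Psi[blk, blk] <- R * tcrossprod(sds[blk])
  kn <- c("fgknow", "ddknow")
  Psi[kn, kn] <- matrix(c(1, cfg$residual_cor$knowledge,
                          cfg$residual_cor$knowledge, 1), 2) * tcrossprod(sds[kn])
  Psi
}

#' True direct/indirect effects implied by a generator configuration
#'
#' Closed-form products and sums of the configured path coefficients,
#' mirroring the rows of the effect decomposition so simulation studies can
#' compare estimates with truth by effect name.
#'
#' @param config a [generator_config()].
#' @return tibble with columns `effect`, `label`, `type`, `domain`, `truth`.
#' @export
implied_true_effects <- function(config = generator_config()) {
  co <- c(setNames(unlist(config$paths$a), paste0("a_", names(config$paths$a))),
          setNames(unlist(config$paths$b), paste0("b_", names(config$paths$b))),
          setNames(unlist(config$paths$d), paste0("d_", names(config$paths$d))),
          direct = config$paths$direct)
  effect_algebra(co) |>
    dplyr::rename(truth = "value")
}

draw_covariates <- function(n, cv) {
  wealth <- sample.int(5L, n, replace = TRUE, prob = unlist(cv$wealth_probs))
  edu <- sample.int(5L, n, replace = TRUE, prob = unlist(cv$education_probs)) - 1L
  tibble(
    religion_muslim = rbinom(n, 1, cv$religion_muslim_prob),
    wealth_quintile = wealth,
    wealth_q2 = as.integer(wealth == 2), wealth_q3 = as.integer(wealth == 3),
    wealth_q4 = as.integer(wealth == 4), wealth_q5 = as.integer(wealth == 5),
    log_homestead_land = rnorm(n, cv$homestead_land_meanlog, cv$homestead_land_sdlog),
    log_agri_land = rnorm(n, cv$agri_land_meanlog, cv$agri_land_sdlog),
    baseline_crop_richness = pmax(0, rnorm(n, cv$baseline_crop_mean, cv$baseline_crop_sd)),
    baseline_market_score = pmax(0, rnorm(n, cv$baseline_market_mean, cv$baseline_market_sd)),
    education = edu,
    emp_social_support = rnorm(n, cv$emp_social_support_mean, cv$emp_social_support_sd),
    emp_comm_husband = rnorm(n, cv$emp_comm_husband_mean, cv$emp_comm_husband_sd),
    emp_external_comm = rnorm(n, cv$emp_external_comm_mean, cv$emp_external_comm_sd),
    emp_decision = rnorm(n, cv$emp_decision_mean, cv$emp_decision_sd),
    emp_mobility = rbinom(n, 1, cv$emp_mobility_prob),
    emp_income = rbinom(n, 1, cv$emp_income_prob),
    baseline_dds = rnorm(n, cv$baseline_dds_mean, cv$baseline_dds_sd)
  )
}

# linear predictor contribution of configured covariate loadings
gamma_contrib <- function(cfg_gamma, key, X) {
  g <- cfg_gamma[[key]]
  if (is.null(g)) return(0)
  out <- 0
  for (nm in names(g)) out <- out + g[[nm]] * X[[nm]]
  out
}

#' Generate a synthetic cluster-randomized trial dataset
#'
#' Draws settlement-level treatment assignment (balanced per the
#' allocation), baseline covariates, correlated mediators, market activity
#' and the dietary-diversity outcome from the configured linear path system
#' with settlement-level random intercepts, then expands the outcome into
#' per-round diet observations. By default the configured missingness
#' pattern is applied; pass `missingness = FALSE` for complete data.
#'
#' Default generation is linear-Gaussian without truncating scores to their
#' questionnaire ranges, so fitted linear path models can recover the
#' configured coefficients exactly up to sampling noise. With
#' `clamp = TRUE` in the config, per-round scores are rounded into range
#' and expanded into granular indicator columns (food groups, practice and
#' knowledge items, market components), exercising the full score-building
#' pipeline at the cost of discretization attenuation.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; the same (config, seed) pair reproduces the
#'   dataset exactly.
#' @param missingness apply the configured missingness pattern?
#' @return list with `panel` (long-format tibble), `baseline` (woman-level
#'   covariates, plus endline empowerment mediators when configured) and
#'   `truth` (tibble from [implied_true_effects()]).
#' @export
generate_dataset <- function(config = generator_config(), seed = 1,
                             missingness = TRUE) {
  validate_generator_config(config)
  set.seed(seed)
  G <- config$n_clusters
  arm_cl <- sample(rep(c(0L, 1L), times = unlist(config$allocation)))
  sizes <- pmax(1L, rpois(G, config$cluster_size_mean))
  n <- sum(sizes)
  cluster_id <- rep(sprintf("c%03d", seq_len(G)), times = sizes)
  arm <- rep(arm_cl, times = sizes)
  woman_id <- sprintf("w%05d", seq_len(n))

  X <- draw_covariates(n, config$covariates)

  sds <- unlist(config$residual_sd)[ENDO_KEYS]
  u_cl <- sapply(ENDO_KEYS, function(k)
    rep(rnorm(G, 0, config$cluster_sd_frac * sds[[k]]), times = sizes))

  blk <- c("crop", "prac", "pltry", "egg")
  Psi <- config_psi(config)
  e_gp <- rmvnorm_chol(n, rep(0, 4), Psi[blk, blk])
  kn <- c("fgknow", "ddknow")
  e_kn <- rmvnorm_chol(n, rep(0, 2), Psi[kn, kn])
  e <- cbind(e_gp, e_kn, market = rnorm(n, 0, sds[["market"]]),
             dds = rnorm(n, 0, sds[["dds"]]))
  colnames(e) <- ENDO_KEYS

  a <- config$paths$a; b <- config$paths$b; d <- config$paths$d
  al <- config$intercepts
  M <- sapply(MED_KEYS, function(k) {
    al[[k]] + a[[k]] * arm + gamma_contrib(config$gamma, k, X) +
      u_cl[, k] + e[, k]
  })
  market <- al$market + a$market * arm +
    gamma_contrib(config$gamma, "market", X) +
    as.numeric(M %*% unlist(d)[MED_KEYS]) + u_cl[, "market"] + e[, "market"]

  emp <- NULL
  ec <- config$empowerment
  if (isTRUE(ec$include) && ec$n_mediators > 0) {
    Re <- matrix(ec$cor, ec$n_mediators, ec$n_mediators); diag(Re) <- 1
    emp <- rmvnorm_chol(n, rep(ec$mean, ec$n_mediators), Re * ec$sd^2) +
      matrix(ec$a * arm, n, ec$n_mediators)
    colnames(emp) <- paste0("empw", seq_len(ec$n_mediators))
  }

  ystar <- al$dds + config$paths$direct * arm +
    as.numeric(M %*% unlist(b)[MED_KEYS]) + b$market * market +
    gamma_contrib(config$gamma, "dds", X) + u_cl[, "dds"] + e[, "dds"] +
    (if (!is.null(emp) && ec$b != 0) rowSums(emp) * ec$b else 0)

  n_rounds <- config$n_rounds
  round_dates <- as.Date("2018-03-01") + round(182.5 * (seq_len(n_rounds) - 1))
  panel <- tidyr::expand_grid(i = seq_len(n), round_index = seq_len(n_rounds)) |>
    dplyr::mutate(
      woman_id = woman_id[.data$i],
      cluster_id = cluster_id[.data$i],
      arm = arm[.data$i],
      round_date = round_dates[.data$round_index],
      ramadan = rbinom(dplyr::n(), 1, config$ramadan_round_prob),
      dds = ystar[.data$i] + rnorm(dplyr::n(), 0, config$round_sd),
      crop_species_harvested = M[.data$i, "crop"],
      garden_practices_score = M[.data$i, "prac"],
      n_poultry = M[.data$i, "pltry"],
      n_eggs_week = M[.data$i, "egg"],
      fg_knowledge_score = M[.data$i, "fgknow"],
      dd_knowledge_score = M[.data$i, "ddknow"],
      market_score = market[.data$i]
    ) |>
    dplyr::select(-"i")

  if (isTRUE(config$clamp)) panel <- clamp_panel(panel)

  baseline <- dplyr::bind_cols(tibble(woman_id = woman_id), X)
  if (!is.null(emp)) baseline <- dplyr::bind_cols(baseline, as_tibble(emp))

  if (isTRUE(missingness)) {
    panel <- impose_missingness(panel,
                                pattern = unlist(config$missingness$rounds_pattern),
                                variable_rates = config$missingness$variable_rates,
                                seed = seed + 500421L)
  }

  list(panel = panel, baseline = baseline,
       truth = implied_true_effects(config), config = config, seed = seed)
}

# Round per-round scores into questionnaire range and expand into granular
# indicator columns (first-k-items coding; item identity carries no signal).
clamp_panel <- function(panel) {
  first_k <- function(k, cols) {
    m <- matrix(NA_real_, length(k), length(cols), dimnames = list(NULL, cols))
    ok <- !is.na(k)
    m[ok, ] <- 0
    for (j in seq_along(cols)) m[ok & k >= j, j] <- 1
    as_tibble(m)
  }
  clampi <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))
  out <- panel |>
    dplyr::mutate(
      dds = clampi(.data$dds, 0, 10),
      crop_species_harvested = clampi(.data$crop_species_harvested, 0, Inf),
      n_poultry = clampi(.data$n_poultry, 0, Inf),
      n_eggs_week = clampi(.data$n_eggs_week, 0, Inf),
      garden_practices_score = clampi(.data$garden_practices_score, 0, 17),
      fg_knowledge_score = clampi(.data$fg_knowledge_score, 0, 5),
      dd_knowledge_score = clampi(.data$dd_knowledge_score, 0, 4),
      market_score = clampi(.data$market_score, 0, 3)
    )
  dplyr::bind_cols(
    dplyr::select(out, -"dds", -"garden_practices_score",
                  -"fg_knowledge_score", -"dd_knowledge_score", -"market_score"),
    first_k(out$dds, FG_COLS),
    first_k(out$garden_practices_score, GP_COLS),
    first_k(out$fg_knowledge_score, FGK_COLS),
    first_k(out$dd_knowledge_score, DDK_COLS),
    first_k(out$market_score, MKT_COLS)
  )
}

#' Impose the trial's round-count and per-variable missingness pattern
#'
#' Each woman's number of observed diet rounds is drawn from the configured
#' pattern (default 75/12/5/8% for 4/3/2/1 rounds, matching the trial);
#' which rounds are observed is uniform given the count. Mediator measures
#' are then knocked out per woman at the configured per-variable rates
#' (missing completely at random).
#'
#' @param panel long-format panel tibble.
#' @param pattern probabilities for 4, 3, 2, 1 observed diet rounds, in that
#'   order (named `r4`..`r1` or positional); must sum to 1.
#' @param variable_rates named list of per-variable missingness
#'   probabilities keyed by mediator (`crop`, `prac`, `pltry`, `egg`,
#'   `fgknow`, `ddknow`, `market`); `NULL` for none.
#' @param seed integer seed; identical seeds give identical masks.
#' @return panel with absences as `NA`.
#' @export
impose_missingness <- function(panel, pattern = c(r4 = 0.75, r3 = 0.12,
                                                  r2 = 0.05, r1 = 0.08),
                               variable_rates = NULL, seed = 1) {
  pattern <- unlist(pattern)
  if (abs(sum(pattern) - 1) > 1e-9) abort("pattern proportions must sum to 1.")
  set.seed(seed)
  women <- unique(panel$woman_id)
  nw <- length(women)
  counts <- c(4L, 3L, 2L, 1L)[sample.int(4L, nw, replace = TRUE, prob = pattern)]
  names(counts) <- women

  rounds_present <- sort(unique(panel$round_index))
  keep_key <- paste0(rep(women, each = length(rounds_present)),
                     "#", rounds_present)
  keep <- setNames(rep(FALSE, length(keep_key)), keep_key)
  for (w in women) {
    obs <- sample(rounds_present, min(counts[[w]], length(rounds_present)))
    keep[paste0(w, "#", obs)] <- TRUE
  }
  row_keep <- keep[paste0(panel$woman_id, "#", panel$round_index)]

  diet_cols <- intersect(c("dds", FG_COLS), names(panel))
  for (cl in diet_cols) panel[[cl]][!row_keep] <- NA_real_

  if (!is.null(variable_rates)) {
    col_groups <- list(
      crop = "crop_species_harvested",
      prac = intersect(c("garden_practices_score", GP_COLS), names(panel)),
      pltry = "n_poultry", egg = "n_eggs_week",
      fgknow = intersect(c("fg_knowledge_score", FGK_COLS), names(panel)),
      ddknow = intersect(c("dd_knowledge_score", DDK_COLS), names(panel)),
      market = intersect(c("market_score", MKT_COLS), names(panel))
    )
    for (key in names(variable_rates)) {
      rate <- variable_rates[[key]]
      if (is.null(rate) || rate <= 0) next
      drop_women <- women[runif(nw) < rate]
      cols <- intersect(col_groups[[key]], names(panel))
      hit <- panel$woman_id %in% drop_women
      for (cl in cols) panel[[cl]][hit] <- NA_real_
    }
  }
  panel
}
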