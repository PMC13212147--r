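test_that("implied true effects are exact coefficient arithmetic", {
  truth <- implied_true_effects(generator_config())
  cfg <- generator_config()
  a <- unlist(cfg$paths$a); b <- unlist(cfg$paths$b); d <- unlist(cfg$paths$d)
  meds <- pathmediate:::MED_KEYS
  # independent summation of every product
  ind <- a[meds] * b[meds]
  via <- a[meds] * d[meds] * b[["market"]]
  mkt <- a[["market"]] * b[["market"]]
  total_ind <- sum(ind) + sum(via) + mkt
  expect_equal(truth$truth[truth$effect == "total_indirect"], total_ind)
  expect_equal(truth$truth[truth$effect == "total"],
               total_ind + cfg$paths$direct)
  expect_equal(truth$truth[truth$effect == "dom_garden"],
               ind[["crop"]] + ind[["prac"]])
  # the default truth reproduces the trial's published effect sizes
  expect_equal(truth$truth[truth$effect == "total_indirect"], 0.433,
               tolerance = 1e-8)
  expect_equal(truth$truth[truth$effect == "total"], 0.423, tolerance = 1e-8)
})

test_that("zero a-paths imply zero indirect effects and total = direct", {
  zero_a <- as.list(setNames(rep(0, 7), c(pathmediate:::MED_KEYS, "market")))
  cfg <- generator_config(paths = list(a = zero_a, direct = 0.25))
  truth <- implied_true_effects(cfg)
  expect_equal(truth$truth[truth$effect == "total_indirect"], 0)
  expect_equal(truth$truth[truth$effect == "total"], 0.25)
  expect_true(all(truth$truth[truth$type == "individual"] == 0))
})

test_that("a single unit mediator path gives unit indirect effect", {
  co <- c(a_m = 1, b_m = 1, direct = 0)
  out <- effect_algebra(co, domains = list(solo = "m"), via_market = character(),
                        market = NULL)
  expect_equal(out$value[out$effect == "total_indirect"], 1)
  expect_equal(out$value[out$effect == "total"], 1)
})

test_that("cluster allocation is exactly balanced and reproducible", {
  cfg <- small_config()
  gen <- generate_dataset(cfg, seed = 5)
  arms <- dplyr::distinct(gen$panel, cluster_id, arm)
  expect_identical(nrow(arms), 20L)
  expect_identical(sum(arms$arm), 10L)
  gen2 <- generate_dataset(cfg, seed = 5)
  expect_identical(as.data.frame(gen$panel), as.data.frame(gen2$panel))
  gen3 <- generate_dataset(cfg, seed = 6)
  expect_false(identical(gen$panel$dds, gen3$panel$dds))
})

test_that("infeasible residual correlation matrices are rejected before sampling", {
  bad <- list(garden_poultry = list(c(1, .9, .9, -.9), c(.9, 1, .9, .9),
                                    c(.9, .9, 1, .9), c(-.9, .9, .9, 1)))
  expect_error(generator_config(residual_cor = bad), "positive definite")
  expect_error(generator_config(residual_sd = list(crop = -1)), "sds")
  expect_error(generator_config(allocation = c(3, 4)), "allocation")
})

test_that("baseline covariates match the configured trial distributions", {
  cfg <- generator_config()
  gen <- generate_dataset(cfg, seed = 202)
  b <- gen$baseline
  expect_gt(nrow(b), 2000)
  expect_lt(abs(mean(b$baseline_dds) - 3.9), 0.1)
  expect_lt(abs(mean(b$religion_muslim) - 0.68), 0.03)
  expect_lt(abs(mean(b$wealth_quintile <= 2) - 0.46), 0.03)
})

test_that("treatment assignment is independent of baseline covariates", {
  diffs <- replicate(30, {
    gen <- generate_dataset(small_config(), seed = sample.int(1e6, 1),
                            missingness = FALSE)
    tab <- quiet_assemble(gen$panel, gen$baseline)
    mean(tab$baseline_dds[tab$arm == 1]) - mean(tab$baseline_dds[tab$arm == 0])
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("null intervention yields null fitted a-paths over replicates", {
  zero_a <- as.list(setNames(rep(0, 7), c(pathmediate:::MED_KEYS, "market")))
  cfg <- generator_config(n_clusters = 10, allocation = c(5, 5),
                          cluster_size_mean = 6,
                          paths = list(a = zero_a))
  # equation-wise least squares is the ML fit for each complete-data equation
  ests <- t(replicate(200, {
    gen <- generate_dataset(cfg, seed = sample.int(1e6, 1),
                            missingness = FALSE)
    tab <- quiet_assemble(gen$panel, gen$baseline)
    vapply(unname(pathmediate:::MED_COLS), function(col)
      coef(lm(tab[[col]] ~ tab$arm))[[2]], numeric(1))
  }))
  mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(colMeans(ests)) < 3 * mc_se))
})

test_that("outcome ICC tracks the configured cluster effect size", {
  cfg <- generator_config(n_clusters = 300, allocation = c(150, 150),
                          cluster_size_mean = 12, round_sd = 0,
                          paths = list(direct = 0), cluster_sd_frac = 0.5)
  gen <- generate_dataset(cfg, seed = 88, missingness = FALSE)
  tab <- quiet_assemble(gen$panel, gen$baseline)
  f <- fit_random_intercept(tab, "dds_mean", "arm")
  # the dds equation's own cluster effect is (0.5 * 1.0)^2 = 0.25; mediator
  # channels add a little on both sides of the ratio, putting the marginal
  # outcome ICC in the high teens
  expect_gt(f$icc, 0.10)
  expect_lt(f$icc, 0.30)
  cfg0 <- generator_config(n_clusters = 300, allocation = c(150, 150),
                           cluster_size_mean = 12, round_sd = 0,
                           cluster_sd_frac = 0)
  gen0 <- generate_dataset(cfg0, seed = 89, missingness = FALSE)
  tab0 <- quiet_assemble(gen0$panel, gen0$baseline)
  f0 <- fit_random_intercept(tab0, "dds_mean", "arm")
  expect_lt(f0$icc, 0.03)
})

test_that("missingness pattern reproduces the trial's round-count mix", {
  cfg <- generator_config(n_clusters = 96, allocation = c(48, 48),
                          cluster_size_mean = 104)  # ~10,000 women
  gen <- generate_dataset(cfg, seed = 9, missingness = FALSE)
  panel <- impose_missingness(gen$panel, seed = 31)
  counts <- panel |>
    dplyr::group_by(woman_id) |>
    dplyr::summarise(k = sum(!is.na(dds)), .groups = "drop")
  expect_gt(nrow(counts), 9000)
  props <- as.numeric(table(factor(counts$k, levels = 4:1)) / nrow(counts))
  expect_true(all(abs(props - c(0.75, 0.12, 0.05, 0.08)) < 0.02))
})

test_that("missingness is seed-reproducible and a keep-all pattern is a no-op", {
  gen <- generate_dataset(small_config(), seed = 4, missingness = FALSE)
  m1 <- impose_missingness(gen$panel, seed = 77,
                           variable_rates = list(fgknow = 0.3))
  m2 <- impose_missingness(gen$panel, seed = 77,
                           variable_rates = list(fgknow = 0.3))
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  m3 <- impose_missingness(gen$panel, pattern = c(1, 0, 0, 0), seed = 1)
  expect_identical(as.data.frame(m3), as.data.frame(gen$panel))
  expect_error(impose_missingness(gen$panel, pattern = c(.5, .5, .5, 0)),
               "sum to 1")
})

test_that("per-variable missingness rates match the trial per-indicator availability", {
  cfg <- generator_config(n_clusters = 40, allocation = c(20, 20),
                          cluster_size_mean = 50)
  gen <- generate_dataset(cfg, seed = 12)
  tab <- quiet_assemble(gen$panel, gen$baseline)
  expect_lt(abs(mean(is.na(tab$fg_knowledge_score)) - 0.324), 0.05)
  expect_lt(abs(mean(is.na(tab$market_score)) - 0.105), 0.03)
  expect_true(all(!is.na(tab$dds_mean)))
})

test_that("empirical moments match the model-implied covariance at scale", {
  cfg <- generator_config(n_clusters = 500, allocation = c(250, 250),
                          cluster_size_mean = 100, cluster_sd_frac = 0,
                          round_sd = 0)
  gen <- generate_dataset(cfg, seed = 17, missingness = FALSE)
  tab <- quiet_assemble(gen$panel, gen$baseline)
  expect_gt(nrow(tab), 45000)
  covs <- full_covariates
  mf <- model_frame_of(tab, covs = covs)
  spec <- spec_of(covs)
  theta <- config_true_theta(cfg, spec)
  X <- as.matrix(mf[spec$exo])
  mom <- implied_moments(spec, theta = theta, mode = "fixed",
                         exo_mu = colMeans(X),
                         exo_sigma = cov(X) * (nrow(X) - 1) / nrow(X))
  endo <- spec$endo
  emp <- cov(as.matrix(mf[endo]))
  scale <- sqrt(tcrossprod(diag(mom$sigma[endo, endo])))
  expect_lt(max(abs(emp - mom$sigma[endo, endo]) / scale), 0.02)
  mu_emp <- colMeans(as.matrix(mf[endo]))
  expect_lt(max(abs(mu_emp - mom$mu[endo]) / sqrt(diag(mom$sigma[endo, endo]))),
            0.02)
})
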