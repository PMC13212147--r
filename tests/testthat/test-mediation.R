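# Effect decomposition and Monte Carlo intervals.

fitted_example <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_dataset(small_config(), seed = 51)
      tab <- quiet_assemble(gen$panel, gen$baseline)
      mf <- model_frame_of(tab, covs = slim_covariates)
      fit <- fit_path_model(spec_of(slim_covariates), mf)
      V <- cluster_robust_vcov(fit, tab$cluster_id)
      cache <<- list(fit = fit, V = V, tab = tab)
    }
    cache
  }
})

test_that("decomposition identities hold on a fitted model", {
  ex <- fitted_example()
  d <- decompose_effects(ex$fit)
  g <- function(e) d$estimate[d$effect == e]
  expect_equal(g("total"), g("direct") + g("total_indirect"))
  expect_equal(g("total_indirect"),
               g("dom_garden") + g("dom_poultry") + g("dom_knowledge") +
                 g("dom_market"))
  expect_equal(g("dom_garden"), g("ind_prac") + g("ind_crop"))
  expect_equal(g("dom_garden_mkt"), g("dom_garden") + g("via_prac") + g("via_crop"))
  expect_equal(g("dom_market"), g("ind_market_alone") + g("via_market_sum"))
  # 14 individual rows, 7 domain rows, 3 summary rows
  expect_equal(sum(d$type == "individual"), 14)
  expect_equal(sum(d$type == "domain"), 7)
  expect_equal(sum(d$type == "summary"), 3)
})

test_that("a missing path is reported by name", {
  ex <- fitted_example()
  expect_error(
    decompose_effects(ex$fit, domains = list(garden = c("prac", "crop"),
                                             poultry = c("pltry", "egg"),
                                             knowledge = c("fgknow", "nosuch"))),
    "nosuch")
})

test_that("zero covariance collapses intervals onto the point estimates", {
  ex <- fitted_example()
  V0 <- ex$V * 0
  ci <- monte_carlo_ci(ex$fit, V0, n_reps = 2000, seed = 1)
  expect_equal(ci$conf.low, ci$estimate, tolerance = 1e-12)
  expect_equal(ci$conf.high, ci$estimate, tolerance = 1e-12)
})

test_that("Monte Carlo intervals are reproducible given the seed", {
  ex <- fitted_example()
  ci1 <- monte_carlo_ci(ex$fit, ex$V, n_reps = 2000, seed = 9)
  ci2 <- monte_carlo_ci(ex$fit, ex$V, n_reps = 2000, seed = 9)
  expect_identical(ci1, ci2)
  ci3 <- monte_carlo_ci(ex$fit, ex$V, n_reps = 2000, seed = 10)
  expect_false(identical(ci1$conf.low, ci3$conf.low))
})

test_that("a single product interval matches a direct simulation of a*b", {
  # stand-alone check of the sampling construction: one mediator, known
  # normal sampling distribution for (a, b)
  mu <- c(a = 0.8, b = 0.3)
  V <- matrix(c(0.04, 0.01, 0.01, 0.0225), 2,
              dimnames = list(c("m~trt", "y~m"), c("m~trt", "y~m")))
  fake_fit <- list(estimates = setNames(mu, c("m~trt", "y~m")))
  # direct large-sample simulation of the product distribution
  set.seed(123)
  Z <- matrix(rnorm(4e5), ncol = 2) %*% chol(unname(V))
  prod_draws <- (mu[1] + Z[, 1]) * (mu[2] + Z[, 2])
  target <- quantile(prod_draws, c(0.025, 0.975), names = FALSE)

  labels <- pathmediate:::path_labels(list(solo = "m"), character(), NULL,
                                      outcome = "y", treatment = "trt")
  fake_fit$estimates <- c(fake_fit$estimates, `y~trt` = 0)
  V3 <- matrix(0, 3, 3, dimnames = list(c(names(fake_fit$estimates)),
                                        c(names(fake_fit$estimates))))
  V3[1:2, 1:2] <- V
  class(fake_fit) <- "path_fit"
  ci <- monte_carlo_ci(fake_fit, V3, n_reps = 2e5, seed = 7,
                       domains = list(solo = "m"), via_market = character(),
                       market = NULL, outcome = "y", treatment = "trt")
  row <- ci[ci$effect == "ind_m", ]
  expect_lt(abs(row$conf.low - target[1]), 0.005)
  expect_lt(abs(row$conf.high - target[2]), 0.005)
})

test_that("interval endpoints are stable when repetitions double", {
  ex <- fitted_example()
  ci1 <- monte_carlo_ci(ex$fit, ex$V, n_reps = 10000, seed = 5)
  ci2 <- monte_carlo_ci(ex$fit, ex$V, n_reps = 20000, seed = 5)
  w1 <- ci1$conf.high - ci1$conf.low
  w2 <- ci2$conf.high - ci2$conf.low
  keep <- ci1$effect %in% c("total_indirect", "total", "dom_garden")
  expect_lt(max(abs(w2[keep] - w1[keep]) / w1[keep]), 0.05)
})

test_that("non-PSD covariance is rejected without silent repair", {
  ex <- fitted_example()
  Vbad <- ex$V
  Vbad["crop~trt", "crop~trt"] <- -1
  expect_error(monte_carlo_ci(ex$fit, Vbad, n_reps = 2000),
               "positive semi-definite")
})

test_that("proportions mediated reproduce the published ratios", {
  # printed decomposition values as inputs
  d <- tibble::tibble(
    effect = c("total", "total_indirect", "dom_garden"),
    type = c("summary", "summary", "domain"),
    estimate = c(0.423, 0.433, 0.318))
  out <- summarize_proportions(d)
  expect_equal(round(out$prop_mediated[out$effect == "total_indirect"], 1), 102.4)
  expect_equal(round(out$prop_mediated[out$effect == "dom_garden"], 1), 75.2)
  # zero indirect effect has zero proportion
  d0 <- dplyr::mutate(d, estimate = c(0.4, 0, 0))
  expect_equal(summarize_proportions(d0)$prop_mediated[2], 0)
  # near-zero totals are flagged unstable
  dz <- dplyr::mutate(d, estimate = c(1e-12, 0.1, 0.05))
  expect_warning(oz <- summarize_proportions(dz), "unstable")
  expect_true(all(is.na(oz$prop_mediated)))
})

test_that("all-zero a-paths yield a decomposition equal to the direct effect", {
  cfg <- small_config(paths = list(
    a = as.list(setNames(rep(0, 7), c(pathmediate:::MED_KEYS, "market"))),
    direct = 0.4))
  gen <- generate_dataset(cfg, seed = 53, missingness = FALSE)
  tab <- quiet_assemble(gen$panel, gen$baseline)
  mf <- model_frame_of(tab, covs = slim_covariates)
  fit <- fit_path_model(spec_of(slim_covariates), mf)
  d <- decompose_effects(fit)
  # estimated indirect effects are noise around zero; the identity
  # total = direct + indirect still holds exactly
  expect_equal(d$estimate[d$effect == "total"],
               d$estimate[d$effect == "direct"] +
                 d$estimate[d$effect == "total_indirect"])
})
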