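test_that("DDS is the sum of the ten food-group indicators", {
  expect_identical(compute_dds(c(1, 1, 0, 1, 0, 1, 0, 1, 0, 0)), 5L)
  expect_identical(compute_dds(rep(0, 10)), 0L)
  expect_identical(compute_dds(rep(1, 10)), 10L)
  # unusable recalls give a missing score, not an error
  expect_identical(compute_dds(c(NA, rep(1, 9))), NA_integer_)
  expect_identical(compute_dds(c(2, rep(1, 9))), NA_integer_)
  expect_error(compute_dds(rep(1, 9)), "10")
})

test_that("MDD threshold sits at 5 of 10 food groups", {
  expect_identical(met_mdd(5), 1L)
  expect_identical(met_mdd(4), 0L)
  expect_identical(met_mdd(10), 1L)
  expect_identical(met_mdd(c(0, 5, NA)), c(0L, 1L, NA))
  expect_error(met_mdd(11), "range")
})

test_that("round aggregation averages observed rounds and counts them", {
  expect_equal(aggregate_woman_rounds(c(3, NA, 5, 4)),
               list(mean = 4, n = 3L))
  expect_equal(aggregate_woman_rounds(4), list(mean = 4, n = 1L))
  # MDD met in 2 of 4 observed rounds
  expect_equal(aggregate_woman_rounds(c(1, 0, 1, 0))$mean, 0.5)
  expect_equal(aggregate_woman_rounds(c(NA, NA))$n, 0L)
})

test_that("Ramadan exclusion drops flagged rounds and is a no-op without flags", {
  v <- c(3, 6, 5, 4)
  expect_equal(aggregate_woman_rounds(v, ramadan = c(0, 1, 0, 0),
                                      drop_ramadan = TRUE),
               list(mean = 4, n = 3L))
  expect_equal(aggregate_woman_rounds(v, ramadan = rep(0, 4),
                                      drop_ramadan = TRUE),
               aggregate_woman_rounds(v))
  # never increases the number of contributing rounds
  for (i in 1:20) {
    set.seed(i)
    vals <- ifelse(runif(4) < 0.3, NA, rpois(4, 4))
    flags <- rbinom(4, 1, 0.4)
    if (all(is.na(vals))) next
    n_with <- aggregate_woman_rounds(vals, flags, TRUE)$n
    expect_lte(n_with, aggregate_woman_rounds(vals)$n)
  }
})

test_that("market score sums the three last-month indicators", {
  expect_identical(build_market_score(1, 0, 1), 2L)
  expect_identical(build_market_score(0, 0, 0), 0L)
  expect_identical(build_market_score(1, 1, 1), 3L)
  expect_identical(build_market_score(NA, 1, 1), NA_integer_)
})

test_that("analysis table matches hand-computed averages on the toy fixture", {
  tab <- quiet_assemble(toy_panel(), toy_baseline())
  # w3 has no diet observation and is excluded
  expect_identical(nrow(tab), 2L)
  expect_false("w3" %in% tab$woman_id)
  w1 <- tab[tab$woman_id == "w1", ]
  expect_equal(w1$dds_mean, 5)            # (4 + 6) / 2
  expect_equal(w1$mdd_prop, 0.5)          # met in round 2 only
  expect_equal(w1$n_diet_rounds, 2L)
  expect_equal(w1$crop_richness_mean, 5)  # (4 + 6) / 2
  expect_equal(w1$market_score, 1.5)      # (1+0+1, 1+0+0) -> (2, 1)
  expect_equal(w1$dd_knowledge_score, 3)
  w2 <- tab[tab$woman_id == "w2", ]
  expect_equal(w2$dds_mean, 6)
  expect_equal(w2$crop_richness_mean, 3)  # round-2 crop absent
  # knowledge battery absent but diet present: row retained, score missing
  expect_true(is.na(w2$dd_knowledge_score))
  # baseline covariates joined
  expect_equal(w1$baseline_dds, 3.5)
  # mdd_prop times diet rounds is an integer count
  expect_equal(tab$mdd_prop * tab$n_diet_rounds,
               round(tab$mdd_prop * tab$n_diet_rounds))
})

test_that("Ramadan-flagged rounds are dropped from the diet aggregation", {
  tab <- quiet_assemble(toy_panel(), toy_baseline(), drop_ramadan = TRUE)
  w2 <- tab[tab$woman_id == "w2", ]   # round 2 flagged
  expect_equal(w2$dds_mean, 5)
  expect_equal(w2$n_diet_rounds, 1L)
})

test_that("schema violations are rejected", {
  p <- toy_panel(); b <- toy_baseline()
  expect_error(quiet_assemble(dplyr::bind_rows(p, p[1, ]), b), "duplicate")
  p2 <- p; p2$cluster_id[2] <- "c9"
  expect_error(quiet_assemble(p2, b), "cluster")
  p3 <- p; p3$arm[2] <- 1L
  expect_error(quiet_assemble(p3, b), "arm")
  expect_error(quiet_assemble(p, b[1:2, ]), "missing from baseline")
})

test_that("a woman with five diet rounds triggers an error", {
  p <- toy_panel()[rep(1, 5), ]
  p$round_index <- 1:5
  expect_error(quiet_assemble(p, toy_baseline()), "at most 4")
})

test_that("partially answered knowledge batteries are flagged and missing", {
  p <- toy_panel() |>
    dplyr::select(-dd_knowledge_score) |>
    dplyr::mutate(ddk_01 = c(1, 1, 1, 1, 1, 1), ddk_02 = c(1, 1, NA, NA, 1, 1),
                  ddk_03 = c(0, 0, 1, 1, 1, 1), ddk_04 = c(1, 1, 0, 0, 1, 1))
  msgs <- capture_messages(tab <- assemble_analysis_table(p, toy_baseline()))
  expect_true(any(grepl("partial", msgs)))
  expect_true(is.na(tab$dd_knowledge_score[tab$woman_id == "w2"]))
  expect_equal(tab$dd_knowledge_score[tab$woman_id == "w1"], 3)
})

test_that("aggregation is invariant to round order", {
  p <- toy_panel(); b <- toy_baseline()
  tab1 <- quiet_assemble(p, b)
  tab2 <- quiet_assemble(p[sample(nrow(p)), ], b)
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))
})

test_that("mdd_prop equals brute-force count ratio on random panels", {
  set.seed(42)
  for (rep in 1:5) {
    cfg <- generator_config(n_clusters = 4, allocation = c(2, 2),
                            cluster_size_mean = 6, clamp = TRUE)
    gen <- generate_dataset(cfg, seed = rep)
    tab <- quiet_assemble(gen$panel, gen$baseline)
    panel <- gen$panel
    for (w in tab$woman_id) {
      rows <- panel[panel$woman_id == w, ]
      dds <- rowSums(rows[paste0("fg_", sprintf("%02d", 1:10))])
      obs <- !is.na(dds)
      expect_equal(tab$mdd_prop[tab$woman_id == w],
                   sum(dds[obs] >= 5) / sum(obs))
      expect_equal(tab$n_diet_rounds[tab$woman_id == w], sum(obs))
    }
  }
})

test_that("panel CSVs round-trip with empty cells as absences", {
  gen <- generate_dataset(small_config(), seed = 3)
  tmp <- withr::local_tempdir()
  pp <- file.path(tmp, "panel.csv"); bp <- file.path(tmp, "baseline.csv")
  readr::write_csv(gen$panel, pp, na = "")
  readr::write_csv(gen$baseline, bp, na = "")
  panel2 <- read_panel_csv(pp)
  expect_equal(nrow(panel2), nrow(gen$panel))
  expect_equal(sum(is.na(panel2$dds)), sum(is.na(gen$panel$dds)))
  tab1 <- quiet_assemble(gen$panel, gen$baseline)
  tab2 <- quiet_assemble(panel2, read_baseline_csv(bp))
  expect_equal(tab1$dds_mean, tab2$dds_mean, tolerance = 1e-12)
})
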