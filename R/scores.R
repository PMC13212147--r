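# scores: woman-level outcome and mediator construction from long-format
# panel records.
#
# Panel schema (one row per woman x survey round): identifiers woman_id,
# cluster_id, arm, round_index, round_date, ramadan; diet either as ten
# binary food-group columns fg_01..fg_10 or as a numeric dds column;
# mediator measures either granular (gp_* practice indicators, ddk_*/fgk_*
# knowledge items, market_bought/sold/went) or pre-summed numeric scores.
# Empty CSV cells are absences; scores with any absent item in their battery
# are treated as missing for that round.

FG_COLS  <- sprintf("fg_%02d", 1:10)
GP_COLS  <- sprintf("gp_%02d", 1:17)
DDK_COLS <- sprintf("ddk_%02d", 1:4)
FGK_COLS <- sprintf("fgk_%02d", 1:5)
MKT_COLS <- c("market_bought", "market_sold", "market_went")

#' Dietary diversity score from ten food-group indicators
#'
#' Sums ten binary 24-hour recall indicators into a dietary diversity score
#' (DDS, 0--10). A recall with any absent or non-binary indicator yields a
#' missing score: that round contributes no diet observation.
#'
#' @param food_groups numeric vector of length 10 with values 0/1 (or `NA`).
#' @return integer DDS in 0--10, or `NA_integer_` if the recall is unusable.
#' @examples
#' compute_dds(c(1, 1, 0, 1, 0, 1, 0, 1, 0, 0))  # 5, meets MDD
#' @export
compute_dds <- function(food_groups) {
  if (length(food_groups) != 10L) {
    abort("`food_groups` must have exactly 10 indicators.")
  }
  if (!all(is_binary01(food_groups))) {
    return(NA_integer_)
  }
  as.integer(sum(food_groups))
}

#' Minimum dietary diversity indicator
#'
#' A woman meets minimum dietary diversity (MDD) when she consumed at least
#' 5 of 10 food groups.
#'
#' @param dds dietary diversity score(s), each in 0--10 (`NA` allowed).
#' @return integer vector of 0/1 (or `NA`).
#' @export
met_mdd <- function(dds) {
  bad <- !is.na(dds) & (dds < 0 | dds > 10)
  if (any(bad)) {
    abort(sprintf("DDS out of range 0-10: %s", paste(dds[bad], collapse = ", ")))
  }
  as.integer(dds >= 5)
}

#' Average a per-round measure over a woman's observed rounds
#'
#' Arithmetic mean over non-missing rounds, optionally dropping rounds
#' flagged as falling in Ramadan, returning the number of contributing
#' rounds alongside the mean. A woman with no contributing rounds gets a
#' missing mean and `n = 0` (downstream, she is excluded for that variable).
#'
#' @param values numeric vector, one entry per round (`NA` = absent).
#' @param ramadan optional binary flags parallel to `values`.
#' @param drop_ramadan drop flagged rounds before averaging?
#' @return list with elements `mean` and `n`.
#' @export
aggregate_woman_rounds <- function(values, ramadan = NULL, drop_ramadan = FALSE) {
  if (isTRUE(drop_ramadan) && !is.null(ramadan)) {
    stopifnot(length(ramadan) == length(values))
    values <- values[!(ramadan %in% 1)]
  }
  obs <- values[!is.na(values)]
  if (length(obs) == 0L) {
    return(list(mean = NA_real_, n = 0L))
  }
  list(mean = mean(obs), n = length(obs))
}

#' Market activity sum score
#'
#' Sum of three last-month indicators: bought goods, sold goods, went to
#' market to buy goods (0--3). Any absent indicator makes the round's score
#' missing.
#'
#' @param bought,sold,went binary indicators (vectors recycle elementwise).
#' @return integer score 0--3 or `NA_integer_`.
#' @export
build_market_score <- function(bought, sold, went) {
  ok <- is_binary01(bought) & is_binary01(sold) & is_binary01(went)
  out <- rep(NA_integer_, length(ok))
  out[ok] <- as.integer(bought[ok] + sold[ok] + went[ok])
  out
}

# Battery sum: all items present and binary -> sum; whole battery absent ->
# NA quietly; partially answered -> NA, counted for a single log message.
battery_sum <- function(mat) {
  n_obs <- rowSums(!is.na(mat))
  ok <- n_obs == ncol(mat) & rowSums(mat == 0 | mat == 1, na.rm = TRUE) == ncol(mat)
  out <- rep(NA_real_, nrow(mat))
  out[ok] <- rowSums(mat)[ok]
  attr(out, "n_partial") <- sum(n_obs > 0 & n_obs < ncol(mat))
  out
}

# Resolve a per-round measure from granular columns or a pre-summed column.
round_score <- function(panel, cols, summed_col, partial_log, log_env) {
  if (all(cols %in% names(panel))) {
    s <- battery_sum(as.matrix(panel[cols]))
    if (attr(s, "n_partial") > 0) {
      log_env$partial <- c(log_env$partial,
                           sprintf("%s: %d partially answered batteries treated as missing",
                                   partial_log, attr(s, "n_partial")))
    }
    as.numeric(s)
  } else if (summed_col %in% names(panel)) {
    panel[[summed_col]]
  } else {
    rep(NA_real_, nrow(panel))
  }
}

#' Assemble the woman-level analysis table
#'
#' Collapses long-format panel records into one row per woman: DDS averaged
#' over up to four diet assessment rounds, the proportion of rounds meeting
#' MDD, and round-averaged mediator scores (crop species richness, garden
#' practices, poultry and egg counts, the two knowledge scores, market
#' activity), joined with baseline covariates. Women contributing no diet
#' observation in the analysed rounds are excluded; missing mediator values
#' are retained as `NA` for downstream full-information estimation.
#'
#' @param panel long-format panel tibble/data frame (see package vignette
#'   for the schema).
#' @param baseline baseline covariate table keyed by `woman_id`.
#' @param drop_ramadan exclude rounds flagged `ramadan == 1` from the diet
#'   aggregation (sensitivity analysis).
#' @return tibble, one row per retained woman.
#' @export
assemble_analysis_table <- function(panel, baseline, drop_ramadan = FALSE) {
  panel <- as_tibble(panel)
  baseline <- as_tibble(baseline)
  req <- c("woman_id", "cluster_id", "arm", "round_index")
  miss <- setdiff(req, names(panel))
  if (length(miss)) abort(paste("panel lacks columns:", paste(miss, collapse = ", ")))
  if (!"woman_id" %in% names(baseline)) abort("baseline lacks `woman_id`.")

  if (anyDuplicated(panel[c("woman_id", "round_index")])) {
    abort("duplicate (woman_id, round_index) rows in panel.")
  }
  const_chk <- panel |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(n_cl = dplyr::n_distinct(.data$cluster_id),
                     n_arm = dplyr::n_distinct(.data$arm), .groups = "drop")
  if (any(const_chk$n_cl > 1)) abort("cluster_id varies within a woman.")
  if (any(const_chk$n_arm > 1)) abort("arm varies within a woman.")
  unknown <- setdiff(unique(panel$woman_id), baseline$woman_id)
  if (length(unknown)) {
    abort(sprintf("%d panel women missing from baseline table (e.g. %s).",
                  length(unknown), unknown[[1]]))
  }

  log_env <- new.env(parent = emptyenv())
  log_env$partial <- character()

  # Per-round derived measures
  if (all(FG_COLS %in% names(panel))) {
    dds <- battery_sum(as.matrix(panel[FG_COLS]))
    if (attr(dds, "n_partial") > 0) {
      log_env$partial <- c(log_env$partial,
                           sprintf("diet recall: %d partial recalls treated as missing",
                                   attr(dds, "n_partial")))
    }
    dds <- as.numeric(dds)
  } else if ("dds" %in% names(panel)) {
    dds <- panel$dds
  } else {
    abort("panel needs either fg_01..fg_10 or a `dds` column.")
  }

  if (all(MKT_COLS %in% names(panel))) {
    mkt <- as.numeric(build_market_score(panel$market_bought, panel$market_sold,
                                         panel$market_went))
  } else if ("market_score" %in% names(panel)) {
    mkt <- panel$market_score
  } else {
    mkt <- rep(NA_real_, nrow(panel))
  }

  rounds <- panel |>
    dplyr::mutate(
      .dds = dds,
      # >= 5 of 10 groups; tolerant of out-of-range synthetic draws where the
      # generator's linear-Gaussian default is left unclamped
      .met = ifelse(is.na(dds), NA_real_, as.numeric(dds >= 5)),
      .crop = if ("crop_species_harvested" %in% names(panel))
        as.numeric(.data$crop_species_harvested) else NA_real_,
      .prac = round_score(panel, GP_COLS, "garden_practices_score",
                          "garden practices", log_env),
      .pltry = if ("n_poultry" %in% names(panel)) as.numeric(.data$n_poultry) else NA_real_,
      .egg = if ("n_eggs_week" %in% names(panel)) as.numeric(.data$n_eggs_week) else NA_real_,
      .ddknow = round_score(panel, DDK_COLS, "dd_knowledge_score",
                            "diet diversity knowledge", log_env),
      .fgknow = round_score(panel, FGK_COLS, "fg_knowledge_score",
                            "food group knowledge", log_env),
      .market = mkt,
      .ram = if ("ramadan" %in% names(panel)) .data$ramadan else 0
    )

  diet_counts <- rounds |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(n_diet = sum(!is.na(.data$.dds)), .groups = "drop")
  if (any(diet_counts$n_diet > 4)) {
    abort("a woman has more than 4 diet assessment rounds; the analysis window allows at most 4.")
  }

  if (isTRUE(drop_ramadan)) {
    rounds <- rounds |>
      dplyr::mutate(.dds = ifelse(.data$.ram %in% 1, NA_real_, .data$.dds),
                    .met = ifelse(.data$.ram %in% 1, NA_real_, .data$.met))
  }

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)

  tab <- rounds |>
    dplyr::group_by(.data$woman_id, .data$cluster_id, .data$arm) |>
    dplyr::summarise(
      dds_mean = mean_or_na(.data$.dds),
      mdd_prop = mean_or_na(.data$.met),
      n_diet_rounds = sum(!is.na(.data$.dds)),
      crop_richness_mean = mean_or_na(.data$.crop),
      garden_practices_score = mean_or_na(.data$.prac),
      poultry_mean = mean_or_na(.data$.pltry),
      eggs_mean = mean_or_na(.data$.egg),
      dd_knowledge_score = mean_or_na(.data$.ddknow),
      fg_knowledge_score = mean_or_na(.data$.fgknow),
      market_score = mean_or_na(.data$.market),
      .groups = "drop"
    )

  n_excluded <- sum(tab$n_diet_rounds == 0)
  if (n_excluded > 0) {
    inform(sprintf("Excluding %d women with no diet observation in the analysed rounds.",
                   n_excluded))
    tab <- dplyr::filter(tab, .data$n_diet_rounds > 0)
  }
  for (msg in log_env$partial) inform(msg)

  dplyr::left_join(tab, baseline, by = "woman_id")
}

#' Read a long-format panel CSV
#'
#' Empty cells are absences; all identifier columns are read as character.
#' @param path file path.
#' @return tibble.
#' @export
read_panel_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    woman_id = readr::col_character(),
                    cluster_id = readr::col_character(),
                    round_date = readr::col_date(),
                    .default = readr::col_double()))
}

#' Read a baseline covariate CSV keyed by woman_id
#' @param path file path.
#' @return tibble.
#' @export
read_baseline_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    woman_id = readr::col_character(),
                    .default = readr::col_double()))
}
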