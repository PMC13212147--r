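# Shared product-of-coefficients algebra. The effect decomposition of a
# fitted path model, the generator's implied true effects, and the Monte
# Carlo draws all evaluate this one routine (scalar evaluation is the
# one-row case of the matrix evaluation), so the additivity identities hold
# by construction on every side and parameter-recovery tests compare like
# with like.

# Default mediator domains; order mirrors the trial's reporting (practices
# before crops within the garden domain).
default_domains <- function() {
  list(garden = c("prac", "crop"),
       poultry = c("pltry", "egg"),
       knowledge = c("fgknow", "ddknow"))
}

default_mediator_labels <- function() {
  c(crop = "Garden crop species richness",
    prac = "Garden practices score",
    pltry = "Number of poultry owned",
    egg = "Number of poultry eggs produced",
    fgknow = "Food group knowledge score",
    ddknow = "Diet diversity knowledge score",
    market = "Market score")
}

# Row metadata for the decomposition table (order mirrors the reporting
# layout: individual effects by domain, then domain sums, then summaries).
effect_meta <- function(domains = default_domains(),
                        via_market = unlist(domains, use.names = FALSE),
                        market = "market") {
  labs <- default_mediator_labels()
  lab <- function(m) if (m %in% names(labs)) labs[[m]] else m
  rows <- list()
  add <- function(effect, label, type, domain)
    rows[[length(rows) + 1L]] <<- tibble(effect = effect, label = label,
                                         type = type, domain = domain)
  for (dn in names(domains)) {
    for (m in domains[[dn]])
      add(paste0("ind_", m), sprintf("%s (a_%s x b_%s)", lab(m), m, m),
          "individual", dn)
    for (m in intersect(domains[[dn]], via_market))
      add(paste0("via_", m),
          sprintf("%s via market (a_%s x d_%s x b_market)", lab(m), m, m),
          "individual", dn)
  }
  if (!is.null(market)) {
    add("ind_market_alone", sprintf("%s (a_market x b_market)", lab(market)),
        "individual", "market")
    if (length(via_market))
      add("via_market_sum",
          "Production/knowledge via market (sum a x d x b paths)",
          "individual", "market")
  }
  for (dn in names(domains)) {
    add(paste0("dom_", dn), sprintf("%s domain (sum of a x b)", dn),
        "domain", dn)
    if (length(intersect(domains[[dn]], via_market)))
      add(paste0("dom_", dn, "_mkt"),
          sprintf("%s domain incl. market legs", dn), "domain", dn)
  }
  if (!is.null(market))
    add("dom_market", "Market activity domain (market alone + via-market legs)",
        "domain", "market")
  add("direct", "Direct effect", "summary", NA_character_)
  add("total_indirect", "Total indirect effect", "summary", NA_character_)
  add("total", "Total effect", "summary", NA_character_)
  dplyr::bind_rows(rows)
}

# Matrix evaluation: C has one column per path coefficient (a_<m>, b_<m>,
# d_<m>, a_market, b_market, direct), one row per coefficient vector.
effect_values <- function(C, domains = default_domains(),
                          via_market = unlist(domains, use.names = FALSE),
                          market = "market") {
  meds <- unlist(domains, use.names = FALSE)
  need <- c(paste0("a_", meds), paste0("b_", meds), "direct",
            if (!is.null(market)) c(paste0("a_", market), paste0("b_", market)),
            if (length(via_market)) paste0("d_", via_market))
  absent <- setdiff(need, colnames(C))
  if (length(absent)) {
    abort(paste("missing path coefficient(s):", paste(absent, collapse = ", ")))
  }
  n <- nrow(C)
  ind <- C[, paste0("a_", meds), drop = FALSE] *
    C[, paste0("b_", meds), drop = FALSE]
  colnames(ind) <- meds
  via <- matrix(0, n, 0)
  if (length(via_market)) {
    via <- C[, paste0("a_", via_market), drop = FALSE] *
      C[, paste0("d_", via_market), drop = FALSE] * C[, paste0("b_", market)]
    colnames(via) <- via_market
  }
  out <- list()
  for (dn in names(domains)) {
    for (m in domains[[dn]]) out[[paste0("ind_", m)]] <- ind[, m]
    for (m in intersect(domains[[dn]], via_market))
      out[[paste0("via_", m)]] <- via[, m]
  }
  mkt_alone <- rep(0, n)
  if (!is.null(market)) {
    mkt_alone <- C[, paste0("a_", market)] * C[, paste0("b_", market)]
    out[["ind_market_alone"]] <- mkt_alone
    if (length(via_market)) out[["via_market_sum"]] <- rowSums(via)
  }
  dom_no_mkt <- rep(0, n)
  for (dn in names(domains)) {
    d0 <- rowSums(ind[, domains[[dn]], drop = FALSE])
    out[[paste0("dom_", dn)]] <- d0
    dom_no_mkt <- dom_no_mkt + d0
    vm <- intersect(domains[[dn]], via_market)
    if (length(vm))
      out[[paste0("dom_", dn, "_mkt")]] <- d0 + rowSums(via[, vm, drop = FALSE])
  }
  dom_market <- mkt_alone + rowSums(via)
  if (!is.null(market)) out[["dom_market"]] <- dom_market
  total_indirect <- dom_no_mkt + dom_market
  out[["direct"]] <- C[, "direct"]
  out[["total_indirect"]] <- total_indirect
  out[["total"]] <- C[, "direct"] + total_indirect
  do.call(cbind, out)
}

#' Evaluate the indirect-effect algebra for one coefficient vector
#'
#' Given named path coefficients (`a_<m>`, `b_<m>`, `d_<m>`, `a_market`,
#' `b_market`, `direct`), forms every mediator-specific product, the
#' sequential products through market activity, domain sums with and
#' without their market legs, the market-activity domain, and the direct /
#' total indirect / total effects.
#'
#' @param coefs named numeric vector of path coefficients.
#' @param domains named list grouping non-market mediators into domains.
#' @param via_market mediators with a `d` path into the market mediator
#'   (may be empty).
#' @param market name of the market mediator, or `NULL` if absent.
#' @return tibble with columns `effect`, `label`, `type`, `domain`, `value`.
#' @export
effect_algebra <- function(coefs, domains = default_domains(),
                           via_market = unlist(domains, use.names = FALSE),
                           market = "market") {
  vals <- effect_values(matrix(coefs, 1, dimnames = list(NULL, names(coefs))),
                        domains, via_market, market)
  meta <- effect_meta(domains, via_market, market)
  stopifnot(identical(meta$effect, colnames(vals)))
  dplyr::mutate(meta, value = unname(drop(vals)))
}
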