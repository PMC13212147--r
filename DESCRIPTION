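Package: pathmediate
Title: Multiple-Mediator Path Analysis for Cluster-Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing the effect of a cluster-randomized
    intervention on women's dietary diversity into direct and
    mediator-specific indirect effects. Builds woman-level outcome and
    mediator scores from long-format panel records, estimates a recursive
    linear path model by full-information maximum likelihood with
    cluster-robust sandwich standard errors, computes chi-square, CFI, TLI
    and RMSEA fit indices, and derives product-of-coefficients indirect
    effects with Monte Carlo percentile confidence intervals. Includes a
    synthetic-data generator that emulates a homestead food production
    trial (settlement-level randomization, correlated mediators,
    round-level missingness) with known true path coefficients, so that
    estimation, decomposition and interval coverage can be tested without
    access to the original trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
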