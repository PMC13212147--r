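---
title: "Decomposing intervention effects on women's dietary diversity through multiple mediators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing intervention effects on women's dietary diversity through multiple mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmediate)
```

## The scientific problem

Homestead food production (HFP) programs train rural women in home
gardening, poultry rearing and nutrition, with the aim of improving their
diets. In a cluster-randomized trial of such a program, the interesting
question is not only *whether* women's dietary diversity improved, but
*through which channels*: did diets improve because women harvested more
crop species, adopted better garden practices, kept more poultry, learned
more about nutrition, or engaged more with markets?

`pathmediate` implements the full analysis pipeline for that question:

1. **Score construction** (`assemble_analysis_table()`): collapse
   long-format survey rounds into one row per woman — the dietary
   diversity score (DDS, the number of 10 food groups consumed in the past
   24 h) averaged over up to four assessment rounds, the proportion of
   rounds meeting minimum dietary diversity (MDD, at least 5 of 10
   groups), and round-averaged mediator scores.
2. **Total effects** (`fit_random_intercept()`, `total_effects_table()`):
   random-intercept linear models of each indicator on treatment,
   accounting for settlement-level clustering.
3. **Path model** (`fit_path_model()`): a recursive linear system
   estimated by full-information maximum likelihood (FIML), with
   cluster-robust sandwich standard errors and chi-square/CFI/TLI/RMSEA
   fit indices.
4. **Effect decomposition** (`decompose_effects()`, `monte_carlo_ci()`):
   products of coefficients with Monte Carlo percentile confidence
   intervals.
5. **Synthetic data** (`generate_dataset()`): a generator whose defaults
   emulate the trial's design and published effect sizes, so that every
   stage can be tested for parameter recovery and interval coverage
   without the trial's raw data.

## The structural model

Let $T$ be the settlement-level treatment indicator, $X$ the baseline
covariates, $M_1,\dots,M_6$ the production and knowledge mediators (crop
species richness, garden practices score, poultry owned, eggs produced,
food-group knowledge, diet-diversity knowledge), $M_{mkt}$ the market
activity score and $Y$ the woman's average DDS. The recursive system is

$$M_j = \alpha_j + a_j T + \Gamma_j X + \zeta_j, \qquad j = 1,\dots,6$$
$$M_{mkt} = \alpha_m + a_{mkt} T + \textstyle\sum_j d_j M_j + \Gamma_m X + \zeta_m$$
$$Y = \alpha_y + c' T + \textstyle\sum_j b_j M_j + b_{mkt} M_{mkt} + \Gamma_y X + \zeta_y$$

Residuals covary freely within the garden/poultry block
$\{\zeta_{crop},\zeta_{prac},\zeta_{pltry},\zeta_{egg}\}$ and within the
knowledge pair $\{\zeta_{fgk},\zeta_{ddk}\}$; all other residual
covariances are fixed at zero. Under linearity and no exposure–mediator
interaction, the effect of $T$ on $Y$ decomposes additively:

* mediator-specific indirect effects $a_j b_j$,
* sequential indirect effects through market activity $a_j d_j b_{mkt}$,
* the market-alone effect $a_{mkt} b_{mkt}$,
* the direct effect $c'$,

and the total effect equals the direct effect plus the sum of all
indirect terms — an identity the package asserts on every fit by
cross-computing the total as the reduced-form treatment coefficient of
$(I-B)^{-1}\Gamma$.

Because treatment is randomized, treatment–mediator and
treatment–outcome confounding is handled by design; the mediator–outcome
links additionally assume no unmeasured confounding given the baseline
covariates, which is why the model adjusts every equation for the full
covariate set (religion, wealth-quintile indicators, log land sizes,
baseline crop richness, baseline market score, education, six empowerment
scores and baseline DDS).

## Estimation

**FIML.** Mediator measures are missing for many women (knowledge scores
especially), so the likelihood is evaluated casewise: each row contributes
the marginal normal density of its observed sub-vector under the
model-implied mean and covariance, grouped by missing-data pattern for
speed (the grouped computation is contractually identical to casewise
evaluation and tested against a brute-force per-row oracle). This is valid
under missing-at-random.

**Exogenous variables.** Two modes are provided. The default `"fixed"`
mode conditions on the exogenous variables, which is exact FIML whenever
$T$ and $X$ are complete (the joint likelihood then factorizes). The
`"saturated"` mode models $(T, X)$ as jointly normal with free moments and
is required when covariates themselves have holes. Both modes agree on
complete data (tested to 1e-4). Degrees-of-freedom bookkeeping counts the
exogenous moments as free parameters in either mode, so the default
7-mediator specification has $\chi^2$ df = 8 — the 4×2 cross-block
residual covariances fixed at zero are the only testable restrictions.
Categorical covariates (religion, wealth quintiles) enter as indicator
columns under the normality approximation, mirroring common practice;
this is a modeling caveat, not an endorsement of their normality.

**Parameterization and optimization.** The residual covariance is
parameterized blockwise by its log-Cholesky factor, keeping every
optimizer proposal positive definite with unconstrained quasi-Newton
(BFGS) iterations; the gradient is analytic (chain rule through the
reduced form) and verified against finite differences in the test suite.
Starting values come from equation-wise complete-case least squares —
for this block-recursive system with shared regressors per residual
block, complete-data least squares *is* the maximizer, a property the
tests assert. Convergence requires the per-observation score,
$\max_k |\partial \ell / \partial \theta_k| / n$, to fall below 1e-5;
this scale-aware form is used because the absolute gradient of a
log-likelihood in the thousands cannot meaningfully reach machine-level
thresholds. Non-convergence is reported as an explicit flag with the
best-found parameters, never silently.

**Cluster-robust variance.** The sandwich $A^{-1} B A^{-1}$ uses the
observed information $A$ (finite differences of the analytic gradient)
and cluster-summed scores for $B$; with every row its own cluster it
reduces to the heteroskedasticity-robust estimator (tested against a
brute-force construction), and duplicating every cluster verbatim halves
it (tested). A small-sample factor $G/(G-1)$ is available but off by
default; whether the original analysis used one is not stated in the
source publication.

**Fit indices.** The saturated reference model (free mean and covariance
under the same missing-data patterns) is fitted by EM; the independence
baseline (free means and variances, zero covariances) separates into
per-variable univariate problems with closed-form solutions. CFI and TLI
use the conventional independence baseline — recorded explicitly because
TLI is sensitive to this choice. RMSEA uses $\sqrt{\max(\chi^2 - df, 0) /
(df \cdot n)}$; a saturated model reports $\chi^2 = 0$, CFI = 1,
RMSEA = 0 and an undefined TLI.

**Monte Carlo intervals.** Indirect effects are products of jointly
normal coefficient estimates, hence skewed; percentile intervals from
10,000 draws (default) of the coefficient sub-vector are therefore used
rather than symmetric normal intervals. Draws use only the sub-covariance
of the coefficients entering effect expressions, for numerical stability
and speed. The draws use the cluster-robust covariance by default —
consistent with the clustering-aware estimation — with the naive
inverse-information covariance available by flag, since the source
analysis does not state which was used.

## The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs: 96
settlements randomized 1:1 with ~27 women each (n ≈ 2,600), baseline
covariate distributions matching the trial's baseline table (e.g. baseline
DDS 3.9 ± 1.35, two-thirds Muslim households, five wealth quintiles),
diet-round missingness of 75/12/5/8% for 4/3/2/1 observed rounds, and
per-variable mediator missingness matching the published per-indicator
sample sizes (about 32% for food-group knowledge, 6–11% for the others).
True `a` paths are the published mixed-model effect estimates (5.4 crop
species, 4.8 practices, 1.0 poultry, 1.7 eggs, 0.6 and 0.4 knowledge
points, 0.3 market points); `b` and `d` paths are back-solved so each
product equals the corresponding published indirect-effect component
(e.g. $b_{crop} = 0.226/5.4$), making the implied total indirect effect
0.433 and the total 0.423. All derived defaults live in
`inst/extdata/default_generator_config.yaml`, not in code.

Choices the source does not pin down, decided once here:

* **Cluster effects / ICC.** The trial does not report ICCs. Each
  equation receives an independent settlement-level random intercept with
  sd equal to 0.3 of its residual sd (outcome ICC ≈ 0.08, within the
  0.05–0.10 range typical of behavioral outcomes in rural cluster
  trials). These defaults are configurable and must not be read as
  estimates of the trial's ICCs.
* **Round-level noise.** Per-round DDS is the woman-level structural
  outcome plus N(0, 1.3²) noise, so woman-level means follow the
  structural equation with heteroskedastic noise shrinking in the number
  of observed rounds — mimicking that DDS is measured per recall while
  mediators are aggregated over their own assessment schedule.
* **No truncation by default.** Scores are left linear-Gaussian
  (unclamped), preserving exact linear-model recovery, because the
  estimand is the linear path system. `clamp = TRUE` rounds scores into
  their questionnaire ranges and expands them into granular indicator
  items (food groups, practice items, knowledge items, market
  components), exercising the full score-construction pipeline; the
  induced discretization attenuates coefficients slightly, which is why
  it is not the default for recovery tests.
* **MCAR by default.** The missingness mechanism is missing completely at
  random, trivially satisfying FIML's MAR assumption; the point of the
  generator is to test the estimator under its stated assumptions, not to
  stress-test MAR violations.

What passing tests do and do not show: the generator draws every variable
from the same linear-Gaussian family the model assumes, with integer-like
scores replaced by continuous values. Parameter recovery and interval
coverage under the generator therefore validate the estimator's
implementation, not its robustness to the discreteness, skewness,
truncation and seasonality of real dietary data.

## Scores: decisions on ambiguous inputs

* A 24-h recall with any absent or non-binary food-group indicator
  contributes no diet observation for that round.
* Women with zero diet observations in the analysed window are excluded;
  women missing only mediator measures are retained with missing values
  (handled by FIML downstream).
* Partially answered knowledge batteries: the source does not state how
  they were scored. Decision: a whole-battery absence is quietly missing;
  a partial battery is treated as missing *and* counted in a log message,
  so data problems surface without changing the estimand.
* More than four diet assessments in the input is an error, not a silent
  truncation.
* Knowledge and market measures observed once are carried as
  round-invariant woman-level values.

## Pipeline decisions

* **Stratified analyses** (religion, wealth low = quintiles 1–2 vs high =
  3–5, education low = up to complete primary vs high = at least partial
  secondary) refit the full model independently per stratum with no
  pooling. The stratifying covariate's own columns are dropped from the
  covariate set inside strata (they are constant or near-constant there);
  all other covariates are kept. Strata below a configurable minimum (200
  women by default) are skipped with a warning.
* **Variants**: the Ramadan sensitivity re-aggregates the outcome with
  flagged rounds dropped; the MDD variant swaps the outcome to the
  proportion of rounds meeting MDD in the same machinery; the empowerment
  variant adds the endline empowerment indicators as an extra mediator
  domain with direct paths only (no market legs) and free residual
  correlations among themselves.
* **Mixed-effects totals** use ML rather than REML by default so
  log-likelihoods are comparable across fixed-effect specifications
  (REML by flag); Wald intervals are reported. Baseline adjustment
  follows the published table: outcome models adjust for baseline DDS,
  the crop model for baseline crop richness, the market model for
  baseline market score.
* Reports round effects to 3 decimals and percentages to 1 decimal at
  render time only; stored values stay unrounded, because proportions
  mediated recomputed from rounded inputs can differ by ±0.1%.

## Problem sizes used in the packaged studies

The simulation studies shipped with the package run at a deliberately
reduced scale chosen to exercise the full estimation path many times: the
recovery/coverage study uses 100 replicates of 40 settlements with ~15
women each (≈600 women, ~180 free parameters per fit), with 2,000 Monte
Carlo draws per interval; the moment-matching oracle uses a single
50,000-woman draw; closed-form oracles run at a few hundred rows. At
these sizes the whole suite completes on a single CPU in well under half
an hour while still detecting coefficient bias of a few hundredths of a
food group.

## Known limitations

* Mediator scores are modeled as continuous Gaussian variables; counts
  and bounded scores are approximated, and the MDD-proportion outcome is
  modeled linearly (its implied mean stays within [0, 1] on the default
  generator, which the tests check, but predictions are not structurally
  bounded).
* Natural-effect identification under exposure–mediator interaction is
  out of scope; the decomposition assumes the linear, interaction-free
  system above.
* Latent variables, ordinal/probit links, Bayesian estimation and
  multiple imputation are out of scope (FIML is the stated estimation
  approach).
* The cluster-robust sandwich relies on a moderate number of clusters;
  with few clusters the G/(G−1) flag mitigates but does not remove
  small-sample optimism.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  generator = generator_config(n_clusters = 40, allocation = c(20, 20),
                               cluster_size_mean = 15),
  mc_reps = 2000, seed = 1)
report <- run_primary(cfg)
report$decomposition
autoplot(report$decomposition)
```
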