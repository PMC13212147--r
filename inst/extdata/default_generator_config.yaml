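# Default synthetic-trial configuration.
#
# Cluster structure and covariate distributions emulate the published
# baseline table of the homestead food production trial (96 settlements
# randomized 1:1, ~27 women per settlement). True intervention->mediator
# (a) paths are the published mixed-model effect estimates; mediator->
# outcome (b) and mediator->market (d) paths are back-solved so each
# product a*b (and a*d*b_market) equals the corresponding published
# indirect-effect component, e.g. b_crop = 0.226 / 5.4. Intercepts are set
# so control-arm means sit near the published descriptive means.
n_clusters: 96
allocation: [48, 48]
cluster_size_mean: 27
n_rounds: 4
covariates:
  religion_muslim_prob: 0.68
  wealth_probs: [0.24, 0.22, 0.20, 0.18, 0.16]
  homestead_land_meanlog: 6.05
  homestead_land_sdlog: 0.80
  agri_land_meanlog: 7.90
  agri_land_sdlog: 1.30
  baseline_crop_mean: 6.2
  baseline_crop_sd: 4.5
  baseline_market_mean: 0.5
  baseline_market_sd: 0.7
  education_probs: [0.155, 0.220, 0.230, 0.340, 0.055]
  emp_social_support_mean: 1.7
  emp_social_support_sd: 0.4
  emp_comm_husband_mean: 1.8
  emp_comm_husband_sd: 0.4
  emp_external_comm_mean: 0.2
  emp_external_comm_sd: 0.4
  emp_decision_mean: 0.65
  emp_decision_sd: 0.6
  emp_mobility_prob: 0.31
  emp_income_prob: 0.106
  baseline_dds_mean: 3.9
  baseline_dds_sd: 1.35
paths:
  a: {crop: 5.4, prac: 4.8, pltry: 1.0, egg: 1.7, fgknow: 0.6, ddknow: 0.4, market: 0.3}
  b:
    crop: 0.0418518519     # 0.226 / 5.4
    prac: 0.0191666667     # 0.092 / 4.8
    pltry: 0.0040000000    # 0.004 / 1.0
    egg: 0.0070588235      # 0.012 / 1.7
    fgknow: 0.0250000000   # 0.015 / 0.6
    ddknow: 0.1400000000   # 0.056 / 0.4
    market: 0.0300000000   # 0.009 / 0.3
  d:
    crop: 0.1296296296     #  0.021 / (5.4 * 0.03)
    prac: -0.0625000000    # -0.009 / (4.8 * 0.03)
    pltry: 0.0666666667    #  0.002 / (1.0 * 0.03)
    egg: -0.0196078431     # -0.001 / (1.7 * 0.03)
    fgknow: 0.2777777778   #  0.005 / (0.6 * 0.03)
    ddknow: 0.0833333333   #  0.001 / (0.4 * 0.03)
  direct: -0.010
intercepts:
  crop: 3.2
  prac: 4.6
  pltry: 2.2
  egg: 3.0
  fgknow: 1.65
  ddknow: 2.45
  market: -0.80
  dds: 2.50
gamma:
  crop: {baseline_crop_richness: 0.35}
  market: {baseline_market_score: 0.30}
  fgknow: {education: 0.08}
  ddknow: {education: 0.08}
  dds: {baseline_dds: 0.30}
residual_sd:
  crop: 4.4
  prac: 3.8
  pltry: 2.4
  egg: 3.4
  fgknow: 1.15
  ddknow: 0.95
  market: 0.62
  dds: 1.00
residual_cor:
  garden_poultry:          # order: crop, prac, pltry, egg
    - [1.00, 0.30, 0.15, 0.15]
    - [0.30, 1.00, 0.15, 0.15]
    - [0.15, 0.15, 1.00, 0.40]
    - [0.15, 0.15, 0.40, 1.00]
  knowledge: 0.30          # fgknow ~~ ddknow
cluster_sd_frac: 0.30      # cluster random-effect sd per equation, as a
                           # fraction of that equation's residual sd
                           # (outcome ICC ~ 0.08)
round_sd: 1.3              # per-round diet noise around the woman-level mean
ramadan_round_prob: 0.0
clamp: false
missingness:
  rounds_pattern: {r4: 0.75, r3: 0.12, r2: 0.05, r1: 0.08}
  variable_rates:
    crop: 0.0563
    prac: 0.0854
    pltry: 0.0632
    egg: 0.0632
    fgknow: 0.3243
    ddknow: 0.0953
    market: 0.1053
empowerment:
  include: true
  n_mediators: 6
  a: 0.0
  b: 0.0
  mean: 1.0
  sd: 0.5
  cor: 0.30
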