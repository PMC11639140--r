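# inqolval

Utility valuation of an 8-dimension subset of the Individualized
Neuromuscular Quality of Life questionnaire (INQoL), the patient-reported
outcome most used in non-dystrophic myotonia (NDM). The INQoL is not
preference-based, so its scores cannot feed QALY calculations directly;
`inqolval` implements the full valuation pipeline that turns it into a
utility instrument:

* **Designs** — a verified strength-2 orthogonal array OA(32, 4^8, 2),
  mapped to 32 composite time trade-off (cTTO) valuation states (symptom
  levels 1/3/5/7, impact levels 0/3/5/7) and 32 Street-shifted discrete
  choice experiment (DCE) pairs (levels 1/2/4/7 and 0/1/4/7), in two
  administration blocks of 16.
* **Models** — four candidate disutility families for a state x with levels
  `dim_l`: main effects `α + Σ dim_l·β_{dim,l}` (28 parameters per arm, 44
  hybrid), linear `α + Σ dim·β_dim/7` (8), and cross-attribute level
  effects, `α + Σ_l β_l Σ_dim dim_l β_dim`, with the level curve β_l shared
  across dimensions (CALE) or per presentation group (CALEsep). All
  disutility coefficients are box-constrained to [0, ∞); the CALE level-7
  multiplier is pinned at 1 so β_dim is the level-7 disutility.
* **Estimation** — maximum likelihood with L-BFGS-B multi-start: cTTO
  disutilities y = 1 − value as censored heteroscedastic normal
  (right-censored at 2, i.e. the cTTO floor of −1; σ_j = α_σ + β_σ·μ_j),
  DCE choices as binary logit on `(d(B) − d(A))/θ + α_DCE`, and the hybrid
  model as their exact sum with shared preference parameters and free scale
  θ. Cluster-bootstrap standard errors resample respondents.
* **Selection** — leave-one-state-out (cTTO) and leave-one-pair-out (DCE)
  cross-validation; held-out states are compared to their censored
  (Tobit-type) state means on out-of-sample log-likelihood, RMSE, MAE,
  Pearson R, ICC and Lin's CCC; ranking is by combined out-of-sample
  log-likelihood.
* **Tariff** — the chosen fit becomes a complete dimension × level
  disutility table: unobserved levels (level 6 in every arm) interpolated as
  midpoints of their fitted neighbours, logical inconsistencies repaired by
  pool-adjacent-violators, every cell flagged `fitted` / `interpolated` /
  `monotonized`; `score_responses()` then converts INQoL-8D responses to
  utilities for QALY estimation.

The raw valuation study data are not public, so the package also ships a
synthetic-cohort generator (`make_truth()`, `simulate_tto()`,
`simulate_dce()`) that reproduces the statistical structure the models
assume — heteroscedastic censored TTO values and rescaled-logit choices from
a known preference profile — at the study's sample sizes (200 cTTO / 508 DCE
respondents). All estimation code consumes plain CSV observation tables, so
real data can replace the simulator without code changes.

## Worked example

```r
library(inqolval)

oa         <- build_orthogonal_array()              # bundled, verified OA
tto_design <- map_to_states(oa, "TTO")
dce_pairs  <- build_dce_pairs(map_to_states(oa, "DCE"))

truth <- make_truth("paper-like")                   # generating preferences
tto <- simulate_tto(truth, tto_design, n_respondents = 200, seed = 42)
dce <- simulate_dce(truth, dce_pairs,  n_respondents = 508, seed = 43)

fit <- fit_value_model(model_spec("cale", "hybrid"), tto, dce,
                       tto_design, dce_pairs)
fit
#> Value model: CALE (hybrid scope) + DCE intercept + heteroscedastic sigma
#>   primary parameters: 13
#>   log-likelihood: TTO -1427.641 DCE -5250.750  combined -6678.391 (converged)
#>          WE          LO          DA          LE          PA          TI
#>      0.2433      0.2175      0.2401      0.1921      0.4167      0.2767
#>          AN          DE       lvl.1       lvl.2       lvl.3       lvl.4
#>      0.3069      0.4531      0.1653      0.2723      0.4059      0.3848
#>       lvl.5       lvl.7   alpha_dce       theta alpha_sigma  beta_sigma
#>      0.5731      1.0000      0.1576      0.7799      0.2074      0.1348
```

The dimension coefficients are level-7 disutilities: pain (0.417) and
depression (0.453) carry the largest losses, matching the generating
profile (truth: PA 0.45, DE 0.48). `theta` (0.78) is the rescaling between
the DCE latent scale and the QALY-anchored TTO scale, and `alpha_dce` is the
alternative-position intercept. Note the fitted level curve dips at level 4
(0.3848 < 0.4059): a logical inconsistency the tariff repairs.

```r
tariff <- build_tariff(fit)
round(tariff$entries[, c("1", "3", "5", "6", "7")], 3)
#>        1     3     5     6     7
#> WE 0.040 0.096 0.139 0.191 0.243
#> LO 0.036 0.086 0.125 0.171 0.217
#> DA 0.040 0.095 0.138 0.189 0.240
#> LE 0.032 0.076 0.110 0.151 0.192
#> PA 0.069 0.165 0.239 0.328 0.417
#> TI 0.046 0.109 0.159 0.218 0.277
#> AN 0.051 0.121 0.176 0.241 0.307
#> DE 0.075 0.179 0.260 0.356 0.453

score_responses(tariff, data.frame(WE = 1, LO = 2, DA = 0, LE = 0,
                                   PA = 5, TI = 3, AN = 0, DE = 4))
#>   respondent_id   utility       d_WE       d_LO d_DA d_LE     d_PA      d_TI
#> 1             1 0.3732063 0.04020415 0.05921727    0    0 0.238825 0.1094095
#>   d_AN      d_DE
#> 1    0 0.1791378
```

A respondent with moderate pain (level 5), some depression (level 4) and
mild symptom involvement scores utility 0.37; the `d_*` columns decompose
the 0.63 utility loss by dimension. Level-6 entries (e.g. PA 0.328) are the
exact midpoints of levels 5 and 7, which no survey arm observes.

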