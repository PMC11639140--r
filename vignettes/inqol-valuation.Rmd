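---
title: "Valuing the 8-dimension INQoL: hybrid cTTO-DCE modelling and tariff construction"
author: "inqolval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing the 8-dimension INQoL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

The Individualized Neuromuscular Quality of Life questionnaire (INQoL) is a
patient-reported outcome widely used in neuromuscular disorders such as
non-dystrophic myotonia (NDM), but it is not preference-based: its scores
cannot be converted into the utilities needed for QALY estimation in economic
evaluation. `inqolval` implements a valuation pipeline for a reduced
8-dimension INQoL descriptive system ("INQoL-8D"): it constructs the
orthogonal valuation designs, models composite time trade-off (cTTO) and
discrete choice experiment (DCE) responses jointly by constrained maximum
likelihood, selects among candidate model families by out-of-sample
cross-validation, and converts the chosen fit into a dimension-by-level
disutility tariff that scores questionnaire responses to utilities anchored
at 1 (full health) and 0 (dead).

Because no respondent-level valuation data are publicly available for this
instrument, the package ships a first-class synthetic-cohort generator with
the exact statistical structure the models assume. Everything downstream —
estimation, cross-validation, tariff construction — is data-agnostic and
consumes plain CSV observation tables, so real survey data can be dropped in
with no code changes.

## The descriptive system

Eight INQoL items form the valuation space, chosen for conceptual overlap
with the EQ-5D plus fatigue: four *symptom* dimensions — weakness (WE),
muscle locking (LO), pain (PA), tiredness/fatigue (TI, alias FA) — and four
*impact* dimensions — daily activities (DA), leisure (LE), anxiety (AN),
depression (DE). Each is graded on ordinal levels 0–7. The symptom items are
preceded in the instrument by a yes/no presence question; a "No" maps to
level 0, so level 0 is the common reference ("not at all" / absent) for both
presentation formats and the all-zero state is full health with utility 1 by
construction. A health state is therefore a vector of 8 levels, e.g.
`make_state(c(1, 2, 0, 1, 4, 7, 0, 3))`.

## Valuation designs

Both surveys restrict each dimension to 4 of its 8 levels and share one
32-run orthogonal array of strength 2 on symbols 0–3 (every pair of columns
shows each of the 16 symbol combinations exactly twice, so main effects are
estimated without aliasing):

* cTTO arm: symptom levels {1, 3, 5, 7}, impact levels {0, 3, 5, 7};
* DCE arm: symptom levels {1, 2, 4, 7}, impact levels {0, 1, 4, 7}.

Symbols map to levels in ascending order. The DCE's second alternative is
the Street shift of the first: every symbol incremented by 1 modulo 4 before
level mapping (level 1 in choice A becomes level 2 in choice B; the top
symbol wraps to the group's lowest level), so the two alternatives differ in
all eight dimensions — the efficient pair construction for main-effects
models. Runs 1–16 form block 1 and 17–32 block 2; each respondent completes
one block of 16 states or pairs.

The bundled array is built deterministically from a partial spread of eight
pairwise-disjoint 2-dimensional subspaces of GF(2)^5 (a Rao–Hamming-type
construction, found by a reproducible backtracking search) and verified by
exhaustive counting; any user-supplied 32 x 8 array is accepted through
`build_orthogonal_array(path)` with the same mandatory verification, since
any strength-2 OA yields an equivalent main-effects design. Level 6 appears
in neither arm, which is what later forces tariff interpolation.

The level restriction also fixes the model-complexity arithmetic: a full
main-effects model has one parameter per observed imperfect
(dimension, level) pair — 28 for either arm alone, and 44 for a hybrid fit
on the union of the two level sets.

## Candidate value models

All models predict the *disutility* d(x) = 1 − u(x) of a state x with levels
`dim_l`:

* **Main effects**: d(x) = α + Σ over observed (dim, l) of
  1[dim at level l] · β(dim, l); the most flexible family (28 or 44 primary
  parameters) and the most prone to overfitting and non-monotonicity.
* **Linear**: d(x) = α + Σ level·β(dim)/7; 8 parameters. The division by 7
  makes β(dim) the level-7 disutility, comparable with CALE.
* **CALE** (cross-attribute level effects): d(x) = α + Σ m(level)·β(dim)
  with one level-multiplier curve m(·) shared across all dimensions.
* **CALEsep**: as CALE with separate curves for the symptom and impact
  presentation groups.

Constraints: all disutility coefficients are box-constrained to [0, ∞)
(fitting in disutility space, which enforces a weakly sensible sign but not
within-dimension monotonicity for the main-effects family — inconsistencies
are repaired later in the tariff, not during fitting). The CALE curves are
constrained to [0, 1] with the level-7 multiplier pinned at 1. That pin is
an identification choice: β(dim)·m(l) is invariant to rescaling, so one
multiplier must be fixed, and pinning level 7 makes each dimension
coefficient read directly as the dimension's level-7 disutility.

Two optional intercepts exist. The TTO intercept α (disutility units)
applies to every valued state; because every design state is imperfect it is
not a full-health discontinuity term. The DCE intercept is an
*alternative-position* constant added to the latent-difference predictor —
an intercept common to both alternatives would cancel in the conditional
logit, so a position effect is the only intercept the choice data can
identify.

## Likelihoods

cTTO values live in [−1, 1]; a recorded −1 means the respondent may have
gone lower, so on the disutility scale y = 1 − value these observations are
right-censored at 2. With predicted disutility μ_j and standard deviation
σ_j, uncensored observations contribute normal log-densities
−½{ln(2πσ_j²) + ((y_j − μ_j)/σ_j)²} and censored ones ln Φ((μ_j − 2)/σ_j).
Heteroscedasticity is modelled as σ_j = α_σ + β_σ·μ_j (variation linear in
predicted disutility), with α_σ ≥ 1e-3 and a feasibility penalty whenever
the linear form goes non-positive over the data. The 1e-3 floor is a
numerical choice: the zero-noise likelihood is unbounded as σ → 0, and a
floor far below any real elicitation noise (empirical σ is ~0.2–0.5) makes
the degenerate boundary optimum attainable by the box-constrained optimizer.

DCE choices follow a binary logit on η_j = (d(B_j) − d(A_j))/θ + α_DCE with
the standard Bernoulli log-likelihood Σ y_j ln p_j + (1 − y_j) ln(1 − p_j).
(`dce_loglik(..., strict_form = TRUE)` evaluates, for comparison only, the
variant that drops the (1 − y) factor; it is not a proper likelihood.) In a
DCE-only fit the coefficients live on their own latent scale and θ is not a
parameter; in the hybrid fit the preference parameters are shared with the
TTO component and θ > 0 is the free rescaling between the QALY-anchored TTO
scale and the DCE latent scale. The hybrid objective is the exact sum of the
two components.

## Estimation

`fit_value_model()` maximizes the applicable objective with multi-start
L-BFGS-B under the box constraints: the first start is a deterministic
vector of small positive values, the remaining starts (default 5 in total)
are seeded multiplicative jitters, and the best restart wins. Because every
observation sits on one of 32 design states or pairs, both likelihoods
collapse onto per-state sufficient statistics (uncensored count, mean and
sum of squares, censored count; per-pair choice counts), making each
objective evaluation O(32) regardless of sample size — this is what keeps
leave-one-out cross-validation and bootstrap refitting cheap. Line-search
failures on nearly degenerate surfaces are retried from the stopping point
before a fit is flagged non-converged; non-convergence is reported, never
silently imputed.

Standard errors come from a cluster bootstrap (`bootstrap_se()`):
respondents are the independent sampling unit, resampled with replacement
independently within the TTO and DCE samples, with each replicate refitted
from a warm start at the original estimate. Replicates that fail to
converge are dropped and counted; more than 10% dropped is an error.

## Model selection

`crossvalidate()` implements out-of-sample validation at the level the data
were generated: leave-one-*state*-out for cTTO (32 folds, each refitted on
31 states plus, for hybrid scope, all DCE data) and leave-one-*pair*-out for
DCE (32 folds). Held-out TTO states are compared against their *censored
state mean* — an intercept-only censored-normal (Tobit-type) MLE, which
reduces to the arithmetic mean when no observation is censored — on six
metrics: out-of-sample log-likelihood, RMSE, MAE, Pearson's R, the
intraclass correlation, and Lin's concordance correlation coefficient
CCC = 2·cov/(var₁ + var₂ + (mean₁ − mean₂)²). Held-out DCE pairs are scored
by out-of-sample log-likelihood only, at the observation level, since no
aggregate analogue of the censored mean exists for choices. Two variant
choices are deliberate and recorded in the output: the ICC is the one-way
agreement ICC on the paired (prediction, target) values, and the TTO fold
log-likelihood evaluates the held-out observations under the fold model's
own predicted mean and noise law.

`select_model()` ranks candidates by combined out-of-sample log-likelihood,
breaking ties by RMSE and then parameter count (parsimony).
`default_model_grid("hybrid")` is the default 16-candidate sweep: 4 families
crossed with the 4 on/off combinations of the two intercepts.

## Tariff construction and scoring

`build_tariff()` turns a converged fit into a complete 8 x 8 (dimension by
level) disutility table in three auditable steps, each cell carrying a
provenance flag:

1. *fitted* entries for every level the fit determines (for shared-CALE this
   includes levels observed in either presentation group, since the curve is
   shared);
2. *interpolated* entries for the rest, each the arithmetic midpoint of its
   nearest fitted flanking levels — level 6, observed in no arm, is always
   (level 5 + level 7)/2; single-arm fits have more gaps (e.g. levels 2, 4,
   6 for a TTO-only CALE fit), filled by the same rule;
3. *monotonized* entries where pool-adjacent-violators repair (isotonic
   least squares via `stats::isoreg`) was needed to remove logical
   inconsistencies — a logically worse level with a smaller point estimate.
   Repair averages violating neighbours, never touches an already monotone
   dimension, and can be disabled (`repair = FALSE`). It is applied after
   interpolation, so in a non-monotone region the repaired level-6 cell can
   move off the exact midpoint; the midpoint identity is a property of the
   interpolation stage.

`score_responses()` computes utility = 1 − (α for non-best states, if the
tariff is configured to apply it) − Σ tariff entries. Whether the fitted TTO
intercept belongs in applied scoring is a configuration choice recorded in
the tariff metadata (default: applied, matching the fitted model equation).
Utilities below −1 are reported as computed — flooring is a presentation
choice left to the caller. Tariffs round-trip losslessly through CSV with
their provenance and metadata, and imports re-validate the invariants.

## The synthetic cohort

`make_truth("paper-like")` defines the default generating preference
structure, chosen once to mirror the qualitative pattern reported for this
instrument's UK valuation: substantial disutility on all eight dimensions
with the largest losses on pain and depression; a level curve that is flat
between levels 3 and 4 and drops sharply between levels 5 and 7
(multipliers 0, 0.15, 0.28, 0.40, 0.40, 0.55, —, 1); dimension weights
summing to 2.4 so the worst design states have disutility above 2 and are
censored at the cTTO floor with realistic frequency; noise σ = 0.25 +
0.10·d, in the range typically seen in composite-TTO interviews; DCE scale
θ = 0.8 and a small position intercept 0.15 (the choice data favour an
alternative-position effect, the TTO data favour no intercept). Sample
sizes default to the study's 200 cTTO and 508 DCE respondents, split
50/50 across the two blocks.

`simulate_tto()` draws latent disutility d + ε with ε ~ N(0, σ(d)²), reports
value = 1 − latent, clamps values above 1 (composite TTO cannot express
better-than-full-health; upper censoring is not part of the likelihood) and
records values below −1 as censored −1. `simulate_dce()` draws choices from
the logistic probability of the rescaled latent difference. The generator
deliberately omits features real data would have: respondent-level random
effects (the likelihoods contain no respondent terms), interviewer effects,
the composite-TTO iteration mechanics, value rounding to the usual 0.05
grid (available via the `round_grid` override, off by default), and
question-order effects. Passing tests therefore demonstrate correctness of
the estimation machinery under the models' own assumptions — not robustness
to the misspecifications a live valuation study would add.

## Problem sizes and numerical choices used in the tests

The test-suite simulations run at the study scale of 200 TTO / 508 DCE
respondents: parameter recovery uses 50 replicates with 32 cluster-bootstrap
replicates each (normal-approximation 95% intervals), and the
hybrid-versus-separate out-of-sample comparison uses 20 replicates of the
full 64-fold (hybrid) plus 2 x 32-fold (separate) cross-validation. Fold and
bootstrap refits use a single warm start from the full-data estimate;
full fits use the multi-start default. The optimizer tolerance is L-BFGS-B's
`factr = 1e7` (~1e-9 relative), with bound-pinned solutions expected and
ties between restarts resolved toward converged runs.

## Known limitations

* The real study's raw data are unavailable, so the package reproduces the
  design identities and the methodology, not the published UK coefficient
  values; fitted numbers in the documentation are from synthetic cohorts.
* The published orthogonal design is not identified beyond its catalogue
  source; the bundled OA is one valid strength-2 choice among equivalents.
* Whether the original Street shift wrapped cyclically at the top level is
  not documented beyond the level 1 to 2 example; the cyclic convention is
  implemented.
* The full 45-item INQoL, its subscale scoring, and mapping of full
  questionnaires onto the 8 valuation items are out of scope.
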