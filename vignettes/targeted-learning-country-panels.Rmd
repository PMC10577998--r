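---
title: "Targeted learning for ordinal exposures in country panels: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted learning for ordinal exposures in country panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the estimand and estimator, the tunable parameters and why their defaults
are what they are, what the synthetic generator does and does not
emulate, the numerical choices, and the known limitations.

## Estimand and identification

The unit is a country. The exposure A is ordinal with four levels
(Low < Mid-Low < Mid-High < High), obtained by discretizing a continuous
1-100 index at fixed cut points; the default bins are
`[41, 64], (64, 72], (72, 82.5], (82.5, 91]`, with the closed/half-open
convention taken literally (an index exactly at an interior edge belongs
to the lower interval, and values outside the covered range are errors,
not clamped). The outcome Y is the natural log of an age-standardized
burden rate (DALYs per 100,000); the natural log is essential to the
reporting convention, because a mean log difference b then reads
approximately as a 100·b percent difference (the exact factor
exp(b) − 1 is always reported alongside).

The targets are the counterfactual means psi_k = E[Y(k)] and their
contrasts versus the Low reference. Identification assumes (i) the
measured covariates close the confounding paths — four confounders
(socio-demographic index, unemployment rate, top-10% income share,
urbanization), the log pre-exposure outcome, and three precision
covariates (child-sexual-abuse exposure, data-quality rating, healthcare
access and quality) that predict only the outcome; (ii) positivity,
verified descriptively rather than assumed; and (iii) one cross-sectional
draw per country (no temporal modelling). Rows with missing required
fields are rejected with an itemized report — with ~90 complete-case
countries, imputation would add model risk for no benefit. A data-quality
threshold (default 3 of 5 stars) is applied at ingest.

## Estimator

TMLE for a bounded continuous outcome:

1. The outcome regression is one pooled stacking-ensemble fit of Y on the
   covariates plus K−1 exposure dummies; the counterfactual matrix Q is
   obtained by setting the dummies to each level in turn. Pooling borrows
   strength across levels — at n = 87, four stratified fits would be far
   noisier.
2. The exposure mechanism g is the same ensemble in multinomial mode.
   Probabilities are floored at 1e-6 and renormalized; positivity is
   otherwise handled by trimming plus diagnostics, not by the floor.
3. Stabilized ratios s_ik = 1(A_i = k) p_k / g_ik are trimmed at a
   percentile of the pooled positive ratios (default 99.9; 99 and 97.5
   as sensitivity settings). Pooled trimming is the default because the
   published rule names a single percentile; per-level trimming is a
   config switch (`per_level = TRUE`), since the original's pooling is
   not stated.
4. Targeting: Y and Q are min-max scaled to [0, 1] (Q bounded into
   [0.005, 0.995] to keep the logit finite); per level, an intercept-only
   logistic fluctuation with offset logit(Q) is fit by weighted maximum
   likelihood with the trimmed ratios as weights; psi_k is the mean
   updated prediction on the original scale. Because the weighted score
   is solved exactly, each influence-curve column has mean zero by
   construction (checked to 1e-6 in the tests).
5. Inference: IC-based Wald intervals with normal quantiles. The IC uses
   the trimmed, de-stabilized ratio (trimmed s divided by p_k), so
   stabilization affects what gets trimmed but not the estimand. The
   contrast SE comes from SD(IC_k − IC_0)/sqrt(n). Whether the original
   analysis used normal or t references is unstated; at n = 87 the two
   differ by under 2% of the interval width, and normal quantiles are the
   TMLE-standard choice.

The saturated marginal structural model — OLS of the targeted
predictions, stacked over levels, on level dummies — is retained as an
exact algebraic cross-check: with a saturated design its coefficients
equal the psi differences to machine precision, and the package tests
this identity on every run at 1e-10.

## The stacking ensemble

The library is the published five: main-effects linear model, forward
stepwise regression by AIC (the reference says only "step forward"), L1
regression, MARS, random forest. Printed hyperparameters are the
defaults: MARS max interaction degree 2; random forest 500 trees, 2
candidate variables per split, minimum node size 5 (regression) and
1 (classification). Additional implementation choices the source leaves
open:

- **Folds**: 10 by default (the convention of the reference ensemble
  framework), stratified by exposure level in multinomial mode. A class
  absent from any training fold is an error that suggests fewer folds.
- **Meta-learner**: out-of-fold predictions are stacked by minimizing
  cross-validated risk over the simplex — squared error for regression
  (non-negative least squares warm start, then projected gradient to the
  simplex optimum), multinomial log-loss for the exposure mechanism
  (projected gradient with backtracking, 1e-10 tolerance, capped
  iterations, and a final guard that no single-learner vertex beats the
  solution). The simplex-optimal refinement guarantees the returned
  weights never do worse than the best single learner — a property the
  plain normalize-after-NNLS convention does not give.
- **Multiclass adaptation**: linear/stepwise/L1 learners become their
  multinomial-logistic counterparts; MARS scores classes one-vs-rest on
  indicators with probability normalization; the forest is a probability
  forest. An `ordered_logit` learner (proportional odds) is available
  because the exposure is ordinal, and an `intercept_only` learner
  supports misspecification experiments.
- **L1 penalty**: chosen by inner cross-validation on the training fold,
  at the penalized-regression package's own conventions (10 folds, a
  100-value lambda path). A sparser grid is noticeably worse: penalty
  selection noise becomes estimator variance that the influence curve
  cannot see, and interval coverage degrades.
- **MARS**: no MARS implementation ships with this stack's R
  distribution, so the package implements it directly — forward
  selection of reflected hinge pairs (candidate knots at nine interior
  deciles per variable, a variable at most once per term), degree cap 2,
  numerically collinear additions dropped via rank-revealing QR, and
  backward pruning by GCV with the usual cost-complexity penalty of 3
  effective parameters per knot. Candidate scoring is vectorized
  (block-projected against the current basis), so a fit at n = 5000 takes
  seconds.
- **Failure policy**: a learner that errors on any fold or the full-data
  refit is dropped with a warning and the simplex weights renormalize;
  the ensemble only fails when every learner fails.

Performance is reported only from out-of-fold predictions:
cross-validated R-squared for the regression and macro-averaged
one-vs-rest AUC (rank-based, tie-corrected) for the exposure mechanism.

## The synthetic generator

`simulate_country_panel()` emulates the study schema with known truth:
confounders drawn on the real variables' supports (beta-distributed
indices on [0, 1], gamma-distributed unemployment, a baseline log burden
correlated with development); a latent globalization score that is a
linear function of the confounders plus logistic noise, cut at sample
quantiles (default probabilities 23/87, 46/87, 65/87, which reproduce the
study's 23/23/19/22 split exactly at n = 87); and a log outcome that is
intercept + additive level effect + linear confounder terms + Gaussian
noise. Because the level effects are additive, the true contrasts equal
the configured `level_effects` exactly; the default (0.13, 0.14, 0.31)
mirrors the published point estimates so that desk runs resemble the
study — a simulation convention, not a reproduction claim. The logistic
latent noise makes the true exposure mechanism an ordered-logit model,
which is exactly what the `ordered_logit` learner fits — that is what
"g correctly specified" means in the double-robustness experiments.

Residual noise on the log scale defaults to SD 0.25, i.e. roughly
three-quarters of outcome variance explained by the covariates —
comparable to the strong covariate signal in real country-level burden
data, where the pre-exposure outcome alone is highly predictive.

Scenarios: `baseline`; `zero_effect` (level effects zeroed);
`strong_confounding` (outcome-side confounder effects roughly doubled and
exposure-side effects scaled by 1.4 — calibrated once so the naive
difference-in-means is biased by more than 0.1 log-units while every
country retains a workable probability of each level, maximum stabilized
weights around 40); `nonlinear_Q` (smooth nonlinearities added to the
outcome surface); `misspecified_g` (nonlinearities added to the latent
score). All scenarios keep the level effects additive, so
`true_contrasts_oracle()` — a Monte-Carlo average of the noiseless mean
difference over fresh covariate draws — returns the configured effects
up to numerical error and serves as the recovery target everywhere.

What the generator does **not** emulate: the GBD estimation uncertainty
attached to real DALY values, spatial/cultural correlation between
countries, measurement error in the composite indices, and the real
covariate joint distribution (only supports and rough locations are
matched). Passing tests therefore demonstrate that the estimator and its
inference behave correctly under a faithful schema with known truth —
not that the published real-data estimates are correct.

## Problem sizes used by the tests and acceptance script

Chosen as the package's own trade-off between Monte-Carlo error and desk
runtime: one large-sample recovery fit at n = 5000 with the full
five-learner library (5 CV folds at that n; the package default stays
10); 95% CI coverage over 300 replicates at n = 500 with the linear + L1
library; double robustness as the mean bias over 80 replicates
(misspecified outcome regression, correct ordered-logit mechanism) and
20 replicates (correct regression, marginal-only mechanism) at n = 5000
— single-draw "bias" in the first direction has Monte-Carlo SD near
0.05, so only a replicate average is meaningful, and the ratios are left
untrimmed there because trimming deliberately attenuates exactly the
units that carry the IPW-side information (with 99.9th-percentile
trimming the High contrast picks up a systematic attenuation near 0.03
under strong confounding — the trade-off trimming is designed to make); and a 60-replicate
null-scenario loop at n = 500 for type-I behavior and the
TMLE-versus-IPW efficiency comparison.

## Known limitations

- **Small-sample inference**: IC-based Wald intervals ignore nuisance
  estimation noise (the package deliberately does not cross-fit — at
  n = 87 sample splitting would be crippling). At n = 500 the High-vs-Low
  interval is close to nominal; at n = 87 intervals are anti-conservative
  and p-values should be read qualitatively.
- **Inference under penalized exposure mechanisms**: when the stack's
  exposure-mechanism fit leans on a penalized learner, the propensities
  shrink toward the marginals; the point estimate remains consistent
  through the outcome regression, but the efficient-influence-curve
  variance then understates the true sampling variance, and the measured
  coverage in the acceptance suite's n = 500 experiment falls slightly
  short of its nominal band. The coverage experiment reports the
  measured value rather than hiding the shortfall.
- **Family-wise significance**: three contrasts each tested at 5% imply
  a family-wise false-positive rate near 13% even under perfect
  calibration; no multiplicity correction is applied (matching the
  reporting convention of the analyses this mirrors), and none is added
  silently.
- **Trimming** trades positivity robustness for a small attenuation
  bias; the sensitivity grid (99.9/99/97.5) makes that trade visible
  rather than hiding it.
- **Ecological design**: the estimand is a country-level association
  under the stated adjustment set; nothing here licenses individual-level
  or mechanistic causal claims.
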