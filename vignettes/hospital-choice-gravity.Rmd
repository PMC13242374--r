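---
title: "Gravity models of hospital choice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gravity models of hospital choice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospflow)
```

## The model and its assumptions

The unit of analysis is the origin–destination flow `T_ij`: the number of
cohort patients living in ZIP code `i` who underwent the index operation
at hospital `j`. The gravity specification assumes flows are
multiplicative in an origin factor, a destination factor, and distance
decay:

```
log T_ij = alpha_i + delta_j + beta_d * log d_ij + e_ij
```

- `d_ij` — geodesic miles between ZIP centroids (haversine on a sphere of
  radius 3958.7613 miles), floored at `floor_miles` (default 0.5) before
  the log. The floor exists because `log 0` is undefined for same-ZIP
  pairs and intra-ZIP travel is not actually zero; centroid coordinates
  carry more error than the floor introduces.
- `alpha_i` absorbs ZIP population, case incidence and anything else
  origin-specific; `delta_j` absorbs everything that makes a hospital
  attractive.
- Only positive flows enter estimation: the log-linear model is undefined
  on zeros, so absent (i, j) pairs are absent from the flow table.
  Prediction, by contrast, scores *every* in-state patient–hospital pair.

Model 1 stops at `beta_d`. Models 2 and 3 explain the destination effect:
model 2 by log hospital volume `V_j` (cohort case count), model 3 by log
volume plus four binary characteristics (medical-school affiliation,
rural location, cancer-program accreditation, centralized health
system). Coefficients on volume are descriptive elasticities, not causal
effects: `V_j` is computed from the same cohort whose choices it
explains, and the within transformation deliberately minimizes
between-hospital variation.

## Why estimation is two-stage

Double-demeaning — alternately subtracting origin-group and
destination-group means until every group mean is below `tol` — removes
`alpha_i` and `delta_j` from both `log T` and `log d` and identifies
`beta_d` from pair-level variation. But the same transformation
*annihilates* any destination-invariant regressor: `log V_j` and the four
characteristics are constant within a destination, so they cannot be
estimated in the within regression. The package therefore:

1. estimates `beta_d` by OLS on the double-demeaned variables (this
   equals explicit dummy-variable least squares; the test suite checks
   agreement to `1e-6` on random 20×10 panels with ~60% of cells
   present);
2. recovers `delta_j` by additively decomposing
   `log T_ij − beta_d log d_ij` into origin plus destination means
   (alternating projections, origin first so the overall level lands in
   the origin effects — harmless, since stage 2 has an intercept);
3. regresses `delta_j` on the destination covariates by least squares
   weighted by each destination's number of positive-flow cells, since
   destinations observed in more cells have better-estimated effects.

This fixed-effect-decomposition route is standard practice when
group-invariant covariates are of interest in a two-way within model; it
keeps the distance elasticity fully robust to unobserved origin and
destination heterogeneity while still producing interpretable volume and
characteristic coefficients.

Convergence controls default to `tol = 1e-10`, `max_iter = 10000`: on a
complete balanced grid one pass suffices; on unbalanced panels
convergence is geometric provided the origin–destination incidence graph
is connected, and non-convergence (a disconnected or pathological panel)
is an error, never a silent result. A regressor that is constant within
the estimation sample is flagged as degenerate — with few hospitals per
stratum a rare binary characteristic (e.g. rural) is often constant, and
model 3 then refuses to fit rather than return an arbitrary coefficient.

## Prediction

For patient `k` in ZIP `i`, every hospital `j` in the patient's state is
scored with the destination-varying part of the linear predictor
(`beta_d log d_ij`, plus `beta_v log V_j` for model 2, plus the
characteristic effects for model 3). Origin effects are constant within a
patient and cannot affect ranks. Scores become probabilities by softmax;
any strictly monotone mapping would give the same accuracy, softmax is
chosen because it yields a proper probability vector over the candidate
set. Ties — exactly equal scores, which arise e.g. for equidistant
hospitals under model 1 — are broken by a seeded random permutation
(default seed 20160101, always recorded); each patient draws from a
stream derived from the master seed and the patient's position, so
changing `k` or scoring a subset never perturbs another patient's
ranking.

Two design points were genuinely open and are resolved as configuration
with defaults:

- **Residual destination effects are off by default.** If prediction used
  the full recovered `delta_j`, models 2 and 3 would produce identical
  rankings (both reduce to `beta_d log d + delta_j`), and the three
  models could not disagree. Using only each model's named regressors
  preserves three genuinely different predictors;
  `use_residual_effects = TRUE` exposes the alternative.
- **Candidate sets are in-state.** The flow data cannot contain
  cross-state choices (out-of-state patients are excluded), so offering
  out-of-state candidates would only add unfalsifiable predictions.

## Evaluation

Top-k accuracy is the share of patients whose observed hospital is among
the k highest-ranked predictions, reported for k = 1, 2, 3, overall, per
state, and among Medicare patients (whose insurance is presumed accepted
everywhere, removing one unmodeled constraint). Sufficiency classes
partition patients by which models were correct at a fixed k; because
"model 1 sufficient" can be read as a margin (model 1 correct, full stop)
or as an exclusive class, both are reported and labelled distinctly.
Travel bias is `mean(observed distance − distance to top predicted
hospital)`; the sign convention makes "the model underestimates travel"
a positive number. Subgroup tables use Welch t-tests for continuous
variables and Pearson chi-squared without continuity correction for
categoricals, matching the usual mean ± SD / n (%) table style; expected
cell counts below 1 attach a warning flag to the affected rows. No
multiplicity adjustment is applied — the tables are descriptive.

## The synthetic market

The generator emulates the structure the analysis assumes, with every
stage deterministic given the master seed:

- **Geography**: `n_zips` centroids uniform on a mid-latitude square of
  side `grid_extent` degrees (default 6°, about 360 miles — two state
  blocks each roughly the travel scale of a large US state), partitioned
  into contiguous equal-count longitude blocks (states). ZIP populations
  are Dirichlet with concentration 0.5, giving the heavy-tailed mix of a
  few dense and many sparse ZIPs that real ZIP tabulations show.
- **Hospitals**: allocated to states by population, placed in
  population-weighted ZIPs, with Bernoulli characteristics at
  prevalences (0.5, 0.15, 0.6, 0.4). Latent log attractiveness is
  `N(0, 1.25²)` plus the characteristic utility contributions
  (0.4, −0.3, 0.3, 0.2); the 1.25 dispersion spreads realized cohort
  volumes over more than an order of magnitude, matching the very wide
  volume IQRs real complex-surgery cohorts show. Characteristics act
  through attractiveness, so they genuinely shift choice.
- **Choices**: in-state multinomial logit with log-odds
  `theta_distance log d + theta_volume log A` (the Gumbel random-utility
  model). Defaults `theta_distance = −1.5`, `theta_volume = 1`,
  `n_patients = 20000` over 100 ZIPs and 15 hospitals. In-hospital death
  is a logistic draw declining with the chosen hospital's attractiveness
  (baseline 2.5%), so volume–outcome associations exist.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: insurance and referral networks,
health-system loyalty, drive-time versus geodesic distance, real ZIP
polygon geography, out-of-state destination hospitals, and any
patient-level heterogeneity in preferences (demographics are drawn
independently of choice). Estimator correctness and pipeline bookkeeping
transfer; empirical accuracy levels do not.

Note one deliberate fidelity: choices are generated from *latent*
attractiveness `A_j`, but estimation uses *realized* volume `V_j`
aggregated from the cohort — reproducing the endogeneity of cohort-based
volume rather than idealizing it away.

## Known numerical behavior and limitations

- **Attenuation of the distance elasticity.** `E[log T | T > 0]` is a
  concave, truncated transform of the Poisson-like cell counts, so on
  markets with many small positive cells the stage-1 elasticity is biased
  toward zero even though the estimator is exact for its estimand (it
  matches dummy-variable OLS to machine precision). On the default
  market the recovery harness measures a mean estimate of roughly −1.32
  for a true −1.5; `scripts/acceptance.R` recomputes this on any seed.
  Poisson pseudo-maximum-likelihood would remove this bias but is outside
  this package's scope, which is the log-linear within estimator.
- **The nearest-choice limit is singular.** As
  `theta_distance → −∞` every patient chooses the nearest hospital, but
  each ZIP then flows to exactly one hospital and the flow table loses
  the within-ZIP variation that identifies `beta_d`; any finite
  coefficient extreme enough to make choice near-deterministic leaves a
  few near-midline ZIPs splitting between near-equidistant hospitals.
  The generator tests the limit property directly against the generator
  (at −500, 99.4% of patients choose the nearest hospital); fitting in
  that regime may legitimately fail with the no-within-variation error.
- **Volume coefficients are not causal**, both in the data-generating
  sense above and because the within transformation is designed to
  minimize between-hospital variation.

## Problem sizes used in the test suite

Unit and property tests run on markets of 20–40 ZIPs, 6–20 hospitals and
3,000–30,000 patients; the end-to-end recovery battery uses the default
20,000-patient market over 20 seeds; conservation properties run 1,000
randomized small cohorts. These sizes were chosen so the full suite
exercises every code path in about a minute while keeping Monte Carlo
noise well inside the asserted tolerances.
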