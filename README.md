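# hospflow

Gravity models of patient flows to hospitals for complex surgery.

## The problem

For operations like pancreatoduodenectomy, where a patient has surgery is
a policy-relevant choice: outcomes are better at high-volume centers, but
centralization pushes travel burden onto patients. Simulation studies of
centralization often assume patients go to the nearest qualifying
hospital. This package asks how well that assumption — and richer
spatial-interaction models — actually predict observed hospital choice,
and what the prediction errors imply about who is mismodeled and how much
travel is underestimated.

`hospflow` is for health-services researchers who have (or can simulate)
patient-level admission data with home ZIP codes and want a tested,
reproducible pipeline from raw tables to accuracy and travel-bias
reports.

## The model

Let `T_ij` be the number of patients from ZIP code `i` treated at
hospital `j`. The gravity model is log-linear in distance and hospital
"mass":

```
log T_ij = alpha_i + delta_j + beta_d * log d_ij + e_ij
```

where `d_ij` is the geodesic distance in miles between the ZIP centroid
and the hospital's ZIP centroid (floored at 0.5 miles), `alpha_i` are
origin fixed effects (ZIP population, case rates) and `delta_j` are
destination fixed effects (everything that makes a hospital attractive).
Three specifications are compared:

1. **Model 1 — distance alone**: `beta_d * log d_ij`.
2. **Model 2 — distance + volume**: the destination effect is regressed
   on log hospital volume `V_j`, giving an elasticity `beta_v`.
3. **Model 3 — distance + volume + hospital characteristics**: adds four
   binary covariates (medical-school affiliation, rural location,
   Commission-on-Cancer accreditation, centralized health system).

Estimation is two-stage. Stage 1 removes `alpha_i` and `delta_j` by an
iterated **double-demeaning** (two-way within) transformation of the
positive flows and estimates `beta_d`; this matches explicit
dummy-variable least squares to machine precision (a property the test
suite verifies on random unbalanced panels). Stage 2 recovers `delta_j`
and regresses it on the destination-invariant regressors — which cannot
survive destination demeaning — by weighted least squares.

Fitted models score every in-state patient×hospital pair, convert scores
to softmax probabilities, and rank with seeded random tie-breaking. The
evaluation battery reports top-1/2/3 accuracy (overall, per state, and
among Medicare patients), per-patient model-sufficiency classes, subgroup
comparison tables (Welch t and Pearson chi-squared), and travel-distance
bias: the mean of observed minus predicted travel, positive when the
model underestimates how far patients really go.

Because the motivating inpatient data are restricted, the package ships a
seeded synthetic market generator (`simulate_market()`): ZIP centroids
with heavy-tailed populations, hospitals with latent attractiveness, and
choices from an in-state multinomial logit with known distance and
attractiveness coefficients — so every estimator claim is testable
against ground truth.

## Worked example

```r
library(hospflow)
cfg <- synthetic_config(n_zips = 40, n_hospitals = 10, n_patients = 5000,
                        seed = 42)
rec <- run_end_to_end_recovery(cfg, specs = 1:2)
rec$estimates
#>        parameter truth  estimate      error
#> 1 theta_distance  -1.5 -1.229097 0.27090285
#> 2   theta_volume   1.0  1.018915 0.01891534
rec$accuracy[rec$accuracy$stratum == "overall", 1:5]
#>         stratum k n_correct n_total accuracy
#> spec1.1 overall 1      2498    5000   0.4996
#> spec1.5 overall 2      3752    5000   0.7504
#> spec1.9 overall 3      4289    5000   0.8578
#> spec2.1 overall 1      3858    5000   0.7716
#> spec2.5 overall 2      4478    5000   0.8956
#> spec2.9 overall 3      4808    5000   0.9616
rec$fits$overall$spec2
#> Gravity model spec 2: 121 flows, 35 origins, 10 destinations
#>   distance elasticity   -1.2291 (se 0.0850)
#>   log-volume elasticity  1.0189 (se 0.1683)
```

The true distance coefficient is −1.5; the log-linear estimate on
positive flows is attenuated toward zero (−1.23 here) because small cell
counts enter through `log T_ij` — see the methods vignette. The volume
elasticity is recovered almost exactly, and adding volume lifts top-1
accuracy from 50.0% to 77.2% in this market: proximity by itself is a
poor guide to where patients actually end up.

For file-based runs, `run_analysis()` takes paths to patient, hospital
and centroid tables and writes the exclusion log, fits, predictions,
accuracy/travel-bias reports, subgroup tables and a manifest to an output
directory.

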