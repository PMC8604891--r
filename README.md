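# planqm

Plan quality metric (PQM) evaluation for head-and-neck MR-linac planning
cohorts.

## The problem

Multicenter treatment-planning comparisons ("planning challenges") score each
submitted radiotherapy plan against a common, tiered scheme of dose–volume
histogram (DVH) goals: target coverage and hot spots for the three nested
planning target volumes of a simultaneous-integrated-boost head-and-neck
prescription (69.96 / 59.4 / 54 Gy in 33 fractions), sparing of ten organs at
risk (OARs), and conformity of the elective dose. Each of the 16 submetrics
earns points by tier — *unacceptable, marginal, acceptable, good, ideal* —
or pass/fail for binary OAR criteria; the sum is the PQM, out of 150 points
(78 for the 6 PTV metrics + 72 for the 10 OAR metrics). A plan is flagged
unacceptable if its delivery time exceeds 20 minutes (inclusive limit) or a
hard dose constraint is violated; gating changes the flag, never the score.

The raw plans behind such challenges are rarely public. `planqm` therefore
rebuilds the whole evaluation pipeline on *synthetic* cohorts: a voxel
phantom with the right topology, a calibrated generator that samples per-plan
metric targets and delivery metadata from published summary statistics
(truncated-normal marginals + a Gaussian copula for the published rank
correlations), and a dose painter that turns each sampled profile into an
actual 3D dose grid whose *measured* DVH metrics reproduce the intended
values. Everything downstream — DVH engine, tiered scoring, cohort
statistics — operates on those measurable volumes, exactly as it would on
real exported dose distributions.

Core quantities:

* **D_x% / D_xcc** — minimum dose to the hottest x % (or x cm³) of a
  structure, from the cumulative DVH by full-voxel counting (inverse queries
  accurate to half a bin width; default bin 0.01 Gy).
* **V_xGy** — percentage of a structure receiving at least x Gy.
* **Conformation number** — CN = (TVRI/TV) · (TVRI/VRI): coverage of the
  target by the reference isodose times the selectivity of that isodose.
* **Cohort statistics** — relative deviations from the ideal-score
  thresholds with exact Wilcoxon signed-rank tests (full 2ⁿ sign
  enumeration for n ≤ 20), the Spearman correlation matrix with strength
  classes (|ρ| > 0.7 strong, > 0.5 moderate), and OLS PTV-vs-OAR trade-off
  fits with 95 % confidence bands.

## Worked example

```r
library(planqm)

phantom  <- build_phantom()                       # 80^3 voxel phantom, 2 mm
profiles <- sample_cohort_profiles(14, load_calibration(), seed = 42)
scheme   <- load_scheme()                         # 16 metrics, 78 + 72 = 150

dose <- paint_dose(phantom, profiles[[1]])
vals <- evaluate_plan_metrics(dose, phantom, scheme)
round(vals[c("ptv1_d95", "ptv3_cn", "parotid_right_dmean")], 3)
#>            ptv1_d95             ptv3_cn parotid_right_dmean
#>              68.235               0.700              25.463

card <- score_plan(vals, c(list(plan_id = "plan_001"), profiles[[1]]$delivery),
                   scheme)
card
#> <pqm_scorecard> plan_001: PQM 139.75 / 150 (PTV 71.50 / 78, OAR 68.25 / 72) - UNACCEPTABLE
#>   gate failures:
#>    - delivery_time: observed 20.15 vs bound 20
```

`ptv1_d95` is the minimum dose (Gy) to the best-covered 95 % of the boost
volume; `ptv3_cn` the conformation number of the 54 Gy isodose around the
elective volume; the scorecard shows the tiered points earned and the
acceptability flag after the 20-minute and hard-constraint gates.

A full run — generate, evaluate, score, cohort statistics, with NIfTI
volumes, CSVs and a hashed manifest — is one call (or
`inst/cli/planqm run --out dir --n 14 --seed 42` from a shell):

```r
run <- run_challenge("challenge_out", n_plans = 14, seed = 42)
run
#> <planqm_run> 14 plans -> challenge_out
#>   PQM median 138.1 [128.5-143.0]; 11/14 acceptable
```

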