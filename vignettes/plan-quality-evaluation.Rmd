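---
title: "Synthetic plan-quality evaluation: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic plan-quality evaluation: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planqm)
```

`planqm` evaluates cohorts of head-and-neck treatment plans with a tiered
150-point plan quality metric (PQM). Because the individual plans behind
multicenter planning comparisons are typically not public, the package
couples the evaluation machinery (DVH engine, scoring, statistics) to a
synthetic-cohort generator calibrated to published summary statistics. This
vignette explains the models, the calibration, the numerical conventions and
the limits of what the synthetic route can show.

## The phantom

The phantom is a configurable set of geometric primitives rasterised onto a
regular voxel grid; the shipped default is 80×80×80 voxels at 2 mm
(a 16 cm cube). Three concentric-ellipsoid planning target volumes realise
the simultaneous-integrated-boost topology (PTV1 ⊂ PTV2 ⊂ PTV3; boost,
intermediate and elective prescriptions of 69.96, 59.4 and 54 Gy in 33
fractions), with ten organs at risk placed with clinically sensible
topology: laterally paired parotids, a posterior midline spinal canal,
superior brainstem and brain, inferior brachial plexus and esophagus, and
anterior glottis, mandible and oral cavity. Default volumes span 1.5 cc
(glottis) to 263 cc (PTV3).

The geometry makes the scored trade-offs *geometrically real*: the elective
isodose must conform around a target whose neighbours (mandible hot spots,
parotid mean doses) are themselves painted structures, and the conformation
number reacts to any dose spill those structures place above the reference
isodose. No anatomical realism beyond topology is attempted — no imaging
simulation, no tissue densities, no registration. Sizes and positions are
configuration (`inst/extdata/default_phantom.json`), not code; `build_phantom()`
enforces strict PTV nesting, presence of all ten OARs, positive volumes and
grid containment.

## Cohort generator

Each synthetic plan is a *profile*: intended values for the 16 dose
submetrics plus delivery metadata (beams, segments, monitor units, beam-on
and total delivery time, general and platform-specific planning experience).

**Marginals.** Each field follows a truncated normal on its published range
with scale equal to the published SD. The *location* is solved so that the
distribution's median equals the published median (`solve_tn_location()`):
published cohorts are summarised by medians, and with an asymmetric
truncation a normal centred on the published mean has a visibly different
median (e.g. for the boost-volume D95%, mean 67.5 and SD 1.2 truncated to
[66.2, 69.7] put the median at 67.66 rather than the published 67.0). Two
conventions handle edge cases: the conformation number's SD is published as
"0.0" (one-decimal rounding), and 0.04 is used as the scale floor; requested
medians are clamped 2% of the range inside the support, since a truncated
normal's median is strictly interior.

**Dependence.** A Gaussian copula imposes the published Spearman
correlations (converted to the copula's Pearson scale by 2·sin(πρ/6)):
beams~segments 0.67, beams~MU −0.63, experience~spinal-canal D0.1cc −0.55,
experience~glottis Dmean −0.55, and segment count against two latent
standard-normal plan-quality factors (0.75 with an overall-quality latent,
0.76 with a PTV-quality latent). All other pairs are left at zero rather
than guessed. Two consequences follow:

* The zero-filled matrix with these entries is not positive semi-definite
  (the segments row alone gives 0.75² + 0.76² > 1 against independent
  latents). The latents are therefore given their structurally implied
  mutual correlation of 0.9 — the overall score contains the PTV subtotal,
  whose spread dominates it — and any remaining infeasibility is repaired to
  the nearest positive semi-definite matrix in a *weighted* Frobenius norm
  (via a congruence transform around `Matrix::nearPD`), weighting the latent
  rows least so the repair lands in the least-identified entries. The
  realised correlations stay within a few hundredths of the imposed ones.
* The latent factors are carried in each profile but do not feed back into
  the metric marginals: the published quality correlations are represented
  by the latents, and the correlation between segment count and the
  *downstream computed* PQM is consequently near zero. Wiring the latents
  into the marginals would have imposed unpublished metric–metadata
  correlations, which we avoid; this is the generator's main known
  limitation.

**Determinism.** One root seed drives the whole cohort; per-plan child seeds
are derived by fixed arithmetic and recorded for provenance. Painting draws
no random numbers at all, so identical (spec, calibration, seed) give
byte-identical cohorts.

## Dose painting

`paint_dose()` turns a profile into a 3D dose grid whose *measured* metrics
reproduce the intended values. Each painting region — PTV1, the PTV2 and
PTV3 shells, each OAR, and the background — receives doses through a
monotone piecewise-linear quantile function d(u) (u = fraction of the region
receiving ≥ d), with anchors computed from the targets:

* **PTV1**: a hot plateau exactly covering the near-maximum volume (D0.1cc)
  followed by a ramp through the D95% anchor.
* **PTV2/PTV3 shells**: anchors are placed in *combined* rank space so that
  metrics defined over a whole nested PTV (hot interior plus shell) land on
  target; the PTV3 shell additionally carries the V56.7Gy anchor (shell-local
  by definition of the metric) and the conformation anchor at the 54 Gy
  reference isodose.
* **Conformation spill compensation**: OARs are painted first, the volume
  they place at or above the reference isodose is counted, and the coverage
  anchor is solved from CN = coverage × selectivity so the measured CN still
  hits the target (a closed-form quadratic).
* **OARs**: near-maximum metrics get a small plateau plus steep falloff
  (which also keeps spill above the reference isodose to a few tenths of a
  cc); mean-dose metrics get a symmetric ±2 Gy ramp whose mean is exact.
* **Background**: exponential falloff with the normalised radial distance
  from PTV3 (scale ⅓ of the radial unit), capped below the shell's coldest
  dose — smooth, monotone, and never reaching the reference isodose.

Spatial assignment is rank-ordered by distance from each structure's centre,
so gradients are spatially coherent; overlapping paints resolve by voxelwise
maximum. The painting contract is 2% relative agreement between intended and
engine-measured values; in practice agreement is ~10⁻⁴ relative (the
contract's slack absorbs coarser grids). Jointly impossible targets — a hot
spot below the coverage dose, elective D95% at or above the reference
isodose, V56.7Gy spill exceeding the conformation coverage — raise an
infeasibility error naming the metric pair. Painted dose never exceeds the
profile's own near-maximum target, hence stays below 115% of the boost
prescription for any calibrated profile.

## DVH engine conventions

* Full-voxel counting (each voxel contributes its whole volume at its dose);
  no partial-volume supersampling. Default bin width 0.01 Gy — 0.1% of the
  elective prescription and far below every tier gap.
* D_x% follows the "minimum dose to the hottest x% of the volume"
  convention (the usual clinical reading of D95 coverage).
* Inverse queries (D_x%, D_xcc) return the centre of the DVH bin where the
  cumulative curve crosses the requested volume, which bounds their error by
  half a bin width against exact sorted-voxel counting — the property the
  oracle test suite asserts. V_xGy and D_mean are exact up to float
  arithmetic.
* Doses are total physical dose in Gy over all 33 fractions; no EQD2/BED
  conversion anywhere.
* Masks must share the dose grid exactly; resampling is out of scope by
  design. The conformation reference isodose for the default scheme is the
  elective prescription, 54 Gy.

## Scoring scheme

The original challenge's per-tier boundaries and point weights are not
recoverable from the published material, so the shipped scheme
(`inst/extdata/default_scheme.json`, provenance `"reconstructed"`) is a
config-driven reconstruction; nothing clinical is hard-coded in logic:

* Ideal (maximum-point) thresholds follow the 95%/107%-of-prescription
  coverage conventions where applicable, adjusted so that the published
  cohort's medians sit on the published side of each threshold (better than
  ideal everywhere except the right parotid and oral cavity means) and the
  four PTV coverage metrics stay within the published <7% deviation bound —
  this pinned the intermediate-volume D95% ideal at 57.0 Gy rather than the
  generic 56.43 Gy.
* Conformation tiers at 0.8 / 0.7 / 0.6 (ideal / good / acceptable).
* Point weights: 6 PTV metrics × 13 = 78; 8 tiered OAR metrics × 7.5 + 2
  binary OAR metrics (brachial plexus D0.5cc, brain D0.1cc) × 6 = 72.
  Tiered points ascend in quarters of the maximum (0, ¼, ½, ¾, 1); binary
  awards all or nothing.
* Values exactly on a boundary take the *better* tier — the same inclusive
  rule as the "20 minutes or less" delivery gate, applied uniformly.
* Delivery time is a gate, not a scored submetric: the 16 submetrics are all
  dose metrics and the maximum score is exactly 78 + 72. Hard-constraint
  bounds (also reconstructed) are placed outside the calibrated ranges so a
  calibrated cohort can only fail the delivery gate — matching the published
  cohort, where a single plan exceeded the time limit.

Because per-tier points are flat and the reconstructed ideal thresholds sit
close to the cohort medians (roughly half the cohort falls one tier short on
any given metric), the synthetic PQM distribution runs a few points lower
than the published one (median ≈ 136–138 vs 141.5). The published per-tier
point values would be needed to close that gap; no parameter here is tuned
to it.

## Cohort statistics

* Relative deviations are (value − threshold)/threshold against each
  metric's ideal threshold; both raw and direction-aligned medians are
  reported, since a boxplot of raw deviations shows "higher/lower" while
  better/worse depends on the metric's direction.
* The signed-rank test drops zero differences (classic Wilcoxon; a
  signed-zero policy is available), uses average ranks for ties, and is
  *exact* for n ≤ 20 by enumeration of all 2ⁿ sign assignments (meet-in-the-
  middle subset sums; identical to brute force, and tested against it). The
  two-sided p is twice the smaller tail, capped at 1. Above n = 20 a normal
  approximation with tie and continuity correction takes over; the branches
  agree within 0.01 at the cutover.
* Spearman correlations use average ranks; p-values come from the
  t-approximation t = ρ√((n−2)/(1−ρ²)) — the approximation used by the
  standard rank-correlation routines. Strength classes use strict cutoffs
  (|ρ| > 0.7 strong, > 0.5 moderate, else weak; 0.5 exactly is weak), and
  the display flag reproduces the "only moderate or stronger shown" matrix
  filter. Constant columns are reported as not-computable, never as 0. No
  multiple-testing correction is applied, matching the analysis being
  reproduced; significance stars are *p<0.05, **p<0.01, ***p<0.001.
* Trade-off fits are ordinary least squares of a PTV metric on the OAR point
  subtotal with a pointwise 95% confidence band for the mean response.

## Problem sizes and what the tests show

The test suite exercises the DVH engine against brute-force sorted-voxel
oracles on random grids up to ~20³, the signed-rank test against full 2ⁿ
enumeration, Spearman against the explicit average-rank formula, and the
scoring layer against boundary-perturbation and monotonicity properties. The
calibration checks paint and re-measure a 500-plan cohort on the default
80³ phantom (about 40 s) and verify that the engine-measured medians recover
the calibrated medians and that the imposed experience~spinal-canal
correlation comes back negative and moderate.

Passing these tests shows the pipeline is self-consistent and correctly
calibrated to the published summaries — it does not show that real plans
behave like painted ones. Painted doses have idealised within-structure
distributions (piecewise-linear quantiles), delivery metadata is sampled
rather than derived from machine physics, and all dependence beyond the
published correlations is absent. Conclusions about real planning behaviour
should rest on real exported dose grids, which the engine accepts unchanged
via NIfTI.
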