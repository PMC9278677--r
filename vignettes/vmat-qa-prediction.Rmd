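---
title: "Predicting patient-specific VMAT QA from MLC kinematics and fluence texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting patient-specific VMAT QA from MLC kinematics and fluence texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatqa)
```

## The problem

Volumetric-modulated arc therapy delivers dose while the gantry rotates and
the multileaf collimator (MLC) continuously reshapes the beam. Before
treatment, each plan is verified by delivering it to a detector and
comparing measured with planned dose via a gamma test; the gamma passing
rate (GPR, percent of points passing at a given dose-difference/distance
criterion) decides clearance. Highly modulated plans — fast leaves, abrupt
accelerations, fragmented fluence — are harder for the machine to deliver
faithfully and tend to produce lower GPR. `vmatqa` builds models that
predict per-arc GPR, or PASS/FAIL against an institutional warning level,
from the plan alone.

The pipeline has five stages, each usable on its own: plan ingestion
(DICOM-RT Plan or a JSON exchange format), feature extraction, SPC
screening of historical GPR, dataset labelling/splitting, and ensemble
model fitting/evaluation.

## Features

**Kinematics.** The delivery sequence is a list of control points (CPs)
with leaf positions per bank and cumulative MU fraction. Under the
constant-gantry-speed assumption the time between CPs is a single per-arc
constant `Δt = cp_interval / gantry_speed` (0.424 s at the defaults of
2.0341° and 4.8°/s). Leaf speed is the magnitude of the position change of
one leaf across one CP interval divided by `Δt`; leaf acceleration is the
magnitude of the change of successive speeds divided by `Δt`. Magnitudes
are used because the summary features — bin-occupancy fractions over
0–20 mm/s and 0–200 mm/s² — are defined on non-negative ranges; the sign of
leaf travel carries no complexity information here. Per bank we report max,
mean, SD, and five bin fractions for speed and acceleration: 32 features.

Two conventions matter and are configurable:

* *Leaf inclusion.* By default only leaf pairs whose physical span
  intersects the y-jaw opening at some CP are included; parked out-of-field
  pairs never modulate dose and would dilute the fractions toward the
  lowest bin. `all_leaves = TRUE` includes every pair.
* *Bins.* Half-open `[lo, hi)` with the top bin closed at the cap. Samples
  above the caps (possible in principle, absent under the generator's
  defaults) are counted in an overflow bucket and logged; fractions then
  sum to less than 1 rather than silently redistributing.

Note a physical coupling: with speeds bounded by 20 mm/s and `Δt = 0.424` s,
acceleration magnitudes cannot exceed `20/0.424 ≈ 47.2` mm/s², so only the
lowest two acceleration bins can be occupied at these delivery settings.
The wider bin grid is kept because other CP spacings or gantry speeds
(smaller `Δt`) populate it.

**Fluence texture.** The per-arc fluence map accumulates, over every CP
interval, the interval's MU increment times the open-aperture indicator
(leaf-pair rows open between the two banks, clipped by the jaws). The
aperture is taken from the interval's starting CP — no intra-interval
interpolation — which keeps accumulation exactly additive over interval
subdivisions. Pixels partially covered along the leaf-travel axis are
area-weighted; across leaf rows the 1 mm default grid aligns with the 5 mm
leaf widths. The grid covers the union bounding box of all apertures padded
by 5 mm at 1 mm spacing — this is a fluence-plane resolution choice, not a
detector property.

The map is linearly quantized to 256 gray levels; co-occurrence matrices at
displacement 1 px and angles 0°/45°/90°/135° are symmetrized, and pairs
whose two pixels are both at background level 0 are excluded before
normalization, so the statistics describe the irradiated region rather than
the empty surround (with the surround included, energy and homogeneity are
dominated by background–background pairs and carry almost no plan
information). Contrast, correlation, energy, entropy (natural log;
`0·log 0 = 0`) and homogeneity are averaged over the four angles to give
one value per arc. Gray-level count, background handling, symmetrization
and log base are all exposed in `glcm()`/`texture_features()` since
different sites quantize differently; results should state them.

## SPC screening and labelling

Historical GPR series are screened with an individuals chart: center line
is the series mean, `mR̄` the mean absolute successive difference, and the
lower control limit `x̄ − 2.66·mR̄` (2.66 = 3/d₂ for moving ranges of two).
Records strictly below the LCL are out of control; records exactly at the
limit are retained. Because the arcs of one plan share a delivery and
measurement session, removal cascades to the whole plan by default
(`level = "arc"` disables this). Only the lower limit filters — QA failures
are one-sided — though the upper limit is reported. The chart may be built
on a longer historical series than the modelling table; both are accepted.

The institutional warning level is the historical mean GPR, which centres
the PASS/FAIL split near 50/50 and keeps the failure class populated —
using a universal tolerance (e.g. 95%) on a cohort that rarely exceeds it
would leave almost no PASS examples to learn from. GPR exactly equal to
the warning level labels PASS: the FAIL definition is "below the level",
so the tie goes to the non-failure side, and the same rule is applied when
thresholding regression predictions.

The train/test split is by plan (default 80/20, `round(0.8·n)` training
plans): arcs of one plan are correlated, and an arc-level split would leak
plan identity across the boundary. The assembled dataset asserts this
invariant on every build.

## Models

* **AdaBoost classification** — discrete AdaBoost (SAMME) authored in the
  package over shallow `rpart` trees (depth ≤ 3, a configurable cap chosen
  as the usual shallow-weak-learner compromise), 500 learners, learning
  rate 0.1 applied to the learner weights `α = lr·log((1−err)/err)`.
  Boosting stops early if a learner is no better than chance or fits
  perfectly.
* **Bagged regression trees** — 500 bootstrap trees with minimum leaf size
  8, implemented as `randomForest` with `mtry = p` (bagging is exactly the
  all-variables special case of random forest). A learning rate is
  sometimes quoted alongside bagged ensembles; bagging has no such
  parameter and none is applied.

Both record a 5-fold cross-validation estimate on the training split as an
overfitting guard, then refit on the full training split; the seed is
mandatory and drives fold assignment and resampling, making fits
bit-reproducible. Tree ensembles are scale-invariant, so no feature
scaling or selection is applied. Feature importance is impurity-based:
learner-weight-weighted `rpart` importance for AdaBoost, total RSS decrease
for the bagged trees, normalized to sum 1.

Evaluation treats FAIL as the positive class (the model exists to catch
failures): sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, reported as
percentages rounded half-up to 2 decimals; for the regressor additionally
RMSE and the percentage of predictions within ±3 GPR points (a difference
of exactly 3 counts as within). An empty class makes the affected metric
`NA` (undefined), never 0.

## The synthetic cohort

`generate_cohort()` exists so that every stage — including failure modes
like out-of-control records — is testable without clinical data. Defaults
emulate a head-and-neck VMAT cohort: 106 plans of 2–4 arcs, 178 CPs per
arc at 2.0341° and 4.8°/s, a 60-pair MLC (5 mm central, 10 mm outer
leaves — a generic leaf model, chosen as a convention). Each arc opens a
contiguous block of 16–36 leaf pairs inside the y jaws; each active leaf
performs a direction-persistent reflecting walk whose per-interval step
lengths are drawn from a five-bin speed mixture. The per-arc mixture
weights jitter around the cohort profile (0.63/0.09/0.05/0.03/0.19,
Dirichlet concentration 55), which is what makes the bin-fraction features
vary between arcs and carry signal. Keeping the two banks on opposite
sides of the midline guarantees collision-free apertures by construction.

GPR is linear in standardized features:
`gpr = clip(intercept − Σ coef_k·z_k + ε, 0, 100)`, with default intercepts
93.50% (2%/2 mm) and 96.53% (3%/2 mm) and the dominant coefficient on
`LS0_4_B` — a larger slow-leaf fraction raises GPR, equivalently high-speed
fractions depress it, the direction complexity metrics are expected to act.
The noise `ε` is Gaussian truncated at 2.5 SD: QA measurement scatter is
bounded in practice, and unbounded tails would plant spurious
out-of-control records that make the SPC stage's planted-truth tests
ill-posed. Planted outliers instead depress all arcs of selected plans by
15 GPR points (plus jitter) — far enough below the expected LCL to stay
out of control even after the outliers themselves inflate the chart's
moving range. A truth record (coefficients, noise SDs, outlier plan ids,
dominant feature) accompanies every cohort so recovery tests compare
against what was planted.

What the generator does **not** emulate: leaf transmission, tongue-and-
groove, rounded leaf ends, dose-rate/gantry-speed modulation, machine
deliverability constraints beyond the speed cap, or clinically realistic
fluence heterogeneity — synthetic maps are smoother than clinical ones, so
their GLCM contrast is much lower and correlation much higher than typical
clinical values. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted structure, not clinical
performance; the published performance of models of this kind can only be
assessed on a real cohort, which no public deposit provides.

## Numerical choices and degenerate inputs

* Closed leaf pairs (equal bank positions) are valid; fully closed arcs
  produce an all-zero fluence map, which quantizes to level 0 and is
  rejected by the GLCM stage only if every pair is background (an error
  naming the cause).
* Degenerate GLCM marginals (a uniform image) make correlation undefined;
  it is reported as 0 with a message.
* A single-interval arc has no acceleration samples; the acceleration
  matrix is empty and downstream moments are `NA` rather than fabricated.
* MU monotonicity, bank collisions and split leakage fail loudly at
  validation rather than propagating.
* DICOM support is a minimal RT-Plan codec (little-endian, explicit or
  implicit VR) covering the beam/control-point subset this analysis reads;
  it is not a general DICOM toolkit, and written files are for fixtures
  and interchange, not treatment.

## Problem sizes used by the test suite

The suite's heavy property checks run at reduced, stated sizes chosen to
exercise the same structure: planted-outlier recovery and importance
recovery use 106-plan cohorts with 30 CPs per arc, 30 leaf pairs and a
2 mm fluence grid over 10–20 seeds; oracle-equivalence checks run on small
random arcs against brute-force loop implementations. The acceptance
script (`scripts/acceptance.R`) runs the full 178-CP, 60-pair
configuration once, end to end.

## Known limitations

* Feature extraction assumes constant gantry speed and CP spacing per arc
  (the single-`Δt` model); plans with strongly modulated gantry speed
  would need per-interval timing, which the data model does not carry.
* The GLCM parameterisation (256 levels, d = 1, background exclusion,
  natural-log entropy) is a documented reconstruction choice; texture
  values are comparable only between runs using the same settings.
* The fluence model is geometric (aperture × MU); it is not a dose engine.
* With FAIL prevalence near 50% by construction of the warning level,
  sensitivity/specificity are stable; on cohorts with rare failures the
  same pipeline would need prevalence-aware thresholds.
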