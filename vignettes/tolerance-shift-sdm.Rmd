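---
title: "Simulating increased thermal tolerance in presence-only SDMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating increased thermal tolerance in presence-only SDMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoshift)
```

## The question the package answers

Sessile cold-adapted marine species — kelps are the motivating case —
cannot track suitable conditions as the ocean warms, and a growing toolbox
(assisted migration, thermal priming, selective breeding) promises to raise
their upper thermal tolerance by a few degrees. `thermoshift` asks the
planning question behind those interventions: *if a species' upper thermal
tolerance were 1–5 °C higher, how much of the habitat that climate change
is projected to take away would be kept?*

The workflow is a standard presence-only species distribution model (SDM)
pipeline with one non-standard step: a logistic transformation of the
training temperature layer that makes the refitted model behave as if the
species tolerated k extra degrees, without creating the artifacts a flat
temperature shift would cause.

## The habitat model

The core model is a MaxEnt-style presence-background estimator. With
feature vector $f(z)$ (linear, quadratic and pairwise-product expansions of
the environmental variables), the habitat model is the Gibbs distribution
over the background cells,

$$ P(z) = \frac{e^{f(z)\cdot\beta}}{Z}, \qquad
   Z = \sum_{z \in \text{background}} e^{f(z)\cdot\beta}, $$

whose coefficients maximize the penalized presence log-likelihood

$$ \frac{1}{m}\sum_{x \in \text{presence}} f(x)\cdot\beta - \log Z
   - \sum_j \lambda_j |\beta_j|, \qquad
   \lambda_j = \mu \, r(\text{class}_j, m)\, \frac{s_j}{\sqrt{m}}, $$

where $m$ is the number of presence cells, $s_j$ the feature's standard
deviation over the background, $\mu$ the beta multiplier (default 1), and
$r(\text{class}, m)$ the published MaxEnt default schedule (breakpoints
$m = 0, 10, 30, 100$ with values $1, 1, 0.2, 0.05$ for linear, quadratic
and product features, interpolated in $m$; see `maxent_reg_schedule()`).
The intercept is implicit in $Z$, so raw predictions sum to exactly 1 over
the training background. Suitability is reported on the cloglog scale,
$1 - \exp(-e^{H}\,P(z))$, with $H$ the entropy of the raw distribution.

**Solver.** The objective is concave with an L1 penalty; `fit_maxnet()`
minimizes its negative by proximal gradient descent (soft-thresholding)
with FISTA momentum on standardized features. A backtracking line search
enforces the majorization bound, and any accelerated step that would raise
the penalized objective is replaced by a plain proximal step with the
momentum restarted — so the objective trace is non-increasing by
construction (it is stored in the fit and asserted in the tests).
Convergence is declared when the objective changes by less than $10^{-8}$
or the largest coefficient update is below $10^{-6}$. The test suite
checks the solver against a generic Nelder–Mead minimization of the same
objective on small instances (agreement within $10^{-4}$ in objective
value).

**Clamping.** At prediction time raw variable values are clamped into the
training range before feature expansion, so projections never extrapolate
features beyond what the fit saw.

## Study design around the model

* **Grid.** All layers live on a shared lattice (`grid_spec`) of square
  0.05° cells, half-open with a lower-left origin; a record exactly on a
  boundary belongs to the higher-index cell. The study-scale default
  covers the North Atlantic (−85…50°E, 35…75°N); the desk-scale default
  (`synthetic_grid()`, 200 × 300 cells) keeps the full pipeline in the
  minutes range.
* **Masking.** Modelling is restricted to sea cells with depth ≤ 200 m;
  the depth boundary is inclusive.
* **Occurrence curation.** Exact coordinate duplicates (after rounding to
  6 decimals, ≈0.1 m — the sources do not define a dedup radius) are
  collapsed; records with spatial uncertainty above 10 km (≈2 cells; no
  published cutoff exists, so it is configuration) or outside the study
  bounds are dropped; records with unknown uncertainty are kept and
  logged, since the curated source datasets are pre-screened.
* **Collinearity pruning.** Pairwise Spearman correlations are computed on
  a seeded subsample of ≤ 10,000 valid cells (the full grid is an option;
  whether the original analysis sampled is unstated). While any
  unprotected pair exceeds |ρ| = 0.8, the member with the larger mean
  absolute correlation against the remaining variables is dropped, ties
  going to the alphabetically later name. Temperature is protected — this
  reproduces the removal of an ice-cover layer against maximum SST.
* **Contribution filter.** "Contribution to the model output" is
  operationalized as permutation importance on training AUC (seeded,
  model-agnostic): shuffle one variable across presences and background,
  rebuild features, record the AUC drop, floor negatives at zero and
  normalize to percentages. Variables under 5% are dropped (temperature
  again protected) and the model refitted, for at most two rounds. In a
  multi-species setting the filter should drop only variables below
  threshold for *all* species; the per-species rule applied here is the
  single-species specialization of that.
* **Spatial cross-validation.** Square blocks are sized from an empirical
  correlogram of the temperature layer (smallest candidate at least as
  large as the distance where autocorrelation first falls below 0.1 —
  the trend-dominated layers of the synthetic world often push this range
  past all candidates, in which case the largest candidate is used with a
  warning), shuffled with a seed, and dealt round-robin into 5 folds.
  Background cells inherit the fold of their cell, so evaluation is
  spatially honest. Candidates (feature-class sets × beta multiplier;
  default {L, LQ, LQP} × {1}) are compared on the mean *absolute*
  train−test AUC difference. The absolute value matters: the signed
  difference would reward underfit candidates whose test AUC happens to
  exceed their training AUC, and we observed exactly that failure mode
  (a linear-only model with test AUC 0.64 "beating" a quadratic model at
  0.86). Ties go to the higher test AUC, then to fewer feature classes.
  The reported map is the cell-wise mean of the five sub-model cloglog
  maps; a pooled all-folds fit supplies the response curve.
* **Binarization.** The threshold is the largest value capturing 95% of
  the occurrence cells (the ⌈0.95 n⌉-th largest occurrence suitability),
  recomputed per model from its own present-day prediction.

## The tolerance transform

A flat +k shift of all warm cells would tear the response curve apart
(missing temperatures, rank inversions). Instead each training cell's
temperature $x$ becomes $x + \delta(x)$ with

$$ \delta(x) = \frac{T_{\mathrm{inc}}}{1 + e^{-r\,(x - p)}}, $$

where $p$ is the suitability peak of the base model's response curve, $r$
(default 2 °C⁻¹, so the transition spans about ±2 °C around $p$; the
original value is unpublished and it is exposed as configuration) sets the
steepness, and $T_{\mathrm{inc}}$ is the asymptotic increment. δ is
strictly increasing and bounded in $(0, T_{\mathrm{inc}})$, so cold cells
are untouched, the warm tail is stretched by almost $T_{\mathrm{inc}}$,
and temperature ranks are preserved. Occurrences are never moved and
projections always use *unmodified* scenario layers — only the training
layer changes, which is what makes the refitted upper tail express added
tolerance.

**Calibration.** $T_{\mathrm{inc}} > k$ is needed to move the *binarized*
warm edge by exactly k. Full-mode calibration bisects
$T_{\mathrm{inc}} \in [k, k+10]$, retraining a pooled model on the
transformed layer at each step, until the retrained response curve's upper
threshold crossing sits $k \pm 0.05$ °C above the base model's. Two design
details matter here:

1. the retrained curve is evaluated at *its own* occurrence-capture
   threshold, because that is the threshold its maps are binarized with;
   matching crossings at the base threshold systematically undershoots
   whenever the shifted model's capture threshold drifts upward;
2. the bisection uses a pooled (all-folds) model rather than the 5-fold
   ensemble — the ensemble is refitted once at the calibrated value, and
   calibrating against it at every bisection step would quintuple the cost
   without changing the crossing estimate.

Fast mode (used in unit tests and available as configuration) skips
retraining and returns the first-order value
$k\,(1 + e^{-r (x_{\mathrm{cross}} - p)})$, i.e. k divided by the fraction
of δ attained at the base crossing.

## Loss and recovery accounting

Cells lost under a scenario are present-suitable ∧ future-unsuitable under
the base model. Areas use the spherical cell area
$(0.05 \cdot \pi/180 \cdot R)^2 \cos(\mathrm{lat})$, $R = 6371.0088$ km.
Range contraction and minimum suitable latitude are reported per ocean
basin (split at a configurable meridian, −40° at study scale, mid-grid on
synthetic worlds).

Recovery is restricted to the lost set: habitat newly colonized elsewhere
is reported separately but never inflates recovery percentages (the area
subtraction in the source method is ambiguous on this point; the
restriction is the conservative reading). For ascending k, the cumulative
recovered set is the *running union* of the per-k recovered sets. The
union matters: defining cumulative(k) as "lost ∧ suitable under model k"
alone breaks the exact identity
`lost = Σ incremental + unrecovered` whenever a cell recovered at some k
drops back out at k+1 (model noise); with the union the identity holds
cell-by-cell on every run (asserted in the tests), cumulative recovery is
non-decreasing, and the per-cell "first recovering k" map is well defined.
Cells that flip back are counted and logged.

## The synthetic world

`make_world()` generates the study conditions at desk scale: a temperature
field with a monotone south-to-north cooling gradient (26 °C at the
southern edge, 1.8 °C per degree latitude) plus smooth seeded noise
(Gaussian-blurred white noise, sd 0.8 °C, length scale 6 cells — cheap,
reproducible, and spatially autocorrelated enough to exercise the blocked
CV); salinity and phosphate fields with mild structure; `degree_days`, a
strictly increasing transform of temperature (Spearman ρ exactly 1, to
exercise pruning); `turbidity`, pure smoothed noise (to exercise the 5%
filter); a depth field with a coastal shelf and a land mask. Future
scenarios add a uniform warming offset to temperature only (a
latitude-dependent option exists). Occurrences are Bernoulli draws from a
planted niche: a Gaussian thermal kernel (peak 17 °C — within the 15–17 °C
range of thermal optima reported for cold-adapted North Atlantic kelps —
sd 1.2 °C) times a logistic salinity response, scaled to a 0.2 maximum
occupancy so that one sampling pass over the default grid yields roughly
500 occupied cells.

What the synthetic world does *not* emulate: real bathymetry or
climatology values, coastline geometry, sampling bias, dispersal
limitation, or biotic interactions. Passing tests therefore demonstrate
that the pipeline recovers *known* structure under its own assumptions —
they say nothing about transferability of any real-data fit.

## Default problem sizes and run times

The default synthetic study uses the 200 × 300 grid (~27,000 modelling
cells after masking), ~500 occurrence cells, a background capped at a
seeded sample of 10,000 cells (the original background size is
unpublished; the cap is configuration), three candidates × 5 folds for
selection, and full calibration for k = 1…5 over three warming scenarios.
That is ~80 penalized fits and completes in well under a minute on one
core; the entire test suite, which runs the study once plus hundreds of
smaller checks, takes under a minute.

## Known limitations

* Only linear, quadratic and product features are implemented (hinge,
  threshold and categorical features were not used by the analysis this
  package operationalizes).
* No reprojection or resampling: all rasters must share the grid exactly.
* Recovery percentages depend on the binarization threshold rule; with
  very few occurrence cells the 95% capture quantile is unstable (warned
  below 20 cells).
* The transform only raises the warm tail; cold-edge tolerance changes and
  mechanistic physiology are out of scope.
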