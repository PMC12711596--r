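---
title: "Methods: ensemble SDM with bias-corrected pseudo-absences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SDM with bias-corrected pseudo-absences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `ensdm`, the design
decisions taken where the methodology is genuinely open, the numerical
conventions that make results reproducible to the bit, and what the
synthetic-landscape tests do — and do not — demonstrate about real data.

## The modelling problem

Presence-only occurrence data carry two intertwined biases: records
accumulate where observers go (accessibility bias), and the absence of a
record says nothing about the absence of the species. The workflow treats
both explicitly. Pseudo-absences are restricted to environmentally
dissimilar ("low-suitability") areas, and additionally to areas that were
demonstrably surveyed, so that the absence of records there is informative.
On top of this labelled set, an ensemble of heterogeneous learners is
fitted, evaluated and combined by predictive skill.

## Pseudo-absence generation

**Envelope index.** For each predictor layer $j$, let $\mu_j$ and
$\sigma_j$ be the mean and standard deviation of the layer at presence
locations. The index of a cell with values $x_j$ is

$$\mathrm{index} = -\frac{1}{p}\sum_{j=1}^{p}
  \left|\frac{x_j - \mu_j}{\sigma_j}\right|,$$

the negative mean absolute z-distance to the presence centroid. It is
maximal (zero) at the centroid, invariant to affine rescaling of any layer,
and free of tuning constants. A Mahalanobis-type index would additionally
account for inter-layer correlation, but requires a well-conditioned
covariance matrix of presence values; the mean-|z| form is the simplest
index consistent with "distance from the mean environmental
characteristics", and is the default. Zero-variance layers at presences are
skipped with a warning.

**Median split.** The threshold between the low- and high-suitability zones
is the *median index value at the presences*, not the landscape median.
These differ: a presence-median split need not halve the study area. The
presence-median rule is used because it is the operational definition that
can be applied to any landscape; ties go to the high zone (cells with index
$\geq$ threshold are high), so when all presences share one index value the
low zone is the strictly-below set.

**Survey effort.** Records of surrogate species with similar detectability
are rasterised to per-cell counts and smoothed with a square focal mean
(default 3 × 3 cells; the window is expressed in cells, which equals a
3 km × 3 km window only when cells are 1 km). Edge and corner cells average
over the neighbours that exist, so a constant field is a fixed point of the
filter. Candidate pseudo-absence cells must have effort at least
`effort_floor` (default 0.40) times the maximum smoothed effort.

**Relaxation.** If fewer than `n` candidates remain, the floor is lowered
by `relax_step` (default 0.05) and candidates re-derived, until either
enough exist or the floor reaches zero; if still short, cells are drawn
with replacement and the result carries a `degraded` flag — never silently.
Relaxation is monotone: lowering the floor can only add candidates.

**Weights.** Presences have weight 1; each pseudo-absence has weight
$n_{\text{presence}} / n$, so the two classes have exactly equal summed
weight within every replicate. Learners that accept case weights use them;
random forest, discriminant analysis and the range envelope do not, which
is recorded in their documentation rather than worked around.

## The ensemble

**Design.** Each of the `algorithms` (default all ten: GLM, GAM, MARS, GBM,
ANN, RF, MAXENT, SRE, CTA, FDA) is fitted once per pseudo-absence replicate
(default 3) and per stratified 70/30 split (default 3), giving 90 runs in
the default design. Splits are stratified by label so class balance is
preserved to within one record, and are drawn independently per replicate.

**Skill metrics.** AUC is the rank-based (Mann–Whitney) estimate with ties
counted one half. TSS is maximised over a fixed grid of 101 thresholds on
$[0,1]$; a record is predicted present when its score is $\geq$ the
threshold, and the smallest threshold attaining the maximum is reported.
The fixed grid makes the argmax deterministic and identical across
platforms; a data-driven threshold set would be marginally sharper but
depends on the score sample.

**Gate and weights.** Runs enter the ensemble iff TSS is *strictly*
greater than `tss_cutoff` (default 0.60) — a run at exactly the cutoff is
excluded. Member weights are raw TSS values normalised to sum to one
(rescaled alternatives such as TSS² concentrate weight faster but add a
free parameter). If no run passes, fitting stops with an explicit error
rather than falling back to an unweighted mean. With a deliberately
non-positive cutoff (only possible by overriding the default) retained TSS
values can sum to zero; equal weights are then used.

**Binarisation.** Continuous ensemble maps are thresholded at the value
maximising the *ensemble's* TSS on the pooled holdout records, and — by
design — future projections reuse the current map's threshold, so
current-vs-future differences reflect the climate signal rather than
threshold drift.

**Delegated learners.** The ensemble framework, the envelope classifier
(SRE: presence iff every predictor lies within the presence
`[q, 1−q]` quantile bounds, default q = 0.025) and all evaluation code are
native. The other learners wrap standard implementations (`stats::glm`,
`mgcv::gam`, `xgboost`, `nnet`, `randomForest`, `rpart`, `glmnet` for the
penalised maximum-entropy-style logistic model, `MASS::lda` on a
linear-plus-quadratic basis for the flexible discriminant, and a
hinge-basis weighted logistic regression for the spline learner) behind a
uniform score-in-$[0,1]$ contract. The framework does not hard-require all
ten: any subset can be configured.

## Predictor screening

VIF is computed from $R^2$ of the linear regression of each layer on all
others, over a seeded subsample of valid cells (default 10,000) — the
statistic stabilises quickly and full-raster regressions add nothing but
cost. While any VIF $\geq$ 5 (default), the largest is dropped; a perfectly
collinear duplicate yields $R^2 = 1$ within guard tolerance
($1 - 10^{-12}$) and is treated as infinite VIF, so it is dropped first.
Ties on the maximum drop the lexicographically later name, making the
dropping order deterministic.

## Spatial conventions

* Rasters are planar with km units; cells are square; row 1 is the
  southern row. Cell membership is half-open
  (`floor((coord − origin)/cellsize)`), so a point on an interior edge
  belongs to the north-eastern cell.
* Thinning keeps one record per 15-km cell (the scale of the focal
  species' home range), chosen uniformly under the stage seed; the grid is
  anchored at the raster origin. Grid-based thinning (not pairwise
  distance thinning) is used because the one-per-cell rule is exactly
  checkable and idempotent.
* Zonal statistics and wind-farm overlap use the cell-centre rule: a cell
  belongs to the polygon (or disc) containing its centre. This makes zonal
  sums over a partition exactly equal the whole-map total. The price is
  quantisation: a clearing buffer smaller than a pixel counts either the
  whole containing pixel or nothing. Overlap percentages are reported per
  farm and aggregated by status; a merged-union variant (each suitable
  cell counted once across overlapping buffers) is also returned, since
  per-farm summation can double-count where buffers overlap.
* The 0.8606 km² per-pixel conversion is the square of 30 arc-seconds of
  arc at the WGS84 equatorial radius; synthetic planar landscapes use
  `cell_size²` instead.

## The synthetic landscape generator

`make_stack()` builds standardised smoothed Gaussian fields (white noise →
Gaussian blur of radius `smoothness` cells with edge renormalisation →
standardisation). Requested collinear pairs are imposed by empirically
orthogonalising the target field against the source and mixing with weight
$\rho$, so the *sample* correlation equals $\rho$ exactly rather than in
expectation. `make_truth()` defines suitability as the inverse logit of a
linear combination of standardised layers — the ground truth for recovery
tests. Presences are drawn cell-wise with probability proportional to
truth × accessibility bias, with coordinates at cell centres so thinning
and envelope arithmetic are exactly checkable. Surrogate species for the
effort layer share the *bias field only* and carry their own random
preference coefficients: survey effort must reflect where observers go,
not where the focal species lives, otherwise the effort floor would
selectively place pseudo-absences in good habitat and corrupt the labels.
Pseudo-GCM futures shift named layers by scenario deltas plus smooth
per-GCM noise; zones are exact Voronoi tilings; wind farms are uniform
points with uniform capacities.

What the generator does **not** emulate: real geography and coastlines,
the semantics of actual bioclimatic variables, spatially structured
residuals beyond Gaussian smoothing, temporal dynamics in occurrence
records, or GCM physics. Passing tests therefore demonstrate the
correctness and internal consistency of the workflow's logic — not that any
particular real-world dataset satisfies its assumptions.

## The recovery benchmark

`recovery_benchmark()` is the package's ground-truth stress test: a
100 × 100-cell landscape (1-km cells, smoothness 2), five predictors of
which three are informative (logit-scale coefficients 8, −5.2 and 4,
intercept −3 — a strong but not separable signal; the intercept keeps
overall prevalence realistic rather than half the landscape suitable), a
two-block accessibility bias (0.5 west, 1.0 east), 500 presence records,
nineteen surrogate species of 100 records each for the effort layer, and
2,000 pseudo-absences through the full envelope → median split → effort
floor machinery. A GLM + RF + GBM + SRE ensemble is fitted with a single
70/30 split and the default 0.60 gate, and scored by pooled-holdout AUC and
the Pearson correlation between the ensemble map and the true surface over
valid cells. These problem sizes keep the benchmark comfortably within a
typical continuous-integration budget while leaving enough cells and
records for the skill statistics to be stable.

## Numerical and degenerate-input conventions

* Every generator and fitting routine is a pure function of its seed;
  stage seeds derive from the master seed by a stable hash
  (`derive_seed()`), so no stage perturbs another's random stream.
* Aspect of flat DEM cells is the sentinel −1 (aspect is undefined at zero
  gradient); DEM borders are nodata under the 3 × 3 stencil.
* Focal means and alignment propagate nodata; aligned stacks apply the
  union of member masks so all layers share one mask.
* Empty cleaning results warn rather than error; an empty low zone, an
  empty target group, an all-zero sampling surface and a single-class
  metric input are errors with specific messages.
* Degraded pseudo-absence mode (floor exhausted) is flagged on the result
  object and in the run manifest. On small demonstration landscapes —
  including the 100 × 100-cell default configuration — the low zone simply
  has fewer cells than the requested 10,000 pseudo-absences, so the
  default run operates in this flagged mode by construction; on
  continental grids of millions of cells the floor binds instead.

## Known limitations

* Learners that ignore case weights (RF, FDA, SRE) see the raw class
  imbalance; with the default equal-sum weighting this is the familiar
  presence/background asymmetry, not a bug, but comparisons of member
  calibration across algorithms should keep it in mind.
* Permutation variable importance (1 − correlation between reference and
  permuted predictions, normalised to 100%) measures each layer's
  influence on the *ensemble output*, which is attenuated for correlated
  predictors that survived screening.
* The pipeline models habitat suitability only: no dispersal constraints,
  demographic processes, or extrapolation (no-analog) screening in
  scenario projections.
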