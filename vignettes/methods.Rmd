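---
title: "Methods: presence-only SDMs with effort-based pseudo-absences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only SDMs with effort-based pseudo-absences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fjordSDM)
```

## The modelling problem

Opportunistic marine-mammal sightings from tour boats tell us where animals
were seen, never where they were absent — and the places anyone looked are
themselves biased toward the harbor, good weather, and previous sightings.
`fjordSDM` implements a monthly pipeline for exactly this situation: it
converts logged survey effort into a background ("pseudo-absence") sample
that carries the same spatial bias as the sightings, then fits and compares
two habitat-suitability engines on the resulting presence/background table,
six environmental covariates per point (sea-surface temperature °C,
chlorophyll-a mg/m³, surface salinity PSU, depth m, seabed slope °, shore
distance m).

The central assumption is that the trackline density is a faithful proxy
for detection opportunity: under it, contrasting presences against
effort-weighted background measures habitat preference rather than
observer behavior. Where that assumption fails (e.g. detectability varying
with distance or sea state) the contrast is still biased; the package makes
no attempt to model the detection process itself.

## Effort-based pseudo-absences

A month with `Effort_h` hours and `Days` search days receives
`round(Effort_h * 4 + Days * 5)` background points (`n_pseudo_absences()`).
Rounding is half-up, though all published monthly inputs are integers so the
rounding never engages for them. Placement is a two-stage draw: cells with
replacement in proportion to a density surface, then a uniform position
inside the drawn cell. The density surface (`trackline_density()`)
accumulates the exact polyline length per cell — segments are split
analytically at grid lines, so a segment crossing three cells equally gives
each exactly one third of its length — and is then smoothed with a Gaussian
kernel (default bandwidth 2 cells; no published value exists, and the
qualitative behavior is insensitive between 1 and 4), zeroed on land, and
normalized. Cells, not points, carry the weights, because the effort proxy
is naturally a raster quantity. Presence cells are *not* excluded from the
background by default — background samples are meant to represent available
and surveyed habitat, which includes occupied cells — but an exclusion set
can be passed for sensitivity analyses.

## The maximum-entropy engine

`fit_maxent()` maximizes the L1-penalized presence/background log-likelihood
("gain") over hinge-feature weights. Design choices worth recording:

* **Features.** Forward and reverse hinges at `knots_per_covariate`
  empirical quantiles (default 30 for standalone fits; the bundled study
  driver uses 10 to keep the 10-fold refits cheap), rescaled to [0, 1] over
  the training range; covariates are clamped to that range at prediction
  time. Constant covariates silently contribute nothing.
* **Penalty.** `λ_j = β √(s²_j / m)` with `s²_j` the feature variance over
  presences (all-rows fallback for presence-constant features, floored at
  1e-4 so no feature is ever penalty-free; features live in [0, 1], so this
  floor is small relative to any informative feature's variance). β defaults
  to 1.
* **Optimizer.** Proximal gradient ascent (soft-thresholding for the
  non-smooth L1 term) with backtracking, started from all-zero weights.
  Backtracking makes the gain sequence provably non-decreasing — a property
  the test suite asserts — and the concavity of the objective means the
  stationary point it reaches is the global maximum, which the tests
  confirm against brute-force grid searches in up to three feature
  dimensions. Convergence is declared at a gain improvement below 1e-5;
  the iteration cap defaults to 500. On strongly separable data with weak
  regularization the objective can be unbounded along a feature direction;
  the fit then runs to the cap and returns with a warning rather than an
  error, mirroring how maximum-entropy software behaves in practice.
* **Output scale.** The fitted Gibbs density is presented as
  `1 − exp(−e^H · raw)` with `H` the entropy of the background density —
  a conventional 0–1 suitability index. Every evaluation in the package is
  rank-based, so nothing downstream depends on this monotone transform;
  `output = "raw"` exposes the relative occurrence rate directly.

## The neural engine

`train_mlp()` trains the fixed 6-16-32-64-1 architecture (ReLU hidden,
sigmoid output) by full-batch gradient descent on mean binary cross-entropy
plus an L1 weight penalty. Parameters and their defaults:

* `learning_rate` 0.05 — plain gradient descent, no momentum or adaptive
  steps, keeping the update rule exactly what it claims to be; a config
  switch is deliberately absent rather than half-supported.
* `l1_strength` 1e-4 — far below the maximum-entropy β of 1, as befits a
  network with thousands of weights rather than hundreds of features.
* Early stopping after `patience = 5` consecutive iterations without a
  strict cost decrease (tolerance 1e-12), cap 500; the returned parameters
  are the best seen, so the reported cost is the minimum of the history.
* He initialization (normal, sd `√(2/fan_in)`) for the ReLU stack — the
  standard choice where only "random values" is otherwise specified —
  biases zero, all seeded and reproducible.
* Inputs are standardized with the mean/sd of the **first** month the model
  ever sees, then frozen, so warm-started models keep a stable input scale
  across the season.

Monthly updating (`update_monthly()`) trains on the new month's rows only,
warm-starting from the previous model; the accumulated signal lives in the
parameters. The alternative reading — retraining on all data to date — is
available to callers by passing a concatenated table, but it changes the
computational character of the method (cost grows with the season) and was
not adopted as the default.

## Evaluation

AUC uses the Mann–Whitney rank construction with ties counted one half,
making it exact and transform-invariant; the background points serve as the
negatives, the only construction available to a presence-only design.
Cross-validation is 10-fold and stratified (plain random subsets would risk
presence-free folds in low-sighting months). Permutation importance
shuffles one covariate at a time (10 repeats, mean drop, negative drops
floored at zero as noise) and normalizes to percentages; it is computed on
whatever table the caller provides — held-out data where available is the
less optimistic choice. Report rounding is 3 decimals, half-even; counts
above the 0.7 threshold use a strict inequality.

## Projections

Two deliberately different protocols probe transfer to an unmodelled year.
The maximum-entropy protocol refits per calendar month on pooled historical
sightings with covariates read from the cell-wise multi-year mean of that
month's stacks (nodata-aware: a cell is missing only if missing in every
year; static layers pass through untouched). The network protocol applies
the final warm-started model unchanged. Both score against the target
month's actual sightings versus pseudo-absences generated from the target
month's own effort — the published protocol names only the test presences,
and effort-based negatives keep the train and test constructions
symmetric. Projections with fewer than 5 test sightings are flagged
(`low_support_flag`) but still reported: an AUC from two points is noise,
and the flag records that without censoring it.

## The synthetic fjord

The generator emulates the statistical structure the pipeline assumes:

* a bathymetry deepening away from a wiggly land margin on the eastern
  edge (harbor on its coastline), slope as the central-difference gradient
  magnitude in degrees, shore distance as a Euclidean distance transform;
* monthly dynamic fields as Gaussian-smoothed white noise (radius 3 cells)
  plus a sinusoidal seasonal cycle, clipped to plausible North Atlantic
  ranges: SST in [−1, 14] °C, chlorophyll-a in [0.05, 20] mg/m³ (generated
  on the log scale), salinity in [30, 36] PSU;
* tours as biased random walks from the harbor, retraced homeward, three
  hours each; when a tour count is not imposed, daily counts are Poisson
  with mean 1.43 over a 28-day month;
* sightings drawn with probability proportional to true suitability times
  trackline density — the same kernel as the pseudo-absence machinery, so
  the built-in observation bias and its correction are commensurable.

The true suitability is the inverse logit of a per-SD linear combination
of the covariates. The default coefficients (SST 3.5, chlorophyll-a 0.8,
depth −1.2, intercept −2.5) encode a warm-water, productivity-linked,
deep-basin feeding preference at low prevalence. The depth sign matters
beyond biology: a shallow-water preference would make suitability peak
near shore exactly where harbor-centred effort concentrates, leaving
presences and background statistically indistinguishable — an
unidentifiable world in which no engine, however correct, could
demonstrate skill. The defaults were set so that an oracle scoring points
by the true suitability itself discriminates in the "good" AUC band; the
engines are then genuinely tested against an attainable ceiling.

What the generator does **not** emulate: currents, prey fields, tides,
weather, distance-dependent detectability, inter-annual environmental
trends, or multi-species confusion. Passing tests on this world therefore
demonstrate correctness of the estimation machinery under the stated
bias model — not that the engines would achieve comparable skill on any
particular real survey.

## Problem sizes and determinism

The bundled end-to-end experiment runs 8 months on a 64 × 64 grid of 500 m
cells with 150 sightings and 40 tours (120 effort hours) per month — large
enough for stable 10-fold AUCs, small enough that the whole study completes
in minutes on one core. Every stochastic stage derives its own child seed
from the master seed and a stage label (`derive_seed()`), so any stage is
reproducible in isolation and identical configurations yield byte-identical
report files, which the test suite verifies. Rasters are exchanged as
plain-text ESRI ASCII grids, tracklines as GeoJSON, models as a
17-significant-digit text serialization that round-trips parameters
exactly.

## Known limitations

* The trackline density bandwidth and the tour random-walk geometry are
  pragmatic stand-ins, not fitted to real vessel behavior.
* The maximum-entropy L1 scales follow the variance-based rule above; no
  attempt is made at bit-compatibility with any specific maximum-entropy
  software release.
* Cross-validation folds are random, not spatially blocked; with strong
  spatial autocorrelation random folds flatter both engines equally.
* The covariate screening reports Pearson correlations and VIFs but never
  drops variables; on the synthetic bathymetry depth and shore distance
  are nearly collinear by construction and their VIFs are accordingly
  enormous — informative output, not a defect.
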