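---
title: "Methods: seafloor up-scaling and maximum-entropy habitat modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seafloor up-scaling and maximum-entropy habitat modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralniche)
```

## The problem

Framework-forming cold-water corals (*Lophelia pertusa* and its relatives)
live on continental shelves, slopes and seamounts, far below the reach of
routine survey. Predicting where they can occur requires two things that are
rarely available together: seafloor environmental conditions at a resolution
fine enough to resolve slopes and seamounts, and a modelling approach that
works with presence-only records. `coralniche` implements both halves as a
tested pipeline:

1. **Up-scaling.** Ocean climatologies (temperature, salinity, nutrients,
   carbonate chemistry) are distributed as coarse grids binned at standard
   depth levels (z-bins). Assuming the value at a given depth bin represents
   conditions on seafloor lying at that depth, each bin can be *draped* over
   the bathymetry cells whose depth falls inside the bin's interval, and the
   draped bins merged into a continuous high-resolution seafloor layer.
2. **Niche modelling.** A presence-background maximum-entropy model (Maxent)
   is fitted to presence records against a random background sample of the
   analysis area, evaluated with presence-background AUC, test gain,
   fixed-percentile thresholding, omission rates and a jack-knife of variable
   importance.

A synthetic-world generator with a planted (known) niche makes every stage
testable end to end and lets the tests measure whether the fitted model
recovers the truth it was given.

## Up-scaling a z-binned climatology

For each depth slice of a z-binned field the pipeline performs:

* **Inverse distance weighting** (`idw_interpolate()`) onto an intermediate
  grid, 0.1° by default. Each output point is the inverse-distance-power
  weighted mean of the `max_neighbors` nearest valid source cell centers.
  Defaults are power 2 and 12 neighbours — the conventional IDW settings —
  and both are exposed in `idw_config()`. Distances are planar degree
  distances between cell centers; interpolation runs on the valid cell
  centers of the native grid. This step exists to close the gaps that
  otherwise open between adjacent depth bins when coarse cells are draped
  onto fine bathymetry.
* **Nearest-neighbour resampling** (`resample_nearest()`) onto the bathymetry
  grid, with no further interpolation: each fine cell takes the value of the
  intermediate cell containing its center, so no value is invented.
* **Depth assignment** (`drape_zbins()`): a sea cell whose depth lies in
  `[top, bottom)` of exactly one interval takes that slice's resampled
  value. Depth-interval membership is half-open so a boundary depth belongs
  to the deeper bin, never to two. Intervals are built from the level depths
  with boundaries at midpoints between consecutive levels
  (`depth_intervals()`); the levels' bin edges are not part of the
  distributed products, and midpoints are the symmetric choice.

Cells deeper than the deepest interval keep the deepest slice's value. Deep
water below the covered range is comparatively stable, and the corals of
interest are not documented at such depths, so holding the deepest bin
constant is benign for suitability modelling. Shallower-than-shallowest
cannot occur because the first interval starts at 0 m.

Surface-only products (`upscale_surface()`) skip depth assignment: IDW, then
resampling, then a land mask.

### Grid model and registration

All rasters share one convention (`coral_grid`): square cells,
cell-center registration, the origin at the outer (NW) corner, and half-open
cell footprints `[west, east) × [north, south)`. Half-open footprints make
point-in-cell assignment deterministic — a record or bottle station on a
shared edge belongs to exactly one cell — which matters for presence
deduplication and station intersection. Depths are metres positive-down
everywhere; elevation-convention bathymetry is negated on ingest and
anything at or above sea level becomes land (nodata). Rasters are read and
written as ESRI ASCII grids with 6-significant-digit values, a plain-text
format that round-trips exactly; z-binned fields use a directory of ASCII
slices plus a JSON manifest of level depths.

### Terrain variables

From bathymetry the package derives, per cell:

* `terrain_slope()` — radians, from a 3×3 Horn finite-difference gradient,
  with east-west spacing converted to metres per row from the cell latitude
  (spherical Earth, radius 6371 km).
* `windowed_slope()` — slope of the depth surface smoothed by a
  kilometre-radius moving average (the field convention uses 5, 20, 30 and
  100 km windows); the km radius becomes a per-row whole-cell radius,
  minimum one cell.
* `rugosity()` — surface-area to planar-area ratio within the window.
  Per-cell surface area is triangulated from eight 3-D facets joining the
  cell center to midpoints towards its eight neighbours; the window ratio
  divides summed facet area by the matching planar area, so flat seafloor is
  exactly 1 and every value is ≥ 1.
* `bpi()` — bathymetric position index: neighbourhood mean depth minus cell
  depth (center excluded), positive on crests, negative in depressions.

Aspect is deliberately not implemented: it does not enter the final model
set this pipeline targets.

## Presence handling

`load_presences()` reads `species, lon, lat` CSVs, normalizes longitudes to
[−180, 180) and drops unparsable rows with a count.
`dedup_and_filter()` applies the standard cleaning: records outside the
analysis area are removed, records on cells lacking any covariate are
removed (a presence is only usable where the model has a complete covariate
vector), and each grid cell keeps a single record — multiple records in one
cell would weight the model towards that cell's conditions. The record kept
is the first in input order, a deterministic tie-break.
`combine_species()` pools species sets and re-deduplicates per cell to build
a combined framework-former analysis. `export_swd()` writes the
samples-with-data table (species, coordinates, covariates) consumed by the
model.

Depth-implausible records (e.g. reported far deeper than the species'
plausible range) are retained, not dropped: such records are usually
position errors rather than fabrications, and the fixed-percentile
threshold (below) exists precisely to absorb a contaminated tail.

## The maximum-entropy model

The model is the Gibbs distribution over the background cells,

$$ q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z_\lambda}, \qquad
   Z_\lambda = \sum_{j \in \text{background}} e^{\lambda \cdot f(x_j)}, $$

whose weights maximise the L1-regularized average log-likelihood of the
presences ("gain"):

$$ G(\lambda) = \frac{1}{m}\sum_{i=1}^{m} \lambda \cdot f(x_i)
   - \log Z_\lambda + \log N - \sum_k \beta_k |\lambda_k|. $$

The gain is 0 for the uniform model and `exp(gain)` is the mean likelihood
ratio of a presence against a random background cell.

**Features.** Covariates are clamped to the training range and scaled to
[0, 1]; features are linear, quadratic, pairwise-product and hinge
transforms, all again in [0, 1]. Which classes are used follows the
presence count, mirroring the auto-feature convention: linear always,
quadratic from 10 presences, hinge from 15, product from 80. Threshold
features are omitted — hinge features span the same step-like responses
smoothly. Hinge knots sit on an even grid over the scaled range, 25 forward
plus 25 reverse hinges per variable; an even 50-knot grid is a tractable
desk-scale stand-in for knots at every data value and showed no recovery
loss in the planted-truth tests.

**Regularization.** Each feature's β is the published Maxent default for its
class, linearly interpolated in the presence count, times the
`regularization_multiplier` (default 1), times the feature's standard
deviation over the presences divided by √m. The deviation is floored at
0.05 so that no feature is ever free of penalty (the published tables do not
state their floor; 0.05 of the unit feature range is this package's choice).

**Optimization.** Sequential coordinate-wise updates: for feature k with
empirical mean p and background expectation E, the update δ minimises the
standard upper bound of the change in regularized log loss,
`−δp + log(1 + (e^δ − 1)E) + β(|λ+δ| − |λ|)`, which has a closed-form
solution by sign case. The bound is valid because features lie in [0, 1],
and it guarantees the gain never decreases across updates — asserted in the
test suite over whole fitting traces. Iteration stops when a full pass
improves the gain by less than `convergence_threshold` (default 10⁻⁵) or at
`max_iterations` (default 500) passes; the regularization multiplier
defaults to 1. Updates are capped at ±30 per step to keep exponentials
finite; E is clipped to [10⁻¹², 1 − 10⁻¹²].

**Logistic output.** The habitat suitability index of a cell is
`HSI = c·q(x) / (1 + c·q(x))` with `q` the cell's Gibbs density relative to
the background sample and `c = exp(H)`, H the entropy of the fitted
background distribution. This is the classic logistic output of the
era of the Maxent software this pipeline mirrors: a no-signal model scores
exactly 0.5 everywhere, and cells typical of presence conditions approach 1.
Prediction clamps covariates outside the training range to the boundary.

**Background.** 10,000 cells drawn uniformly without replacement from the
jointly valid cells, seeded; if the analysis area has fewer valid cells, all
of them are used with a warning (the synthetic fixture's 60×80 world has
≈4,400 valid cells, so desk-scale runs use the full area as background).

## Evaluation

* `partition_presences()` — seeded uniform 70/30 train/test split
  (`round(0.7 n)` training records).
* `auc_presence_background()` — rank-based (Mann-Whitney) AUC: the
  probability that a presence is scored above a random background cell, ties
  counting one half. 0.5 is chance; 1 is the maximum.
* `test_gain()` — mean over test presences of `log(q(x)·N)`.
* `percentile_threshold()` — the 10th percentile of training-presence
  scores, interpolating linearly between order statistics (the convention
  pinned down by the worked example `1..10 → 1.9`). The rationale: up to 10%
  of presence records may be positionally wrong, so the map is binarized
  just above the lowest-scoring 10% of training presences.
* `omission_rate()` — fraction of (test) presences *strictly below* the
  threshold, complementing the ≥ rule of `binary_map()`: a presence exactly
  at the threshold is predicted present. One subtlety is documented in the
  tests: with linear interpolation, training omission at the 10% threshold
  is bounded by 10% plus at most one record (exactly ≤ 10% whenever
  `(n−1)/10` is integral, as at the n = 200 used in the acceptance run).
  Both test-presence and training-presence omission are reported.
* `auc_significance()` — two-sided Wilcoxon rank-sum test of replicate test
  AUCs against matched null AUCs from label-permuted scores; the AUC
  standard deviation reported alongside comes from repeated seeded
  partitions (10 by default). The replicate scheme and the null
  construction are this package's documented choices.
* `covariation_screen()` — Pearson correlations over 10,000 random valid
  cells with |r| > 0.7 flagged. Flagged pairs are *reported, not dropped*:
  in practice strongly correlated pairs are sometimes both retained on the
  strength of their individual contributions, so an automatic rule would be
  wrong as often as right.
* `maxent_jackknife()` — per variable, the training gain without it and
  with only it, plus the single-variable model's test AUC.
* `niche_summary()` — per-variable presence-cell statistics with optional
  threshold-exceedance percentages (aragonite saturation > 1, depth
  < 1500 m, dissolved oxygen > 4 ml/l, and so on).

## Layer validation against bottle stations

`filter_stations()` keeps stations strictly deeper than 50 m (surface
bottles say nothing about seafloor layers); `intersect_layer()` pairs each
station with the layer cell containing it and reports Pearson r and r²;
`binned_profile()` aggregates pairs into 50 m depth, 5° latitude or 10°
longitude bins; `error_grid()` maps mean (layer − station) differences onto
a coarse grid. The difference sign is model minus observation. Stations are
matched to the seafloor layer by horizontal position only, which is the
comparison the up-scaling claims to support (the layer *is* a seafloor
representation); matching bottles at their sampled depth to the z-bin they
came from is a different, easier test and is not the default.

## The synthetic world

`simulate_world()` generates the package's standard study conditions, fixed
once as the desk-scale analogue of a real analysis:

* 60 × 80 bathymetry at 0.05° (a 3° × 4° mid-latitude window): western land
  margin, 200 m shelf, linear ramp to a 4000 m abyssal plain, six Gaussian
  seamounts (2500 m relief), 30 m depth noise.
* Three z-binned fields on a coarser 0.25° native grid (to exercise the
  interpolation/resampling path) at seven levels from 0 to 5000 m:
  temperature (18 °C surface-to-depth decay, e-folding 700 m, latitudinal
  gradient), salinity and dissolved oxygen with weaker structure, plus
  small per-cell noise.
* A planted Gaussian niche on temperature with optimum 8 °C and tolerance
  2 °C — the envelope typical of framework-forming cold-water corals —
  from which presences are drawn proportionally to suitability, without
  replacement (so one presence per cell holds by construction).
* Bottle stations at seeded random sea locations whose depth is the cell's
  seafloor depth and whose value is the native field value plus Gaussian
  measurement noise.

What the generator does *not* emulate: spatially autocorrelated sampling
bias, ocean circulation, fronts and upwelling, mixed substrate control, or
coastline geometry. Passing tests therefore demonstrate that the machinery
is correct and that planted signal of realistic shape is recovered; they do
not demonstrate that any real coral dataset would yield models of similar
quality.

Problem sizes throughout (60 × 80 grids, ≈4,400-cell backgrounds, 300
presences, 10 evaluation replicates) are the package's chosen desk scale:
large enough for the statistics to behave, small enough that the full test
suite and a complete pipeline run finish in minutes.

## Determinism and the pipeline

`run_all()` executes simulate → upscale → presences → fit → evaluate →
validate → map from a single `run_config()`, deriving every stage seed
deterministically from one global seed, and writes a manifest (seeds,
record counts per cleaning step, MD5 digests, timings). Re-running with the
same configuration is byte-identical on all CSV/JSON outputs. Configurations
can be loaded from YAML (`load_run_config()`). The package deliberately
ships no shell wrapper: the exported functions, `run_all()` and the
`scripts/acceptance.R` runner are the interface.

## Known limitations

* Everything is geographic WGS84; there is no reprojection and no dateline
  wrap-around handling, and grids are in-memory (no tiling), so true global
  30-arc-second extents are out of reach — the design targets regional
  windows and the synthetic fixture.
* GeoTIFF and NetCDF are not read or written; rasters travel as ESRI ASCII
  grids and z-binned fields as the manifest-plus-slices text format.
* IDW uses planar degree distances, adequate at regional extents but
  increasingly distorted towards the poles.
* The optimizer is plain coordinate descent; it satisfies the monotone-gain
  contract but makes no speed claims at feature counts far beyond the
  desk-scale defaults.
* Temporal variability is out of scope: all layers are annual-mean style,
  consistent with organisms whose lifespans dwarf oceanographic measuring
  periods.
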