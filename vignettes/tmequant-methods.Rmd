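---
title: "Quantifying immune-cell spatial organization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune-cell spatial organization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmequant)
```

## Scope and model

`tmequant` quantifies how immune cells are arranged relative to stromal
structures in tumor tissue, and how vascular volume and survival respond to
treatment. It implements four analyses that are usually re-coded ad hoc for
each study:

1. **Cell and structure segmentation** of single fluorescence channels
   (e.g. CD3 for T cells, alpha-SMA for perivascular/myofibroblast stroma)
   by intensity, size and morphology thresholds.
2. **Nearest-distance-to-structure statistics**: for each cell centroid, the
   Euclidean distance to the nearest structure-positive pixel, binned (by
   default at 20 µm) into stroma-adjacent versus stroma-distant fractions.
3. **Grid (quadrat) occupancy**: the fraction of fixed-size image tiles
   containing at least one cell — a simple, robust heterogeneity statistic.
   Populations that are excluded from parts of the tissue occupy fewer
   grids; populations free to infiltrate occupy more.
4. **Vessel volumetry** from 3D MR angiography by relative-threshold
   binarization and voxel counting, with maximum intensity projections.

Survival summaries (Kaplan–Meier curves, median survival, integer-percent
median increase, cure rate, log-rank with Holm-family adjustment) and two
closed-form cytometry/qPCR formulas (bead-corrected counts, ΔΔCt) round out
the reporting layer.

## Conventions that everything else relies on

* Images are `[row, col]` matrices, 1-based, **pixel centers at integer
  coordinates**; pixel `i` covers `[i − 0.5, i + 0.5)`. All distances are
  computed center-to-center in this geometry, then converted with
  `distance_um = distance_px / pixel_scale`. The default `pixel_scale` is
  1.98 px/µm, a common 10× widefield configuration.
* Intensities are never rescaled on load (constant-exposure convention);
  thresholds only mean something because all fields of a study share
  acquisition settings.
* Binarization uses strict inequality (`> threshold`) everywhere, so
  exactness tests behave predictably.
* A centroid whose containing pixel is structure-positive has distance
  exactly 0; cells inside the structure are recorded, not excluded.

## Segmentation

`estimate_threshold()` computes `mean + k·SD` (default `k = 3`) of a
channel on a secondary-antibody-only control section. This replaces
manual threshold review with a reproducible rule while remaining
overridable. `segment_cells()` then labels 8-connected components of the
thresholded channel and filters them by:

| parameter | default | meaning |
|---|---|---|
| `min_area_px`, `max_area_px` | 5, 500 px² | plausible cell footprint at ~2 px/µm |
| `min_solidity` | 0.7 | area / convex-hull-image area; rejects ragged debris |
| `max_eccentricity` | 0.99 | rejects fibers and fold artifacts |

Solidity uses the regionprops definition — component area divided by the
number of lattice points inside the convex hull of member pixel centers.
The geometric (polygon-area) variant is systematically harsher for small
blobs and would make the permissive 0.7 default reject genuine noisy cells.
Eccentricity comes from the central second moments of the member pixels.
Touching-cell splitting (watershed) is deliberately not performed: no
splitting rule is part of the procedure this package implements, and the
statistics downstream are robust to occasional merges.

Connected components are labeled with `EBImage::bwlabel` (4-connected)
followed by a union-find merge across diagonal label adjacencies, giving
exact 8-connectivity; a BFS flood-fill oracle in the test suite verifies
the equivalence on random masks.

## Distance statistic

`nearest_structure_distances()` must be exact, not approximate, because its
validation compares against exhaustive search at 10⁻⁹ µm. A Euclidean
distance transform (`EBImage::distmap`) of the structure mask gives, for
the pixel containing each centroid, an upper bound
`b = |centroid − pixel center| + dmap` on the true nearest-positive-pixel
distance; the true minimum is then taken over the positive pixels inside
the `±b` window (widened by 10⁻⁷ px so boundary pixels exactly at the
bound are kept). This is exact like the brute-force scan but near-linear in
practice.

Distance binning uses half-open bins `[e_i, e_{i+1})` with the last bin
closed above at infinity; the default edges `c(0, 20)` report the
stroma-adjacent (< 20 µm) and stroma-distant (≥ 20 µm) fractions. Fields
with no detected cells are flagged (`empty = TRUE`) and excluded from
distance summaries rather than contributing zeros; they still contribute a
density of 0.

`split_rich_poor()` partitions fields at the mean structure-area fraction;
ties go to "poor" so the rule is deterministic.

## Grid occupancy

Images are tiled into `grid_side_px × grid_side_px` squares (default 100
px ≈ 50 µm at 1.98 px/µm); partial squares at the right/bottom edges are
included so all tissue counts, and this is configurable for sensitivity
analysis. Three positivity criteria are provided because the combination
of centroid-presence and pixel-fraction tests can be composed either way:

* `centroid` (default): ≥ 1 cell centroid in the square;
* `pixel_fraction`: ≥ 50 % of the square's pixels structure-positive;
* `either`: union of the two.

The default follows the reading "count grids with cells present"; nothing
downstream assumes a particular mode.

## Vessel volumetry

`binarize_volume()` thresholds at `v_min + fraction·(v_max − v_min)` with
`fraction = 0.5` by default — the "50 % intensity threshold" convention of
interactive MRA tools, interpreted as 50 % of the per-volume min–max range.
Whether such thresholds should be relative to the range, the maximum, or a
reference tissue is genuinely underdetermined; the range convention is
invariant to affine intensity rescaling (gain/offset), which is the
property that matters for cross-volume comparability, and the threshold
actually used is recorded in the output. Optional percentile clipping
(off by default) guards against single-voxel outliers; no minimum
component size is imposed. `vessel_volume()` is exact voxel arithmetic:
`count × (voxel_size_um/1000)³` mm³, at the default 50 µm isotropic voxels
1.25 × 10⁻⁴ mm³ per voxel. Capillaries below voxel resolution are a
physical acquisition limit, not something the software can recover.

## Survival and reporting arithmetic

Kaplan–Meier estimation and the two-group log-rank test are delegated to
the `survival` package (`survfit`, `survdiff`); the package adds the
reporting conventions around them:

* median survival = smallest `t` with `S(t) ≤ 0.5`, undefined when the
  curve never reaches 0.5 (cured-majority groups);
* `percent_median_increase()` reports the gain rounded **up** to the next
  whole percent — the convention that reproduces published figures
  (a 36.36 % gain prints as 37 %, a 33.64 % gain as 34 %);
* `cure_rate()` rounds half-up (3 of 8 → 38 %);
* subjects alive at end of study are censored for the curve and counted as
  survivors for the cure rate;
* `holm_adjust()` implements the step-down Holm–Bonferroni and Holm–Šídák
  adjustments with monotonicity enforcement (the Bonferroni flavor is
  cross-checked against `p.adjust(method = "holm")` in the tests);
* `anova_oneway()` is the classical equal-variance F test via
  `oneway.test`, with the degenerate all-equal case defined as `F = 0`.

Tukey-type pairwise comparisons and Cox regression are out of scope.

## Synthetic data: what it emulates and what it does not

The generator exists so every stage can be validated against known ground
truth without animal imaging data. Its defaults define the simulated study
conditions and were chosen a priori:

* **Camera model**: 16-bit-like integer digital numbers, background offset
  100 DN, additive Gaussian read noise SD 20 DN. Integer output makes
  TIFF round-trips bit-exact. Poisson shot noise is not modeled.
* **Cells**: isotropic Gaussian blobs, σ = 2 px (≈ 1 µm nucleus-scale spot
  at 1.98 px/µm), default peak amplitude 200 DN (SNR 10; recovery is
  validated down to SNR 5). Centroids keep a hard-core separation of 4σ —
  cells are solid bodies and do not interpenetrate — and a 3σ + 1 border
  margin keeps blobs fully in-field.
* **Stroma**: ribbon-like chords of width 10 px crossing the full field,
  by default 14 on a 1024² field. Fourteen chords give a mean spacing
  (~73 px) comparable to the 2 × 20 µm exclusion diameter (~79 px), i.e.
  stroma-rich tissue in which exclusion genuinely fragments the admissible
  area. This density is what makes the excluded-vs-attracted contrast
  behave like its biological counterpart: with sparse stroma the excluded
  population still reaches nearly every grid and the occupancy contrast
  disappears.
* **Placement processes**: `uniform`; `excluded` (rejection sampling,
  distance ≥ 20 µm — the same boundary as the default distance bin);
  `attracted` (acceptance probability `exp(−d/10 µm)`). The exponential
  attraction kernel is a modeling choice, not an estimate from data.
* **Phantoms**: flat-ended cylinders (optionally capsule-capped); a voxel
  is tube-positive when its center is within the radius of the axis. The
  analytic volume πr²L is recorded alongside. The half-voxel overcount at
  each flat end is the standard voxelization bias and shrinks with tube
  length.
* **Cohorts**: exponential death times with a stated median, a cure
  fraction censored at the end of study (default day 100), and
  administrative censoring at that day.

What passing tests on these data do **not** show: robustness to uneven
illumination, optical blur and chromatic shift, autofluorescence texture,
touching-cell clusters, non-exponential hazards, or informative censoring.
The QC flags (`saturation`, `near_empty`, `illumination_gradient`) screen
for the first class of problems on real data but are advisory only.

## Numerical choices and degenerate inputs

* Binarization threshold ties: strict `>`, everywhere.
* Containing pixel of a continuous coordinate: `floor(x + 0.5)` —
  round-half-up, avoiding banker's rounding asymmetries.
* Constant control image: SD = 0, threshold = mean.
* Constant MRA volume: relative threshold undefined → error.
* Empty structure mask: distances undefined → error (not NA), because a
  field with no stroma cannot support the statistic.
* Empty cell set: empty `CellSet`, density 0, flagged distance result.
* Log-rank with zero events in both groups: undefined, returned as `NA`
  with a note rather than an error, so batch runs can proceed.
* The exclusion sampler checks feasibility on a 64 × 64 probe lattice and
  aborts with an explicit error when the exclusion radius leaves no
  admissible area.

## Problem sizes used in validation

The test suite validates the distance and grid statistics against
brute-force oracles on 100 random instances each (up to 128 × 128 px for
distances), segmentation recovery on 512² fields with 0–50 blobs at SNR 5,
the placement-regime contrast on twenty 1024² field pairs at n = 200
cells, phantom volumetry at radii 2–8 voxels, and the log-rank type-I
error on 2000 null replicates of 30 + 30 subjects. These sizes were chosen
so the full suite runs in about a minute and a half on one CPU while
keeping every Monte-Carlo check well-powered.

## Known limitations

* No watershed splitting: heavily confluent infiltrates will undercount
  cells and bias density (not the distance or occupancy statistics, which
  are per-object).
* The distance statistic measures centroid-to-mask distance, not
  membrane-to-membrane distance; at 1.98 px/µm the difference is ≈ a cell
  radius and constant across groups.
* Vessel volumetry has no partial-volume correction; accuracy degrades
  below ~3 voxel radii, as the phantom benchmark quantifies.
* The cure-rate summary is nonparametric; no mixture-cure model is fit.
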