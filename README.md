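# tmequant

Spatial quantification of tumor immune microenvironments.

Immunotherapy response depends not just on how many T cells reach a tumor
but on *where* they are: cells trapped in or excluded by stromal barriers
(alpha-SMA⁺ perivascular cells and myofibroblasts) cannot engage tumor
cells. `tmequant` packages the image-analysis and reporting procedures such
studies need, for researchers doing fluorescence immunohistochemistry of
tissue sections and small-animal MR angiography:

* **Segmentation** — cells and structure areas from single channels by
  intensity, size and morphology thresholds, with thresholds estimated
  reproducibly from no-primary-antibody control sections
  (`mean + k·SD`).
* **Distance-to-stroma** — for every cell centroid, the exact Euclidean
  distance to the nearest structure-positive pixel, in µm:
  `d_i = min_p ‖x_i − p‖ / s` (pixel scale `s` in px/µm), binned by
  default into `< 20 µm` vs `≥ 20 µm` fractions.
* **Grid occupancy** — the quadrat statistic for infiltration
  heterogeneity: tile the image into 100 px squares and count squares with
  at least one cell. Excluded populations occupy fewer grids.
* **Vessel volumetry** — binarize an MRA volume at 50 % of its intensity
  range, count voxels: `V = N · (h/1000)³ mm³` at voxel size `h` µm; plus
  maximum intensity projections.
* **Survival reporting** — Kaplan–Meier product-limit curves, median
  survival (smallest `t` with `S(t) ≤ 0.5`), integer-percent median
  increase and cure rate, two-group log-rank tests with Holm–Bonferroni
  (or Holm–Šídák) step-down adjustment, one-way ANOVA.
* **Closed-form quantification** — bead-corrected absolute counts
  (`viable × total beads / counted beads`), cells per gram, ΔΔCt relative
  expression (`2^−ΔΔCt`).
* **Synthetic ground truth** — a generator for two-channel fields
  (Gaussian-blob cells placed uniformly, stroma-excluded or
  stroma-attracted around ribbon-like structures), tubular vessel phantoms
  of known analytic volume, and censored exponential survival cohorts with
  cure fractions — so the whole pipeline is testable without imaging data.

See `vignettes/tmequant-methods.Rmd` for the model, parameter defaults and
design rationale.

## Worked example

```r
library(tmequant)

# simulate a stroma-rich field where T cells are excluded from stroma
g <- generate_field(field_spec(shape = c(1024, 1024), n_cells = 200,
                               placement = "excluded", seed = 11))

# thresholds from a matched no-primary control (background + noise only)
ctl <- generate_field(field_spec(shape = c(256, 256), n_cells = 0,
                                 ribbon_amplitude = 0, seed = 12))
thr   <- estimate_threshold(ctl$field, "CD3", k = 3)    # 159.9
thr_s <- estimate_threshold(ctl$field, "aSMA", k = 5)   # stricter: clean mask

cells  <- segment_cells(g$field, "CD3", segmentation_params(thr))
stroma <- segment_area(g$field, "aSMA", thr_s)
nearest_structure_distances(cells, stroma, pixel_scale = 1.98)
#> <distance_result> n = 199, mean = 49.736 um
#>   [0, 20) um: 0.101
#>   >= 20 um: 0.899
grid_occupancy(cells, grid_side_px = 100)
#> <grid_heterogeneity> 68 / 121 grids positive (0.562), side 100 px, mode 'centroid'
cell_density(cells, pixel_scale = 1.98)
#> [1] 744.04
```

199 of the 200 simulated cells are recovered; 89.9 % of them lie more than
20 µm from the nearest stroma-positive pixel (the generator excluded them
from a 20 µm zone around the stromal ribbons, measured from the ribbon
axis, so a tail just under 20 µm from the mask edge remains), and they
occupy 56 % of the 100-px grids — an attracted population at the same n
and seed occupies 63 %.

```r
# survival reporting with a cure fraction
co <- generate_cohort(cohort_spec(
  n_per_group = 12,
  groups = list(list(name = "control", median_days = 22, cure_fraction = 0),
                list(name = "combo",  median_days = 30, cure_fraction = 0.3)),
  end_of_study_day = 100, seed = 13))
km_estimate(co, "combo")
#> <survival_summary> group 'combo': n = 12, median = 43.69875 d, cure rate = 33%
logrank_test(co, "control", "combo")
#> $chi2 4.37 ... $p 0.036
percent_median_increase(30, 22)   # printed-medians arithmetic -> 37 (%)
cure_rate(3, 8)                   # -> 38 (%)

# vessel phantom: cylinder r = 200 um, L = 3.2 mm
ph <- generate_phantom(phantom_spec(
  shape = c(48, 48, 65),
  tubes = list(list(from = c(24, 24, 1), to = c(24, 24, 65), radius_um = 200))))
vessel_volume(binarize_volume(ph$volume, 0.5), 50)
#> <vessel_quant> 3185 voxels = 0.3981 mm^3 (threshold 50% of range = 50)
ph$analytic_volume_mm3
#> [1] 0.4021239   # voxel count within 1% of pi*r^2*L
```

A YAML-configurable end-to-end runner (`run_pipeline()`, with a thin
Rscript wrapper in `inst/scripts/run_pipeline.R`) chains
simulation/loading → segmentation → spatial metrics → optional
angiography/survival, writes per-stage CSV/JSON outputs and a
deterministic run report, and keeps field identifiers anonymized until the
reporting stage (blinded analysis).

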