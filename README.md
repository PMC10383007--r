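# conemosaic

Morphometry of the cone photoreceptor mosaic from adaptive-optics scanning
light ophthalmoscope (AOSLO) split-detection images, for researchers
quantifying photoreceptor structure in inherited retinal degenerations such
as choroideremia (CHM).

Given a region of interest (ROI) described by manually identified cone
centres (CSV) and a cone inner-segment segmentation (integer label mask,
PNG/TIFF), the package computes:

* **Bound Voronoi cone density** — number of Voronoi cells lying entirely
  inside the ROI divided by their summed area (cells/mm²), immune to edge
  cells distorted by unseen neighbours;
* **Per-cone area, perimeter, circularity** — area as pixel count,
  perimeter as border-pixel count, circularity `4πA/P²` (uncapped; small
  pixelated shapes exceed 1 by construction);
* **Percent intercone space** — `100 × (unoccupied pixels in the bound
  Voronoi region) / (bound-region pixels)`;
* **Regularity** — mean/SD of per-cone area and circularity;
* **Group statistics** — unbalanced two-way (group × eccentricity) ANOVA
  with type III sums of squares and sum-to-zero coding, implemented from
  explicit design matrices, plus Bonferroni-adjusted post hoc cell-mean
  contrasts (family m = 9);
* **Space-filling feasibility** — occupancy % = density × mean area × 10⁻⁴,
  used to test whether a hypothetical mosaic (e.g. normal density with
  CHM-sized cones) could physically exist;
* **Synthetic mosaics** — a generator producing jittered hexagonal cone
  lattices with lognormal inner-segment areas, harmonic boundary
  irregularity, dropout (localized cone loss) and full ground truth, plus
  cohort presets emulating control and CHM group statistics at 1°, 2° and
  4° temporal eccentricity.

## Worked example

```r
library(conemosaic)

# a synthetic CHM-like ROI at 1 degree temporal: 38,800 cells/mm2 target
# density, 20 um^2 mean inner-segment area, 8% dropout
roi    <- roi_spec(128, 128, eccentricity_deg = 1,
                   microns_per_pixel = microns_per_pixel(24))  # 0.5 um/px
params <- mosaic_params(38800, 20, dropout_frac = 0.08, seed = 11)
syn    <- generate_roi(params, roi)
roi_metrics(syn$centers, syn$mask)
#> <roi_metrics> density 35789 cells/mm2 | mean area 19.43 um2 | circ 1.324 |
#>   intercone 30.3% | 119 cones (104 bound)
```

The measured bound density (35,789 cells/mm²) recovers the post-dropout
target 38,800 × 0.92 ≈ 35,700 within sampling noise; the mean segmented
area recovers the 20 µm² draw; intercone space is emergent from the
density–area packing. Circularity is on the border-pixel-count scale, on
which even perfect digital discs of this size measure well above 1.

The space-filling check behind the "could the CHM phenotype be congenital?"
argument:

```r
space_filling_check(63000, 20.0)   # normal 1-deg density, CHM 1-deg area
#> occupancy 126.0%: not physically possible (overfilled by 26%)
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
reproduction; each is a thin script over package functions and writes small
tables under `results/` (bulky simulated images go to `scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R    # 12 control + 13 CHM subjects, 71 ROIs
Rscript analysis/02_roi_metrics.R        # measure every ROI from its files
Rscript analysis/03_group_statistics.R   # summary grid, ANOVA, post hoc
Rscript analysis/04_space_filling.R      # feasibility at 1, 2, 4 degrees
```

A single run prints, e.g., a density group effect of `F(1, 65) = 184.67,
p < 2e-16` and per-cell means such as control 1°: 62,491 cells/mm² / 11.9
µm² vs CHM 1°: 36,963 cells/mm² / 20.7 µm² — the CHM mosaic is sparser,
with enlarged inner segments and more intercone space at every
eccentricity, and the 71-observation design yields the error df of 65.

`run_pipeline()` exposes the same chain as one call (synthetic or
file-based input, per-ROI error records, deterministic outputs for a fixed
seed).

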