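---
title: "Quantifying the cone photoreceptor mosaic: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the cone photoreceptor mosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conemosaic)
```

## The measurement problem

Adaptive-optics scanning light ophthalmoscopy (AOSLO) resolves individual
cone photoreceptors in the living human eye. In its nonconfocal
split-detection mode the visible structure is the cone *inner segment*, so a
completed analysis of a region of interest (ROI) consists of two manual
products: a list of cone centre coordinates and a segmentation of each
inner-segment border. `conemosaic` takes those two products — a coordinate
table and an integer label mask — and computes the mosaic metrics used to
compare diseased (here, choroideremia — CHM) and healthy retinas:

* **bound Voronoi cone density** (cells/mm²),
* per-cone **inner-segment area** (µm²), **perimeter** and **circularity**,
* **percent intercone space** within the bound Voronoi region,
* **regularity** (mean/SD) of area and circularity per ROI,

followed by an unbalanced two-way ANOVA across disease group and
retinal eccentricity, Bonferroni post hoc contrasts, and a space-filling
feasibility check. A synthetic mosaic generator with known ground truth
stands in for human imaging data, so the full pipeline is testable offline.

## Spatial conventions

Pixels are on a 0-based grid with pixel centres at integer coordinates; an
ROI of width $W$ and height $H$ occupies the half-open rectangle
$[0, W) \times [0, H)$. The retinal scale is the first-order (Emsley-style)
linear convention: $291\ \mu m/\mathrm{deg}$ at a 24.0 mm axial length,
scaled proportionally, so
$\mu m/px = 291 \cdot (AL/24) \cdot \mathrm{FOV} / \mathrm{pixels}$.
The default sampling of 582 px across a 1° field (0.5 µm/px at 24 mm) is a
configuration choice, not a measurement; both the axial length and the
sampling are parameters of `microns_per_pixel()`.

## Bound Voronoi density

Density estimates from small ROIs are biased by cells whose shape depends on
unseen neighbours outside the crop. The *bound* construction removes them: a
Voronoi cell participates only if every polygon vertex lies strictly inside
the ROI rectangle. Density is then (number of bound cells) / (summed bound
polygon area). Cells are computed by half-plane clipping — each cell starts
as a large box and is clipped against perpendicular bisectors to neighbours
in order of increasing distance, stopping when no remaining neighbour can
cut the polygon. This is exact for the cells we keep, needs no external
geometry library, and is validated against analytic lattice densities
($1/s^2$ square, $2/(\sqrt{3}s^2)$ hexagonal) and an independent per-pixel
nearest-centre oracle.

The *bound region* used by the intercone metric is rasterized by assigning
every pixel to its nearest centre (ties to the lowest centre index) and
keeping pixels owned by bound cells. The same rule is its own cross-check:
rasterized cell pixel counts must agree with polygon areas to within a
half-perimeter discretization bound. Centres without a segmented cone (e.g.
cones cut off by the ROI border) still participate in the tessellation —
they shape their neighbours' cells correctly — but can never be bound.

## Per-cone shape metrics

Area is the raw pixel count of a label. The perimeter is the count of the
cone's *border pixels* — pixels with at least one 4-neighbour outside the
region (the image edge counts as outside). Circularity is
$4\pi A / P^2$ with both quantities in pixel counts, and is deliberately not
clamped: because a border-pixel count underestimates true boundary length at
small sizes, small compact shapes exceed 1 (a single pixel gives $4\pi$; a
3×3 square gives $36\pi/64 \approx 1.77$). Values are therefore comparable
*within* a fixed scale and shape regime, which is how they are used (groups
imaged at the same resolution). Regularity is mean/sample-SD (n−1); a
zero-SD input returns NaN with a warning rather than infinity.

Mean area and circularity are computed over **all** segmented cones in the
ROI, while density and intercone space use the bound Voronoi construct —
the metric definitions are independent and deliberately kept so. By
construction the package enforces the identity
(cone-pixel fraction of the bound region) + intercone/100 = 1; published
group tables do not always satisfy this identity (drawn cone borders can be
excluded from both numerator and denominator), so absolute intercone levels
from other workflows are not directly comparable.

## Unbalanced two-way ANOVA

`fit_two_way_anova()` fits the full group × eccentricity model with
interaction via explicit sum-to-zero design matrices and QR, and computes
**type III** sums of squares (each effect's SS is the rise in residual SS
when its columns are dropped). Type III with sum-to-zero coding is the de
facto meaning of "unbalanced two-way ANOVA" in mainstream statistical
software; on balanced data it provably coincides with the classical
decomposition, which the tests assert exactly, and on unbalanced data it is
cross-checked against an independent implementation (`car::Anova`). With 2×3
cells the effect dfs are 1, 2 and 2 and the error df is $n-6$; a 71-ROI
cohort (25 subjects × 3 eccentricities − 4 missing) gives error df 65. Any
empty cell makes the interaction inestimable and is reported as an error
naming the cell.

Post hoc testing uses the nine natural cell-mean contrasts (3 eccentricity
pairs within each group + the group contrast at each eccentricity), each a
two-sample t on the pooled error mean square, Bonferroni-adjusted with
family size m = 9 — the most conservative natural family, since the
original family is typically unstated in the field.

## Space-filling feasibility

Occupancy is density × mean area × 10⁻⁴ (cells/mm² × µm² → %). Combining
*normal* density with *CHM-sized* cones asks whether the diseased phenotype
could be congenital: at 1° temporal, 63,000 cells/mm² × 20.0 µm² = 126%
— overfilled by 26%, physically impossible — so enlarged cones and reduced
density must arise together during degeneration. `space_filling_check()`
reports occupancy plus either the overfill or the remaining intercone
headroom and leaves interpretation to the user.

## The synthetic generator: what it emulates and what it does not

`generate_centers()` places cones on a hexagonal lattice at the spacing
implied by the target density (with a seeded random phase), jitters each
site with Gaussian noise (default SD 0.15 × spacing, typical of parafoveal
mosaics), and thins sites independently with probability `dropout_frac` to
emulate localized cone loss; realized density is target × (1 − dropout).
`render_cones()` draws each inner segment as a radial blob whose boundary
carries order 2–5 harmonic irregularity with seeded amplitudes and phases.
Rendering is *rank-based*: the cone takes the m pixels of its own Voronoi
domain with smallest shape-weighted radius, where m is a lognormal area
draw (truncated to 4–80 µm²), so per-cone pixel area equals the draw
exactly unless the Voronoi cell itself is smaller. A per-ROI packing
compensation factor (solved by root-finding) offsets the truncation that
dense mosaics impose, keeping the realized mean area unbiased. Cones whose
pixels would touch the ROI border are omitted from the mask — mirroring the
convention that cut-off cones are not segmented — while their centres still
act as Voronoi neighbours.

`generate_cohort()` draws subject-level density and mean area per cell from
preset means ± SDs (truncated normal at ±3 SD and physical bounds). The
area draw is taken *conditionally* on the density draw with correlation
−0.6: mosaics that have lost cones carry enlarged inner segments, which is
the central phenotype being modelled, and without this coupling the preset
cells whose joint tail exceeds 100% occupancy would be unrealizable. The
construction preserves both preset marginals; draws that would still
overfill saturate at 95% occupancy. Axial lengths are drawn per subject
(24.2 ± 1.0 mm, truncated) so the pixel scale varies realistically across
the cohort. Four CHM subjects (seeded choice) lack the 4° ROI, reproducing
the 71-ROI unbalanced design; the count is exact rather than Bernoulli so
the error-df geometry of the emulated study is reproduced deterministically.
A single run seed expands into per-ROI child seeds through a documented
multiplicative-congruential rule, so any ROI can be regenerated in
isolation.

Defaults the presets do not pin down, chosen once as field-realistic
values: within-ROI area CV 0.25, shape irregularity 0.2, CHM dropout 0.08
(controls 0), ROI side 128 px (64 µm at the default scale — within the
50–100 µm range typical for parafoveal density analysis and large enough
for tens to hundreds of bound cells per ROI).

**What passing tests do and do not show.** The generator produces
irregularly shaped, correctly packed, non-overlapping inner segments with
known density, area and dropout — it does not model optical blur, detector
noise, montage distortion, rods intruding at higher eccentricity, or
segmentation error. Intercone space is *emergent* (≈ 100 − occupancy over
the bound region), not set to published group values: published density ×
area × intercone triples are mutually inconsistent under the pixel
identity above, so the generator prioritizes density and area and lets
intercone follow. Consequently, circularity and intercone levels validate
the *measurement machinery*, not agreement with any published absolute
value.

## Numerical choices and degenerate inputs

* Voronoi boundedness uses strict interior comparisons; vertices on the ROI
  boundary mark a cell unbound. Rasterization ties go to the lowest centre
  index, which also makes pixel partitions deterministic.
* Tessellation requires ≥ 4 non-collinear centres (collinearity via SVD
  rank); fewer, or zero bound cells, raise informative errors.
* ANOVA sums of squares below 10⁻¹⁸ × ΣY² are floored to exact zeros; a
  zero residual variance warns and reports undefined F.
* Masks are stored as 16-bit grayscale TIFF (lossless up to 65,535 labels);
  8/16-bit PNG is accepted on input. Labels are always canonicalized to
  1..K in row-major first-appearance order, making write→read the identity.
* Centre files are validated with half-open bounds and a 0.5 px minimum
  separation; violations are reported by row number.

## Problem sizes used in the shipped experiments

The statistical calibration experiments run at the metric level (drawing
per-subject metric values from the presets — 200 replicates for power, 500
for the type I error of the group test), because they are properties of the
ANOVA machinery; image-level simulation would add cost but no information.
Full image-level parameter recovery uses three 71-ROI cohorts (128×128 px
per ROI, 36–39 ROIs per preset cell after pooling). These sizes
give standard errors small enough for the 2-SE recovery checks while
keeping a complete run in tens of seconds on one core.

## Known limitations

* Circularity is on the border-pixel-count scale: comparable across groups
  at a fixed image scale, but not to continuous-boundary circularity.
* The ANOVA treats one ROI per subject per eccentricity as the unit; no
  mixed-effects or eye-level clustering (one eye per subject is assumed).
* The generator's dropout is spatially independent (Bernoulli per site);
  real degeneration shows spatially correlated patches.
* Bound-density variance grows for ROIs with < ~30 bound cells; the
  default ROI size keeps well above this except at the lowest densities.

## A worked example

```{r example, eval = FALSE}
library(conemosaic)

roi <- roi_spec(128, 128, eccentricity_deg = 1,
                microns_per_pixel = microns_per_pixel(24))
params <- mosaic_params(38800, 20, dropout_frac = 0.08, seed = 7)
syn <- generate_roi(params, roi)
roi_metrics(syn$centers, syn$mask)

# full cohort + statistics
cohort <- generate_cohort(seed = 1)
run_pipeline(run_config(synthetic = list(), out_dir = "run1", seed = 1))
```
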