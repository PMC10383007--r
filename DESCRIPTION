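Package: conemosaic
Title: Cone Photoreceptor Mosaic Morphometry from Adaptive-Optics Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantification of the cone photoreceptor mosaic from
    adaptive-optics scanning light ophthalmoscope (AOSLO) region-of-interest
    data: bound Voronoi cone density, per-cone inner-segment area, perimeter
    and circularity from segmentation label masks, percent intercone space
    over the bound Voronoi region, and regularity (inverse coefficient of
    variation) metrics. Includes an unbalanced two-way (group x eccentricity)
    ANOVA with type III sums of squares and Bonferroni post hoc contrasts, a
    space-filling feasibility check, and a synthetic mosaic generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
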