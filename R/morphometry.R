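#' Per-cone area in pixels
#'
#' Area of one cone's inner segment, by counting the pixels carrying its
#' label.
#'
#' @param mask A [cone_mask()].
#' @param label Integer label present in the mask.
#' @return Pixel count (integer).
#' @export
cone_area <- function(mask, label) {
  stopifnot(inherits(mask, "cone_mask"))
  label <- as.integer(label)
  a <- sum(mask$labels == label)
  if (a == 0L) stop("label ", label, " absent from mask")
  a
}

#' Per-cone perimeter in border pixels
#'
#' Counts the pixels of a cone that touch the outside: a pixel is a border
#' pixel if at least one of its 4-neighbours lies outside the cone's region
#' (a different label, background, or past the image edge). This is a
#' border-*pixel* count, not an edge-length estimate, so circularity values
#' computed from it are on a pixelated scale and may exceed 1 for very
#' small cones.
#'
#' @inheritParams cone_area
#' @return Border pixel count (integer).
#' @export
cone_perimeter <- function(mask, label) {
  stopifnot(inherits(mask, "cone_mask"))
  label <- as.integer(label)
  if (!any(mask$labels == label)) stop("label ", label, " absent from mask")
  border <- border_pixels(mask$labels)
  sum(border & mask$labels == label)
}

# logical matrix: label pixels with >= 1 four-neighbour outside their region
# (image edge counts as outside)
border_pixels <- function(L) {
  h <- nrow(L); w <- ncol(L)
  pad <- matrix(-1L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- L
  ctr <- pad[2:(h + 1L), 2:(w + 1L)]
  up    <- pad[1:h,         2:(w + 1L)]
  down  <- pad[3:(h + 2L),  2:(w + 1L)]
  left  <- pad[2:(h + 1L),  1:w]
  right <- pad[2:(h + 1L),  3:(w + 2L)]
  ctr > 0L & (up != ctr | down != ctr | left != ctr | right != ctr)
}

#' Circularity of a pixelated region
#'
#' `4 * pi * area / perimeter^2` with area and perimeter in pixel counts.
#' Not clamped: small pixelated shapes can exceed 1 (a single pixel gives
#' 4*pi) because the border-pixel perimeter underestimates the continuous
#' boundary length at small sizes.
#'
#' @param area_px Pixel area (>= 1).
#' @param perimeter_px Border pixel count (>= 1).
#' @return Dimensionless circularity.
#' @export
circularity <- function(area_px, perimeter_px) {
  stopifnot(all(area_px >= 1), all(perimeter_px >= 1))
  4 * pi * area_px / perimeter_px^2
}

#' Per-cone shape metrics table
#'
#' Area, perimeter and circularity for every cone in a mask, in one pass.
#'
#' @param mask A [cone_mask()].
#' @return Data frame: `label`, `area_px`, `area_um2`, `perimeter_px`,
#'   `circularity`.
#' @export
cone_shape_table <- function(mask) {
  stopifnot(inherits(mask, "cone_mask"))
  K <- mask$n_cones
  if (K == 0L) stop("empty mask: no cones segmented")
  L <- mask$labels
  area_px <- tabulate(L[L > 0L], nbins = K)
  border <- border_pixels(L)
  perim_px <- tabulate(L[border], nbins = K)
  upp <- mask$roi$microns_per_pixel
  data.frame(label = seq_len(K),
             area_px = area_px,
             area_um2 = area_px * upp^2,
             perimeter_px = perim_px,
             circularity = circularity(area_px, perim_px))
}

#' Percent intercone space
#'
#' Percentage of pixels within the bound Voronoi region that are not
#' occupied by any segmented cone: `100 * (# region pixels with label 0) /
#' (# region pixels)`.
#'
#' @param mask A [cone_mask()].
#' @param region A [bound_region()] over the same ROI grid.
#' @return Percentage in `[0, 100]`.
#' @export
intercone_space <- function(mask, region) {
  stopifnot(inherits(mask, "cone_mask"), inherits(region, "bound_region"))
  if (!all(dim(region$pixel_mask) == dim(mask$labels))) {
    stop("mask and bound region have different dimensions")
  }
  if (region$total_px < 1L) stop("empty bound region")
  100 * sum(region$pixel_mask & mask$labels == 0L) / region$total_px
}

#' Regularity (inverse coefficient of variation)
#'
#' Mean of a per-cone measurement divided by its sample standard deviation
#' (n - 1 denominator). Undefined (NaN, with a warning) when the SD is zero.
#'
#' @param values Numeric vector, length >= 2.
#' @return `mean(values) / sd(values)`.
#' @export
regularity <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("regularity needs at least 2 values")
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero standard deviation: regularity undefined")
    return(NaN)
  }
  mean(values) / s
}

#' All mosaic metrics for one ROI
#'
#' Assembles the full metric set for a region of interest: bound cone
#' density (over the bound Voronoi cells), mean cone area and circularity
#' (over *all* segmented cones, boundedness is not a filter for per-cone
#' shape), percent intercone space (over the bound Voronoi region), and the
#' area / circularity regularities.
#'
#' @param centers A [cone_centers()].
#' @param mask A [cone_mask()] on the same ROI grid.
#' @return A list of class `roi_metrics`: `bound_density_cells_mm2`,
#'   `mean_area_um2`, `mean_circularity`, `intercone_pct`,
#'   `area_regularity`, `circularity_regularity`, `n_cones_segmented`,
#'   `n_cones_bound`, plus the per-cone table as attribute `"cones"`.
#' @export
roi_metrics <- function(centers, mask) {
  stopifnot(inherits(centers, "cone_centers"), inherits(mask, "cone_mask"))
  if (centers$roi$width_px != mask$roi$width_px ||
      centers$roi$height_px != mask$roi$height_px) {
    stop("centers and mask refer to different ROI dimensions")
  }
  shapes <- cone_shape_table(mask)
  tess <- tessellate(centers)
  region <- bound_region(tess)
  out <- structure(list(
    bound_density_cells_mm2 = bound_density(tess),
    mean_area_um2 = mean(shapes$area_um2),
    mean_circularity = mean(shapes$circularity),
    intercone_pct = intercone_space(mask, region),
    area_regularity = regularity(shapes$area_px),
    circularity_regularity = regularity(shapes$circularity),
    n_cones_segmented = mask$n_cones,
    n_cones_bound = length(region$member_indices)
  ), class = "roi_metrics")
  attr(out, "cones") <- shapes
  out
}

#' @export
print.roi_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<roi_metrics> density %.0f cells/mm2 | mean area %.2f um2 | ",
    "circ %.3f | intercone %.1f%% | %d cones (%d bound)\n"),
    x$bound_density_cells_mm2, x$mean_area_um2, x$mean_circularity,
    x$intercone_pct, x$n_cones_segmented, x$n_cones_bound))
  invisible(x)
}

#' @export
as.data.frame.roi_metrics <- function(x, ...) {
  data.frame(bound_density_cells_mm2 = x$bound_density_cells_mm2,
             mean_area_um2 = x$mean_area_um2,
             mean_circularity = x$mean_circularity,
             intercone_pct = x$intercone_pct,
             area_regularity = x$area_regularity,
             circularity_regularity = x$circularity_regularity,
             n_cones_segmented = x$n_cones_segmented,
             n_cones_bound = x$n_cones_bound)
}
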