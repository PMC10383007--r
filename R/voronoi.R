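#' Voronoi tessellation of cone centres
#'
#' Computes the Voronoi cell of every cone centre by iterative half-plane
#' clipping: each cell starts as a large bounding box and is clipped against
#' the perpendicular bisector to neighbouring centres in order of increasing
#' distance, stopping once no remaining neighbour can cut the cell (a
#' neighbour at distance d cuts only if d/2 is less than the farthest cell
#' vertex). A cell is *bound* iff every vertex lies strictly inside the ROI
#' rectangle, so its geometry cannot be influenced by unseen cones beyond
#' the ROI; cells reaching the ROI edge or the bounding box are unbound.
#'
#' @param centers A [cone_centers()] with at least 4 non-collinear points.
#' @return A list of class `voronoi_cells`: per cell `center_index`,
#'   `vertices` (two-column matrix, px), `is_bound`, `area_px2` (shoelace
#'   polygon area; NA for cells truncated by the bounding box).
#' @export
tessellate <- function(centers) {
  stopifnot(inherits(centers, "cone_centers"))
  x <- centers$x; y <- centers$y
  n <- length(x)
  if (n < 4L) stop("degenerate configuration: need at least 4 centres")
  if (collinear(x, y)) stop("degenerate configuration: centres are collinear")
  W <- centers$roi$width_px; H <- centers$roi$height_px
  M <- W + H  # bounding-box margin, generous
  box <- cbind(c(-M, W + M, W + M, -M), c(-M, -M, H + M, H + M))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    poly <- box
    maxd2 <- max((poly[, 1] - x[i])^2 + (poly[, 2] - y[i])^2)
    for (j in ord) {
      if (d2[j] >= 4 * maxd2) break
      poly <- clip_halfplane(poly, x[i], y[i], x[j], y[j])
      if (nrow(poly) < 3L) break
      maxd2 <- max((poly[, 1] - x[i])^2 + (poly[, 2] - y[i])^2)
    }
    eps <- 1e-9
    bound <- nrow(poly) >= 3L &&
      all(poly[, 1] > eps & poly[, 1] < W - eps &
            poly[, 2] > eps & poly[, 2] < H - eps) &&
      # also require strictly off the construction box (unbounded direction)
      all(abs(poly[, 1] + M) > 1e-6 & abs(poly[, 1] - (W + M)) > 1e-6 &
            abs(poly[, 2] + M) > 1e-6 & abs(poly[, 2] - (H + M)) > 1e-6)
    cells[[i]] <- list(center_index = i, vertices = poly,
                       is_bound = bound,
                       area_px2 = if (nrow(poly) >= 3L) shoelace(poly) else NA_real_)
  }
  structure(list(cells = cells, roi = centers$roi, centers = centers),
            class = "voronoi_cells")
}

#' @export
print.voronoi_cells <- function(x, ...) {
  nb <- sum(vapply(x$cells, `[[`, logical(1), "is_bound"))
  cat(sprintf("<voronoi_cells> %d cells (%d bound)\n", length(x$cells), nb))
  invisible(x)
}

collinear <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  s <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  s[2] < 1e-9 * max(s[1], 1)
}

# Sutherland-Hodgman clip of convex polygon `poly` to the half-plane of
# points closer to (xi, yi) than to (xj, yj).
clip_halfplane <- function(poly, xi, yi, xj, yj) {
  nx <- xj - xi; ny <- yj - yi
  mx <- (xi + xj) / 2; my <- (yi + yj) / 2
  # signed "distance": negative inside (closer to i)
  s <- (poly[, 1] - mx) * nx + (poly[, 2] - my) * ny
  nv <- nrow(poly)
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (k in seq_len(nv)) {
    k2 <- if (k == nv) 1L else k + 1L
    in1 <- s[k] <= 0; in2 <- s[k2] <= 0
    if (in1) {
      keep_x <- c(keep_x, poly[k, 1]); keep_y <- c(keep_y, poly[k, 2])
    }
    if (xor(in1, in2)) {
      t <- s[k] / (s[k] - s[k2])
      keep_x <- c(keep_x, poly[k, 1] + t * (poly[k2, 1] - poly[k, 1]))
      keep_y <- c(keep_y, poly[k, 2] + t * (poly[k2, 2] - poly[k, 2]))
    }
  }
  cbind(keep_x, keep_y, deparse.level = 0)
}

shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

bound_flags <- function(tess) {
  vapply(tess$cells, `[[`, logical(1), "is_bound")
}

#' Bound cone density
#'
#' Number of bound Voronoi cells divided by their summed polygon area,
#' expressed in cells/mm^2. Only cells lying entirely inside the ROI count,
#' so the estimate is unaffected by cones beyond the ROI border.
#'
#' @param centers A [cone_centers()], or a precomputed [tessellate()] result.
#' @return Density in cells per mm^2.
#' @export
bound_density <- function(centers) {
  tess <- if (inherits(centers, "voronoi_cells")) centers else tessellate(centers)
  b <- bound_flags(tess)
  if (!any(b)) stop("no bound cells; enlarge ROI")
  areas_px2 <- vapply(tess$cells[b], `[[`, numeric(1), "area_px2")
  area_mm2 <- sum(areas_px2) * (tess$roi$microns_per_pixel * 1e-3)^2
  sum(b) / area_mm2
}

# Nearest-centre index for every pixel of the ROI grid (pixel centres at
# integer coordinates), ties to the lowest centre index. Chunked to bound
# memory. Returns an integer matrix [height, width].
nearest_center_index <- function(centers) {
  W <- centers$roi$width_px; H <- centers$roi$height_px
  x <- centers$x; y <- centers$y
  n <- length(x)
  px <- rep(0:(W - 1L), each = H)   # column-major over [H, W] grid
  py <- rep(0:(H - 1L), times = W)
  npix <- W * H
  out <- integer(npix)
  chunk <- max(1L, floor(4e6 / n))
  for (start in seq(1L, npix, by = chunk)) {
    idx <- start:min(npix, start + chunk - 1L)
    d2 <- outer(px[idx], x, `-`)^2 + outer(py[idx], y, `-`)^2
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  matrix(out, nrow = H, ncol = W)
}

#' Bound Voronoi region
#'
#' Rasterizes the union of bound Voronoi cells: each ROI pixel is assigned
#' to the cell whose centre is nearest (ties broken to the lowest centre
#' index) and belongs to the bound region iff that cell is bound. This
#' pixel set is the denominator of the percent-intercone-space metric.
#'
#' @param centers A [cone_centers()], or a precomputed [tessellate()] result.
#' @return A list of class `bound_region`: `pixel_mask` (logical matrix
#'   [height, width]), `total_px`, `member_indices` (bound cone indices),
#'   and `owner` (integer matrix of nearest-centre indices).
#' @export
bound_region <- function(centers) {
  tess <- if (inherits(centers, "voronoi_cells")) centers else tessellate(centers)
  b <- bound_flags(tess)
  if (!any(b)) stop("no bound cells; enlarge ROI")
  owner <- nearest_center_index(tess$centers)
  mask <- matrix(b[owner], nrow(owner), ncol(owner))
  structure(list(pixel_mask = mask, total_px = sum(mask),
                 member_indices = which(b), owner = owner),
            class = "bound_region")
}

#' @export
print.bound_region <- function(x, ...) {
  cat(sprintf("<bound_region> %d px over %d bound cells\n",
              x$total_px, length(x$member_indices)))
  invisible(x)
}
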