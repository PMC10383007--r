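#' Parameters of a synthetic cone mosaic
#'
#' Ground-truth parameters for one simulated ROI. Cones sit on a hexagonal
#' lattice whose spacing matches the target density, perturbed by Gaussian
#' positional jitter and thinned by random dropout (emulating localized
#' cone loss); inner segments are rendered as radial blobs with a lognormal
#' area distribution and low-order harmonic boundary irregularity.
#'
#' @param target_density_cells_mm2 Post-dropout cone density, cells/mm^2.
#' @param mean_area_um2 Mean inner-segment area, um^2.
#' @param density_sd Between-subject density SD (used at cohort level).
#' @param area_cv Within-ROI coefficient of variation of cone area.
#' @param shape_irregularity Boundary irregularity in `[0, 1]`: relative
#'   amplitude of the order 2-5 harmonic perturbation of the blob radius
#'   (0 = perfect discs).
#' @param coverage_jitter SD of a per-ROI lognormal factor applied to all
#'   cone areas (extra ROI-level coverage variability; 0 = none).
#' @param lattice_jitter_frac Positional jitter SD as a fraction of the
#'   lattice spacing, in `[0, 0.5]`.
#' @param dropout_frac Probability that a lattice site is removed, `[0, 1)`;
#'   the realized density is `target * (1 - dropout)` in expectation.
#' @param seed Integer seed; all randomness is derived from it.
#' @return A `mosaic_params` list.
#' @export
mosaic_params <- function(target_density_cells_mm2, mean_area_um2,
                          density_sd = 0, area_cv = 0.25,
                          shape_irregularity = 0.2, coverage_jitter = 0,
                          lattice_jitter_frac = 0.15, dropout_frac = 0,
                          seed = 1L) {
  stopifnot(target_density_cells_mm2 > 0, mean_area_um2 > 0,
            density_sd >= 0, area_cv >= 0, coverage_jitter >= 0,
            shape_irregularity >= 0, shape_irregularity <= 1,
            lattice_jitter_frac >= 0, lattice_jitter_frac <= 0.5,
            dropout_frac >= 0, dropout_frac < 1)
  occ <- target_density_cells_mm2 * mean_area_um2 * 1e-4
  if (occ > 95) {
    stop("implied occupancy ", round(occ, 1),
         "% exceeds 95%: such a mosaic cannot be packed")
  }
  structure(list(target_density_cells_mm2 = target_density_cells_mm2,
                 mean_area_um2 = mean_area_um2, density_sd = density_sd,
                 area_cv = area_cv, shape_irregularity = shape_irregularity,
                 coverage_jitter = coverage_jitter,
                 lattice_jitter_frac = lattice_jitter_frac,
                 dropout_frac = dropout_frac, seed = as.integer(seed)),
            class = "mosaic_params")
}

# run code with a temporary RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a child seed
#'
#' Deterministic seed-splitting rule (multiplicative congruential step,
#' modulus 2^31 - 1) so that every subject / ROI is regenerable in
#' isolation from the run seed and its index.
#'
#' @param seed Parent integer seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer(1 + ((s * 48271 + 13 * as.numeric(index) + 1) %% 2147483645))
}

#' Generate jittered hexagonal cone centres
#'
#' Lays a hexagonal lattice at the spacing implied by the target density,
#' applies Gaussian positional jitter, removes sites independently with the
#' dropout probability (localized cone loss), and keeps points inside the
#' half-open ROI bounds. Deterministic for a fixed seed.
#'
#' @param params A [mosaic_params()].
#' @param roi An [roi_spec()]; must accommodate at least 9 lattice sites.
#' @return A [cone_centers()].
#' @export
generate_centers <- function(params, roi) {
  stopifnot(inherits(params, "mosaic_params"), inherits(roi, "roi_spec"))
  d_um2 <- params$target_density_cells_mm2 * 1e-6   # cells per um^2
  s_um <- sqrt(2 / (sqrt(3) * d_um2))          # hex lattice spacing
  s_px <- s_um / roi$microns_per_pixel
  if (s_px < 2) stop("scale too coarse: lattice spacing ", round(s_px, 2),
                     " px < 2 px at this density and pixel size")
  W <- roi$width_px; H <- roi$height_px
  dy <- s_px * sqrt(3) / 2
  n_rows_fit <- floor(H / dy)
  n_cols_fit <- floor(W / s_px)
  if (n_rows_fit * n_cols_fit < 9L) {
    stop("ROI too small for 9 lattice sites at this spacing")
  }
  with_seed(params$seed, {
    ox <- stats::runif(1, 0, s_px)
    oy <- stats::runif(1, 0, dy)
    rows <- seq(-1, ceiling(H / dy) + 1)
    pts <- do.call(rbind, lapply(rows, function(j) {
      xs <- seq(-1, ceiling(W / s_px) + 1) * s_px + ox +
        (j %% 2) * s_px / 2
      cbind(xs, j * dy + oy)
    }))
    jit <- params$lattice_jitter_frac * s_px
    if (jit > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, jit), nrow(pts), 2)
    }
    if (params$dropout_frac > 0) {
      pts <- pts[stats::runif(nrow(pts)) >= params$dropout_frac, , drop = FALSE]
    }
    inside <- pts[, 1] >= 0 & pts[, 1] < W & pts[, 2] >= 0 & pts[, 2] < H
    pts <- pts[inside, , drop = FALSE]
    drop <- close_pairs(pts[, 1], pts[, 2], 0.5)
    if (length(drop)) pts <- pts[-drop, , drop = FALSE]
    cone_centers(roi, pts[, 1], pts[, 2])
  })
}

#' Render cone inner segments as a label mask
#'
#' Draws each cone as a radial blob around its centre with boundary shape
#' `r(theta) proportional to 1 + irregularity * sum of order 2-5 harmonics`
#' (seeded random amplitudes and phases) and pixel area equal to a
#' lognormal draw (mean `mean_area_um2`, CV `area_cv`, truncated to
#' 4-80 um^2). Rendering is by rank: within the cone's own Voronoi domain,
#' the target number of pixels with the smallest shape-weighted radius
#' `r / r(theta)` is taken, so the per-cone pixel count matches the draw
#' exactly unless the Voronoi cell itself is smaller (dense mosaics), in
#' which case the cone fills its cell. Regions therefore never overlap;
#' each is reduced to the 4-connected component containing its centre.
#' Cones whose pixels would touch the image border are excluded from the
#' mask entirely (they would be cut off by the ROI), mirroring the
#' segmentation protocol; their centres remain available as Voronoi
#' neighbours.
#'
#' @param centers A [cone_centers()].
#' @param params A [mosaic_params()].
#' @return A list: `mask` (a [cone_mask()]), `label_of_center` (integer
#'   vector, NA for unsegmented cones), `target_area_um2` (per-cone area
#'   draws).
#' @export
render_cones <- function(centers, params) {
  stopifnot(inherits(centers, "cone_centers"), inherits(params, "mosaic_params"))
  roi <- centers$roi
  W <- roi$width_px; H <- roi$height_px
  upp <- roi$microns_per_pixel
  n <- length(centers$x)
  owner <- nearest_center_index(centers)
  with_seed(child_seed(params$seed, 1L), {
    cv <- params$area_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(params$mean_area_um2) - sdlog^2 / 2
      lo <- stats::plnorm(4, meanlog, sdlog)
      hi <- stats::plnorm(80, meanlog, sdlog)
      areas <- stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
    } else {
      areas <- rep(params$mean_area_um2, n)
    }
    if (params$coverage_jitter > 0) {
      areas <- areas * exp(stats::rnorm(1, 0, params$coverage_jitter))
    }
    irr <- params$shape_irregularity
    harmonics <- 2:5
    amp <- matrix(stats::runif(n * length(harmonics)), n)
    amp <- amp / pmax(rowSums(amp), 1e-12)
    phase <- matrix(stats::runif(n * length(harmonics), 0, 2 * pi), n)
    target_px <- pmax(1L, as.integer(round(areas / upp^2)))
    # packing compensation: in dense mosaics some draws exceed their Voronoi
    # cell's capacity and are truncated; scale all draws by a common factor c
    # so the expected realized mean matches the drawn mean
    cap <- tabulate(owner, nbins = n)
    live <- cap > 0L
    if (any(live)) {
      tgt <- mean(target_px[live])
      f <- function(c) mean(pmin(c * target_px[live], cap[live])) - tgt
      if (f(1) < 0 && f(3) > 0) {
        cfac <- stats::uniroot(f, c(1, 3), tol = 1e-4)$root
        target_px <- pmax(1L, as.integer(round(cfac * target_px)))
      } else if (f(3) <= 0) {
        target_px <- pmax(1L, as.integer(round(3 * target_px)))
      }
    }
    labels <- matrix(0L, H, W)
    for (k in seq_len(n)) {
      own <- which(owner == k)
      if (!length(own)) next
      pyx <- arrayInd(own, dim(owner))
      dx <- (pyx[, 2] - 1) - centers$x[k]
      dy <- (pyx[, 1] - 1) - centers$y[k]
      r <- sqrt(dx^2 + dy^2)
      shape <- rep(1, length(r))
      if (irr > 0) {
        theta <- atan2(dy, dx)
        pert <- rep(0, length(theta))
        for (h in seq_along(harmonics)) {
          pert <- pert + amp[k, h] * cos(harmonics[h] * theta + phase[k, h])
        }
        shape <- 1 + irr * pert
      }
      q <- r / shape                      # shape-weighted radius
      m <- min(target_px[k], length(own))
      labels[own[order(q)[seq_len(m)]]] <- k
    }
    # drop cones reaching the image border (cut off by the ROI)
    edge_labels <- unique(c(labels[1, ], labels[H, ], labels[, 1], labels[, W]))
    edge_labels <- edge_labels[edge_labels > 0L]
    if (length(edge_labels)) labels[labels %in% edge_labels] <- 0L
    # keep only the 4-connected component containing each centre
    for (k in setdiff(unique(labels[labels > 0L]), 0L)) {
      labels <- keep_center_component(labels, k,
                                      round(centers$x[k]), round(centers$y[k]))
    }
    surviving <- sort(unique(labels[labels > 0L]))
    lut <- rowmajor_lut(labels)
    relab <- labels
    relab[relab > 0L] <- lut[relab[relab > 0L]]
    label_of_center <- rep(NA_integer_, n)
    label_of_center[surviving] <- lut[surviving]
    list(mask = cone_mask(roi, relab),
         label_of_center = label_of_center,
         target_area_um2 = areas)
  })
}

# first-appearance (row-major) relabelling lookup table
rowmajor_lut <- function(labels) {
  v <- as.vector(t(labels))
  nz <- v[v > 0L]
  if (!length(nz)) return(integer())
  first <- nz[!duplicated(nz)]
  lut <- integer(max(first))
  lut[first] <- seq_along(first)
  lut
}

# restrict label k to the 4-connected component containing (cx, cy);
# if the centre pixel does not carry the label, keep the largest component
keep_center_component <- function(labels, k, cx, cy) {
  h <- nrow(labels); w <- ncol(labels)
  sel <- labels == k
  if (!any(sel)) return(labels)
  comp <- flood4(sel, cx, cy)
  if (is.null(comp)) {
    # centre pixel off the region: seed from the region pixel nearest centre
    idx <- which(sel)
    pyx <- arrayInd(idx, dim(sel))
    d2 <- (pyx[, 1] - 1 - cy)^2 + (pyx[, 2] - 1 - cx)^2
    seedpx <- pyx[which.min(d2), ]
    comp <- flood4(sel, seedpx[2] - 1L, seedpx[1] - 1L)
  }
  labels[sel & !comp] <- 0L
  labels
}

# 4-connected flood fill of TRUE pixels from 0-based (x, y); NULL if the
# seed pixel is FALSE
flood4 <- function(sel, x, y) {
  h <- nrow(sel); w <- ncol(sel)
  if (x < 0 || x >= w || y < 0 || y >= h || !sel[y + 1L, x + 1L]) return(NULL)
  comp <- matrix(FALSE, h, w)
  queue <- (x) * h + (y + 1L)   # column-major linear index
  comp[queue] <- TRUE
  while (length(queue)) {
    cur <- queue
    queue <- integer()
    r <- ((cur - 1L) %% h) + 1L
    cl <- ((cur - 1L) %/% h) + 1L
    for (d in 1:4) {
      nr <- r + c(-1L, 1L, 0L, 0L)[d]
      nc <- cl + c(0L, 0L, -1L, 1L)[d]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      ni <- (nc[ok] - 1L) * h + nr[ok]
      ni <- ni[sel[ni] & !comp[ni]]
      if (length(ni)) {
        comp[ni] <- TRUE
        queue <- c(queue, ni)
      }
    }
    queue <- unique(queue)
  }
  comp
}

#' Generate one synthetic ROI with ground truth
#'
#' Couples [generate_centers()] and [render_cones()] and attaches the
#' realized truth, computed by the generator's own direct pixel counts
#' (independent of the measurement pipeline): realized centre-count
#' density, realized mean segmented-cone area, and the whole-ROI unoccupied
#' pixel fraction.
#'
#' @param params A [mosaic_params()].
#' @param roi An [roi_spec()].
#' @return A list of class `synthetic_roi`: `centers`, `mask`,
#'   `label_of_center`, `truth`.
#' @export
generate_roi <- function(params, roi) {
  centers <- generate_centers(params, roi)
  rend <- render_cones(centers, params)
  L <- rend$mask$labels
  K <- rend$mask$n_cones
  areas_px <- if (K > 0L) tabulate(L[L > 0L], nbins = K) else integer()
  truth <- list(
    params = params,
    n_centers = length(centers$x),
    realized_density_cells_mm2 = length(centers$x) / roi_area_mm2(roi),
    realized_mean_area_um2 = if (K) mean(areas_px) * roi$microns_per_pixel^2 else NA_real_,
    realized_unoccupied_roi_pct = 100 * mean(L == 0L))
  structure(list(centers = centers, mask = rend$mask,
                 label_of_center = rend$label_of_center, truth = truth),
            class = "synthetic_roi")
}

#' Group-level mosaic presets (control / CHM at 1, 2, 4 degrees)
#'
#' Default per-cell means and SDs of bound density, cone area, circularity
#' and percent intercone space used by the cohort simulators. The values
#' emulate published AOSLO statistics for choroideremia patients and
#' normal-sighted controls at 1, 2 and 4 degrees temporal: density falls
#' and cone area grows with eccentricity in both groups, and the CHM group
#' shows roughly halved density, enlarged inner segments and increased
#' intercone space at every eccentricity.
#'
#' @return Data frame with one row per (group, eccentricity): columns
#'   `group`, `eccentricity_deg`, `density_mean`, `density_sd`,
#'   `area_mean`, `area_sd`, `circ_mean`, `circ_sd`, `intercone_mean`,
#'   `intercone_sd`.
#' @export
default_presets <- function() {
  data.frame(
    group = rep(c("control", "CHM"), each = 3),
    eccentricity_deg = rep(c(1, 2, 4), 2),
    density_mean = c(63000, 37000, 19100, 38800, 22300, 13700),
    density_sd   = c(6900, 4000, 2000, 14700, 7400, 200),
    area_mean    = c(12.0, 19.5, 31.5, 20.0, 27.3, 39.4),
    area_sd      = c(1.2, 3.9, 6.1, 6.3, 8.7, 6.1),
    circ_mean    = c(0.755, 0.757, 0.762, 0.762, 0.762, 0.779),
    circ_sd      = c(0.017, 0.025, 0.009, 0.026, 0.021, 0.013),
    intercone_mean = c(4.3, 11.1, 23.8, 14.2, 25.6, 31.3),
    intercone_sd   = c(1.6, 5.2, 7.4, 6.3, 10.5, 9.7),
    stringsAsFactors = FALSE)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  out <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  ifelse(sd <= 0, mean, out)
}

#' Simulate a full image-level cohort
#'
#' For each subject and eccentricity, draws subject-level density and mean
#' area from the preset cell (truncated normal), generates one synthetic
#' ROI, and collects metadata. A configurable number of CHM subjects have
#' no 4-degree ROI, emulating the unbalanced design of a real cohort (with
#' defaults, 75 - 4 = 71 ROIs). Fully deterministic for a fixed seed; each
#' ROI's generator seed is derived by [child_seed()].
#'
#' @param presets Preset table as from [default_presets()].
#' @param n_control,n_chm Numbers of subjects per group (defaults 12, 13).
#' @param n_missing_chm4 Number of CHM subjects lacking the 4-degree ROI
#'   (default 4).
#' @param seed Run seed.
#' @param roi_px ROI side in pixels (square ROI, default 128).
#' @param dropout_chm Dropout fraction applied to CHM mosaics (patchy cone
#'   loss; default 0.08). Controls use 0.
#' @param area_cv Within-ROI cone-area CV (default 0.25).
#' @param shape_irregularity Boundary irregularity (default 0.2).
#' @param density_area_cor Between-subject correlation of the density and
#'   mean-area draws (default -0.6): mosaics that have lost cones carry
#'   enlarged inner segments. The preset marginals are preserved; draws
#'   whose joint value would overfill the retina saturate at 95% occupancy.
#' @return A list of class `synthetic_cohort`: `rois` (list of records with
#'   `subject_id`, `group`, `eccentricity_deg`, `axial_length_mm`, `roi`
#'   a `synthetic_roi`), `presets`, `seed`.
#' @export
generate_cohort <- function(presets = default_presets(), n_control = 12L,
                            n_chm = 13L, n_missing_chm4 = 4L, seed = 1L,
                            roi_px = 128L, dropout_chm = 0.08,
                            area_cv = 0.25, shape_irregularity = 0.2,
                            density_area_cor = -0.6) {
  stopifnot(nrow(presets) == 6L)
  subjects <- data.frame(
    subject_id = c(sprintf("C%02d", seq_len(n_control)),
                   sprintf("P%02d", seq_len(n_chm))),
    group = rep(c("control", "CHM"), c(n_control, n_chm)),
    stringsAsFactors = FALSE)
  missing4 <- with_seed(child_seed(seed, 0L), {
    al <- rtruncnorm1(nrow(subjects), 24.2, 1.0, 21.5, 27.5)
    m <- if (n_chm > 0L && n_missing_chm4 > 0L) {
      sample(subjects$subject_id[subjects$group == "CHM"],
             min(n_missing_chm4, n_chm))
    } else character()
    list(al = al, m = m)
  })
  subjects$axial_length_mm <- missing4$al
  rois <- list()
  idx <- 0L
  for (i in seq_len(nrow(subjects))) {
    for (ecc in c(1, 2, 4)) {
      idx <- idx + 1L
      if (subjects$group[i] == "CHM" && ecc == 4 &&
          subjects$subject_id[i] %in% missing4$m) next
      p <- presets[presets$group == subjects$group[i] &
                     presets$eccentricity_deg == ecc, ]
      rseed <- child_seed(seed, idx)
      drop <- if (subjects$group[i] == "CHM") dropout_chm else 0
      draws <- with_seed(child_seed(rseed, 99L), {
        d <- rtruncnorm1(1, p$density_mean, p$density_sd,
                         max(2000, p$density_mean - 3 * p$density_sd),
                         p$density_mean + 3 * p$density_sd)
        # cone enlargement accompanies density loss: draw area conditional
        # on the density draw with correlation `density_area_cor`, which
        # preserves both preset marginals
        zd <- max(-3, min(3, (d - p$density_mean) / max(p$density_sd, 1e-9)))
        a_mu <- p$area_mean + density_area_cor * p$area_sd * zd
        a_sd <- p$area_sd * sqrt(1 - density_area_cor^2)
        a <- rtruncnorm1(1, a_mu, a_sd,
                         max(4, p$area_mean - 3 * p$area_sd),
                         min(80, p$area_mean + 3 * p$area_sd))
        c(d, a)
      })
      d_draw <- draws[1]; a_draw <- draws[2]
      # dropout thins the lattice, so lay it denser to realize the drawn
      # density; saturate the area draw at the packing bound
      d_lat <- d_draw / (1 - drop)
      if (d_lat * a_draw * 1e-4 > 94.99) {
        a_draw <- 94.99 / (d_lat * 1e-4)
      }
      upp <- microns_per_pixel(subjects$axial_length_mm[i])
      rs <- roi_spec(roi_px, roi_px, eccentricity_deg = ecc,
                     microns_per_pixel = upp)
      mp <- mosaic_params(
        target_density_cells_mm2 = d_lat, mean_area_um2 = a_draw,
        density_sd = p$density_sd, area_cv = area_cv,
        shape_irregularity = shape_irregularity,
        lattice_jitter_frac = 0.15, dropout_frac = drop, seed = rseed)
      rois[[length(rois) + 1L]] <- list(
        subject_id = subjects$subject_id[i], group = subjects$group[i],
        eccentricity_deg = ecc,
        axial_length_mm = subjects$axial_length_mm[i],
        roi = generate_roi(mp, rs))
    }
  }
  structure(list(rois = rois, presets = presets, seed = seed,
                 subjects = subjects),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d ROIs from %d subjects (seed %d)\n",
              length(x$rois), nrow(x$subjects), x$seed))
  invisible(x)
}

#' Simulate a cohort at the metric level
#'
#' Draws per-subject metric values (density, area, circularity, intercone
#' space) directly from the preset cells — no images — producing a
#' [cohort_table()] with the same 2 x 3 unbalanced structure as the imaging
#' cohort. Used for statistical calibration experiments (power, type I
#' error) where full image simulation would add nothing.
#'
#' @inheritParams generate_cohort
#' @return A [cohort_table()] with metrics `density`, `area`, `circularity`,
#'   `intercone`.
#' @export
simulate_cohort_metrics <- function(presets = default_presets(),
                                    n_control = 12L, n_chm = 13L,
                                    n_missing_chm4 = 4L, seed = 1L) {
  stopifnot(nrow(presets) == 6L)
  with_seed(seed, {
    subjects <- data.frame(
      subject_id = c(sprintf("C%02d", seq_len(n_control)),
                     sprintf("P%02d", seq_len(n_chm))),
      group = rep(c("control", "CHM"), c(n_control, n_chm)),
      stringsAsFactors = FALSE)
    miss <- if (n_chm > 0L && n_missing_chm4 > 0L) {
      sample(subjects$subject_id[subjects$group == "CHM"],
             min(n_missing_chm4, n_chm))
    } else character()
    grid <- merge(data.frame(subject_id = subjects$subject_id,
                             group = subjects$group,
                             stringsAsFactors = FALSE),
                  data.frame(eccentricity_deg = c(1, 2, 4)))
    grid <- grid[!(grid$group == "CHM" & grid$eccentricity_deg == 4 &
                     grid$subject_id %in% miss), ]
    grid <- grid[order(grid$subject_id, grid$eccentricity_deg), ]
    p <- presets[match(paste(grid$group, grid$eccentricity_deg),
                       paste(presets$group, presets$eccentricity_deg)), ]
    n <- nrow(grid)
    grid$density <- rtruncnorm1(n, p$density_mean, p$density_sd, 0, Inf)
    grid$area <- rtruncnorm1(n, p$area_mean, p$area_sd, 0, Inf)
    grid$circularity <- rtruncnorm1(n, p$circ_mean, p$circ_sd, 0, Inf)
    grid$intercone <- rtruncnorm1(n, p$intercone_mean, p$intercone_sd, 0, 100)
    cohort_table(grid)
  })
}
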