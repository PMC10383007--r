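test_that("mosaic parameters reject impossible packings", {
  expect_error(mosaic_params(63000, 20), "occupancy")
  expect_s3_class(mosaic_params(38800, 20), "mosaic_params")
  expect_error(mosaic_params(-1, 10), ">")
  expect_error(mosaic_params(10000, 10, lattice_jitter_frac = 0.7), "<=")
})

test_that("noise-free hexagonal mosaics recover the analytic density", {
  d <- 46188
  p <- mosaic_params(d, 15, lattice_jitter_frac = 0, shape_irregularity = 0,
                     area_cv = 0, seed = 2)
  cc <- generate_centers(p, roi_spec(128, 128, 1, 0.5))
  expect_lt(abs(bound_density(cc) - d) / d, 0.005)
})

test_that("centre generation is deterministic per seed", {
  p <- mosaic_params(30000, 18, seed = 42)
  r <- roi_spec(96, 96, 1, 0.5)
  c1 <- generate_centers(p, r)
  c2 <- generate_centers(p, r)
  expect_identical(c1$x, c2$x); expect_identical(c1$y, c2$y)
  p2 <- mosaic_params(30000, 18, seed = 43)
  c3 <- generate_centers(p2, r)
  expect_false(identical(c1$x, c3$x))
})

test_that("a too-coarse pixel scale is rejected", {
  p <- mosaic_params(60000, 10, seed = 1)
  expect_error(generate_centers(p, roi_spec(32, 32, 1, 3)), "scale too coarse")
  expect_error(generate_centers(mosaic_params(8000, 10, seed = 1),
                                roi_spec(16, 16, 1, 0.5)),
               "9 lattice sites")
})

test_that("dropout thins sites at the requested rate", {
  # ~500-site lattice, dropout 0.2: realized removals inside binomial 99% CI
  p0 <- mosaic_params(20000, 10, lattice_jitter_frac = 0,
                      dropout_frac = 0, seed = 77)
  p <- mosaic_params(20000, 10, lattice_jitter_frac = 0,
                     dropout_frac = 0.2, seed = 77)
  r <- roi_spec(320, 320, 1, 0.5)   # 0.0256 mm^2 -> ~512 lattice sites
  n_sites <- length(generate_centers(p0, r))
  n_kept <- length(generate_centers(p, r))
  expect_gt(n_sites, 450)
  ci <- qbinom(c(0.005, 0.995), n_sites, 0.8)
  expect_gte(n_kept, ci[1]); expect_lte(n_kept, ci[2])
})

test_that("disc-mode rendering matches the digital-disc circularity oracle", {
  # 28.27 um^2 at 0.5 um/px is a 113-px target, the radius-6 digital disc
  p <- mosaic_params(12000, 113 * 0.25, shape_irregularity = 0, area_cv = 0,
                     lattice_jitter_frac = 0.1, seed = 8)
  roi <- generate_roi(p, roi_spec(128, 128, 1, 0.5))
  shapes <- cone_shape_table(roi$mask)
  L <- oracle_disc_mask(6, 10, 10, 21, 21)
  oracle_circ <- 4 * pi * oracle_area(L, 1L) / oracle_perimeter(L, 1L)^2
  expect_equal(median(shapes$area_px), 113)
  expect_lt(abs(mean(shapes$circularity) - oracle_circ) / oracle_circ, 0.05)
})

test_that("rendered areas recover the target mean within sampling error", {
  # ~300 cones at low occupancy so cell truncation is negligible
  p <- mosaic_params(20000, 20, area_cv = 0.3, seed = 14)
  roi <- generate_roi(p, roi_spec(280, 280, 1, 0.5))
  shapes <- cone_shape_table(roi$mask)
  expect_gt(nrow(shapes), 250)
  se <- 20 * 0.3 / sqrt(nrow(shapes))
  expect_lt(abs(mean(shapes$area_um2) - 20), 2 * se)
})

test_that("gap regime propagates to measured intercone space", {
  # density x area chosen to leave ~14% gaps, emulating degenerate mosaics
  p <- mosaic_params(43000, 20, area_cv = 0.15, lattice_jitter_frac = 0.1,
                     seed = 6)
  roi <- generate_roi(p, roi_spec(128, 128, 1, 0.5))
  m <- roi_metrics(roi$centers, roi$mask)
  expect_lt(abs(m$intercone_pct - 14), 4)
})

test_that("generated masks satisfy the label-mask invariants", {
  p <- mosaic_params(35000, 18, shape_irregularity = 0.35, seed = 19)
  roi <- generate_roi(p, roi_spec(72, 72, 1, 0.5))
  L <- roi$mask$labels
  # every label 4-connected (independent flood fill)
  for (k in seq_len(roi$mask$n_cones)) {
    expect_true(oracle_connected4(L, k))
  }
  # no blob crosses its own Voronoi domain (brute-force nearest centre)
  own <- oracle_nearest(roi$centers$x, roi$centers$y, 72L, 72L)
  lab_of <- roi$label_of_center
  for (k in seq_along(roi$centers$x)) {
    if (is.na(lab_of[k])) next
    expect_true(all(own[L == lab_of[k]] == k))
  }
})

test_that("increasing dropout increases measured intercone space", {
  mean_icp <- function(drop) {
    vals <- vapply(1:6, function(s) {
      p <- mosaic_params(30000, 18, dropout_frac = drop, seed = 100 + s)
      roi <- generate_roi(p, roi_spec(96, 96, 1, 0.5))
      roi_metrics(roi$centers, roi$mask)$intercone_pct
    }, numeric(1))
    mean(vals)
  }
  icp <- vapply(c(0, 0.15, 0.3), mean_icp, numeric(1))
  expect_true(all(diff(icp) > 0))
})

test_that("pipeline measurements regress on generator truth with unit slope", {
  set.seed(77)
  dens_t <- numeric(); dens_m <- numeric()
  area_t <- numeric(); area_m <- numeric()
  for (s in 1:24) {
    d <- runif(1, 15000, 55000)
    a <- runif(1, 10, min(35, 0.9 * 95 / (d * 1e-4)))
    p <- mosaic_params(d, a, seed = 1000 + s)
    roi <- generate_roi(p, roi_spec(96, 96, 1, 0.5))
    m <- roi_metrics(roi$centers, roi$mask)
    dens_t <- c(dens_t, roi$truth$realized_density_cells_mm2)
    dens_m <- c(dens_m, m$bound_density_cells_mm2)
    area_t <- c(area_t, a)   # the drawn target, not the realized pixel count
    area_m <- c(area_m, m$mean_area_um2)
  }
  expect_lt(abs(coef(lm(dens_m ~ dens_t))[2] - 1), 0.1)
  expect_lt(abs(coef(lm(area_m ~ area_t))[2] - 1), 0.1)
})

test_that("cohort generation honours the unbalanced design contract", {
  ch <- generate_cohort(n_control = 3, n_chm = 3, n_missing_chm4 = 2,
                        seed = 4, roi_px = 80)
  expect_s3_class(ch, "synthetic_cohort")
  expect_identical(length(ch$rois), 3L * 3L + 3L * 3L - 2L)
  eccs <- vapply(ch$rois, `[[`, numeric(1), "eccentricity_deg")
  grps <- vapply(ch$rois, `[[`, character(1), "group")
  expect_identical(sum(grps == "CHM" & eccs == 4), 1L)
  # determinism / seed sensitivity
  ch2 <- generate_cohort(n_control = 3, n_chm = 3, n_missing_chm4 = 2,
                         seed = 4, roi_px = 80)
  expect_identical(ch$rois[[1]]$roi$centers$x, ch2$rois[[1]]$roi$centers$x)
  ch3 <- generate_cohort(n_control = 3, n_chm = 3, n_missing_chm4 = 2,
                         seed = 5, roi_px = 80)
  expect_false(identical(ch$rois[[1]]$roi$centers$x,
                         ch3$rois[[1]]$roi$centers$x))
})

test_that("single-group cohorts are generable but rejected by the ANOVA", {
  ch <- generate_cohort(n_control = 0, n_chm = 4, n_missing_chm4 = 0,
                        seed = 6, roi_px = 80)
  expect_identical(length(ch$rois), 12L)
  rows <- lapply(ch$rois, function(r) {
    cbind(data.frame(subject_id = r$subject_id, group = r$group,
                     eccentricity_deg = r$eccentricity_deg),
          as.data.frame(roi_metrics(r$roi$centers, r$roi$mask)))
  })
  tab <- cohort_table(do.call(rbind, rows)[
    c("subject_id", "group", "eccentricity_deg", "bound_density_cells_mm2")])
  expect_error(fit_two_way_anova(tab, "bound_density_cells_mm2"),
               "empty cell")
})

test_that("metric-level cohort simulation matches the design structure", {
  tab <- simulate_cohort_metrics(seed = 31)
  expect_s3_class(tab, "cohort_table")
  expect_identical(nrow(tab), 71L * 4L)    # 71 ROIs x 4 metrics
  expect_true(all(tab$value > 0))
  # deterministic
  expect_identical(simulate_cohort_metrics(seed = 31)$value, tab$value)
})
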