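#' Write a synthetic cohort to disk in the package's exchange formats
#'
#' One directory per ROI (`<subject>_<ecc>deg/`) holding `centers.csv`,
#' `mask.tif` (16-bit labels) and `truth.json`, plus a top-level
#' `cohort.json` with subject records and per-ROI metadata (paths, group,
#' eccentricity, axial length, pixel scale). These are exactly the formats
#' [read_cohort()] ingests.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to `cohort.json`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$rois, function(rec) {
    sub <- sprintf("%s_%gdeg", rec$subject_id, rec$eccentricity_deg)
    rdir <- file.path(dir, sub)
    dir.create(rdir, showWarnings = FALSE)
    write_centers(rec$roi$centers, file.path(rdir, "centers.csv"))
    write_label_mask(rec$roi$mask, file.path(rdir, "mask.tif"))
    tr <- rec$roi$truth
    tr$params <- unclass(tr$params)
    jsonlite::write_json(tr, file.path(rdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    rs <- rec$roi$centers$roi
    list(subject_id = rec$subject_id, group = rec$group,
         eccentricity_deg = rec$eccentricity_deg,
         axial_length_mm = rec$axial_length_mm,
         width_px = rs$width_px, height_px = rs$height_px,
         microns_per_pixel = rs$microns_per_pixel,
         centers = file.path(sub, "centers.csv"),
         mask = file.path(sub, "mask.tif"))
  })
  meta <- list(seed = cohort$seed,
               subjects = cohort$subjects,
               rois = entries)
  path <- file.path(dir, "cohort.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Ingests a `cohort.json` written by [write_cohort()] (or assembled by
#' hand for real data in the same layout): validates every ROI's centre
#' file and label mask against its declared geometry.
#'
#' @param path Path to a `cohort.json` metadata file.
#' @return A list of class `file_cohort`: per ROI `subject_id`, `group`,
#'   `eccentricity_deg`, `centers` ([cone_centers()]), `mask`
#'   ([cone_mask()]).
#' @export
read_cohort <- function(path) {
  stopifnot(file.exists(path))
  meta <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  base <- dirname(path)
  rois <- lapply(meta$rois, function(e) {
    rs <- roi_spec(e$width_px, e$height_px,
                   eccentricity_deg = e$eccentricity_deg,
                   microns_per_pixel = e$microns_per_pixel)
    list(subject_id = e$subject_id, group = e$group,
         eccentricity_deg = e$eccentricity_deg,
         centers = read_centers(file.path(base, e$centers), rs),
         mask = read_label_mask(file.path(base, e$mask), rs))
  })
  structure(list(rois = rois, seed = meta$seed), class = "file_cohort")
}

#' Pipeline run configuration
#'
#' Exactly one input mode must be active: `synthetic` (a list of arguments
#' for [generate_cohort()]) or `files` (path to a `cohort.json`).
#'
#' @param synthetic `NULL`, or a (possibly empty) list of overrides for
#'   [generate_cohort()].
#' @param files `NULL`, or a path to cohort metadata for [read_cohort()].
#' @param out_dir Output directory for run artifacts.
#' @param seed Integer run seed (recorded in every artifact; passed to the
#'   generator in synthetic mode).
#' @param metrics Metric columns to analyse with the ANOVA.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = NULL, files = NULL, out_dir, seed = 1L,
                       metrics = c("bound_density_cells_mm2", "mean_area_um2",
                                   "mean_circularity", "intercone_pct")) {
  if (!is.null(synthetic) && !is.null(files)) {
    stop("exactly one input mode must be active: got both 'synthetic' and 'files'")
  }
  if (is.null(synthetic) && is.null(files)) {
    stop("exactly one input mode must be active: got neither")
  }
  structure(list(synthetic = synthetic, files = files, out_dir = out_dir,
                 seed = as.integer(seed), metrics = metrics),
            class = "run_config")
}

#' Run the full mosaic-quantification pipeline
#'
#' Ingests (or generates) a cohort, measures every ROI with
#' [roi_metrics()], assembles the cohort table, fits the unbalanced
#' two-way ANOVA and Bonferroni post hoc contrasts for each configured
#' metric, and writes all artifacts under `config$out_dir`:
#' `cohort.csv` (one row per ROI), `summary.csv` (per-cell mean/SD/n),
#' `anova.json`, `posthoc.csv`, `report.md` and `run.json` (seed, config,
#' package version). A malformed ROI is skipped and recorded in
#' `errors.csv`; the run fails only if every ROI fails. Synthetic-mode
#' outputs are deterministic for a fixed config and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `cohort` (data frame), `anova` (list of
#'   [fit_two_way_anova()] results), `posthoc`, `summary`, `errors`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    args$seed <- config$seed
    cohort_in <- do.call(generate_cohort, args)
    rois <- lapply(cohort_in$rois, function(r) {
      list(subject_id = r$subject_id, group = r$group,
           eccentricity_deg = r$eccentricity_deg,
           centers = r$roi$centers, mask = r$roi$mask)
    })
  } else {
    rois <- read_cohort(config$files)$rois
  }
  rows <- list(); errs <- list()
  for (r in rois) {
    res <- tryCatch(roi_metrics(r$centers, r$mask), error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        subject_id = r$subject_id, eccentricity_deg = r$eccentricity_deg,
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = r$subject_id, group = r$group,
                   eccentricity_deg = r$eccentricity_deg,
                   stringsAsFactors = FALSE),
        as.data.frame(res))
    }
  }
  if (!length(rows)) stop("all ROIs failed; see error records")
  cohort <- do.call(rbind, rows)
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(subject_id = character(), eccentricity_deg = numeric(),
               error = character())
  tab <- cohort_table(cohort[c("subject_id", "group", "eccentricity_deg",
                               config$metrics)])
  fits <- lapply(config$metrics, function(m) fit_two_way_anova(tab, m))
  names(fits) <- config$metrics
  ph <- do.call(rbind, lapply(config$metrics, function(m) {
    cbind(metric = m, pairwise_posthoc(tab, m))
  }))
  summ <- summary_table(tab)
  # artifacts
  utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(summ, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ph, file.path(config$out_dir, "posthoc.csv"),
                   row.names = FALSE)
  utils::write.csv(errors, file.path(config$out_dir, "errors.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(fits, function(f) list(metric = f$metric, effects = f$effects,
                                  df_error = f$df_error, n_obs = f$n_obs)),
    file.path(config$out_dir, "anova.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = config$seed,
         mode = if (is.null(config$synthetic)) "files" else "synthetic",
         metrics = config$metrics,
         package_version = as.character(utils::packageVersion("conemosaic")),
         n_rois = nrow(cohort), n_errors = nrow(errors)),
    file.path(config$out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  writeLines(render_report(summ, fits, config$seed),
             file.path(config$out_dir, "report.md"))
  invisible(list(cohort = cohort, anova = fits, posthoc = ph,
                 summary = summ, errors = errors, out_dir = config$out_dir))
}

# markdown report: per-cell summary grid + one ANOVA table per metric
render_report <- function(summ, fits, seed) {
  lines <- c("# Cone mosaic quantification report", "",
             sprintf("Seed: %d", seed), "", "## Group summaries (mean ± SD (n))", "")
  for (m in unique(summ$metric)) {
    s <- summ[summ$metric == m, ]
    lines <- c(lines, sprintf("### %s", m), "",
               "| eccentricity | control | CHM |",
               "|---|---|---|")
    for (e in c(1, 2, 4)) {
      fmt <- function(g) {
        r <- s[s$group == g & s$eccentricity_deg == e, ]
        if (r$n == 0L) return("n = 0")
        sprintf("%.4g ± %.3g (n=%d)", r$mean,
                ifelse(is.na(r$sd), NaN, r$sd), r$n)
      }
      lines <- c(lines, sprintf("| %d° | %s | %s |", e,
                                fmt("control"), fmt("CHM")))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Two-way ANOVA (type III sums of squares)", "")
  for (f in fits) {
    lines <- c(lines, sprintf("### %s (n = %d, error df = %d)",
                              f$metric, f$n_obs, f$df_error), "",
               "| effect | SS | df | F | p |", "|---|---|---|---|---|")
    for (i in seq_len(nrow(f$effects))) {
      r <- f$effects[i, ]
      lines <- c(lines, sprintf("| %s | %.6g | %d | %s | %s |", r$effect,
                                r$sum_sq, r$df,
                                ifelse(is.na(r$F), "", sprintf("%.2f", r$F)),
                                ifelse(is.na(r$p), "", format.pval(r$p, digits = 3))))
    }
    lines <- c(lines, "")
  }
  lines
}
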