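#' Assemble a long-format cohort table
#'
#' Validates and normalises a long table of per-ROI measurements feeding
#' the group analysis: one row per (subject, eccentricity, metric). Missing
#' cells are allowed (the design may be unbalanced), duplicated rows are
#' not.
#'
#' @param df Data frame with columns `subject_id`, `group` (control/CHM),
#'   `eccentricity_deg` (1, 2 or 4) and one column per metric, or already
#'   long with columns `metric`, `value`.
#' @return A data frame of class `cohort_table` with columns `subject_id`,
#'   `group`, `eccentricity_deg`, `metric`, `value`.
#' @export
cohort_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("subject_id", "group", "eccentricity_deg")
  if (!all(need %in% names(df))) {
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("metric", "value") %in% names(df))) {
    metric_cols <- setdiff(names(df), need)
    if (!length(metric_cols)) stop("no metric columns found")
    long <- do.call(rbind, lapply(metric_cols, function(m) {
      data.frame(df[need], metric = m, value = as.numeric(df[[m]]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    long <- df[c(need, "metric", "value")]
  }
  if (!all(long$group %in% c("control", "CHM"))) {
    stop("group must be 'control' or 'CHM'")
  }
  if (!all(long$eccentricity_deg %in% c(1, 2, 4))) {
    stop("eccentricity_deg must be 1, 2 or 4")
  }
  long <- long[!is.na(long$value), , drop = FALSE]
  key <- paste(long$subject_id, long$eccentricity_deg, long$metric)
  if (anyDuplicated(key)) {
    stop("more than one row per (subject, eccentricity, metric): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(long) <- NULL
  class(long) <- c("cohort_table", "data.frame")
  long
}

# sum-to-zero coded design matrix columns for the 2x3 layout
design_columns <- function(group, ecc) {
  g <- ifelse(group == "control", 1, -1)           # contr.sum, levels (control, CHM)
  e1 <- ifelse(ecc == 1, 1, ifelse(ecc == 4, -1, 0))
  e2 <- ifelse(ecc == 2, 1, ifelse(ecc == 4, -1, 0))
  cbind(intercept = 1, g = g, e1 = e1, e2 = e2,
        ge1 = g * e1, ge2 = g * e2)
}

rss_fit <- function(X, yv) {
  fit <- qr(X)
  if (fit$rank < ncol(X)) return(NA_real_)
  sum(qr.resid(fit, yv)^2)
}

#' Unbalanced two-way ANOVA (group x eccentricity)
#'
#' Fits the full two-way linear model with interaction by explicit design
#' matrices (sum-to-zero factor coding) and computes type III (marginal)
#' sums of squares: each effect's SS is the increase in residual SS when
#' its columns are dropped from the full model. F statistics use the full
#' model's mean squared error; with a 2 x 3 design the effect dfs are 1
#' (group), 2 (eccentricity), 2 (interaction) and the error df is n - 6.
#'
#' @param table A [cohort_table()].
#' @param metric Name of the metric to analyse.
#' @return A list of class `anova_result`: data frame `effects` (rows
#'   group / eccentricity / interaction / error with `sum_sq`, `df`, `F`,
#'   `p`), `df_error`, `n_obs`, `mse`, and cell means/counts.
#' @export
fit_two_way_anova <- function(table, metric) {
  stopifnot(inherits(table, "cohort_table"))
  d <- table[table$metric == metric, , drop = FALSE]
  if (!nrow(d)) stop("metric '", metric, "' not present in cohort table")
  n <- nrow(d)
  if (n <= 6L) stop("need more than 6 observations, got ", n)
  cells <- base::table(factor(d$group, c("control", "CHM")),
                       factor(d$eccentricity_deg, c(1, 2, 4)))
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    nm <- paste(rownames(cells)[empty[, 1]], "x",
                colnames(cells)[empty[, 2]], "deg", collapse = ", ")
    stop("empty cell(s) make the interaction inestimable: ", nm)
  }
  X <- design_columns(d$group, d$eccentricity_deg)
  yv <- d$value
  rss_full <- rss_fit(X, yv)
  drop_set <- list(group = "g", eccentricity = c("e1", "e2"),
                   interaction = c("ge1", "ge2"))
  ss <- vapply(drop_set, function(cols) {
    rss_fit(X[, setdiff(colnames(X), cols), drop = FALSE], yv) - rss_full
  }, numeric(1))
  dfs <- c(group = 1L, eccentricity = 2L, interaction = 2L)
  df_err <- n - 6L
  # round-off floor: SS below machine-level noise are exact zeros
  floor_ss <- 1e-18 * sum(yv^2)
  ss[ss <= floor_ss] <- 0
  rss_full_r <- if (rss_full <= floor_ss) 0 else rss_full
  mse <- rss_full_r / df_err
  if (mse == 0) {
    warning("zero residual variance: F statistics are infinite/undefined")
  }
  Fv <- (ss / dfs) / mse
  pv <- stats::pf(Fv, dfs, df_err, lower.tail = FALSE)
  eff <- data.frame(
    effect = c(names(dfs), "error"),
    sum_sq = c(ss, rss_full_r),
    df = c(dfs, df_err),
    F = c(Fv, NA),
    p = c(pv, NA),
    row.names = NULL)
  means <- tapply(yv, list(factor(d$group, c("control", "CHM")),
                           factor(d$eccentricity_deg, c(1, 2, 4))), mean)
  structure(list(metric = metric, effects = eff, df_error = df_err,
                 n_obs = n, mse = mse, cell_means = means,
                 cell_n = unclass(cells)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (type III), metric '%s', n = %d\n",
              x$metric, x$n_obs))
  print(transform(x$effects, F = round(F, 3), p = signif(p, 3)))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' Multiplies each p value by the family size `m` and caps at 1.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @param m Family size, at least `length(p_values)`.
#' @return Adjusted p values, order preserved.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop("m must be >= number of p values")
  pmin(1, m * p_values)
}

#' Bonferroni post hoc cell-mean contrasts
#'
#' The nine natural pairwise comparisons in the 2 x 3 layout: between
#' eccentricities within each group (3 pairs x 2 groups) and between groups
#' within each eccentricity (3). Each contrast is a two-sample t test on
#' the pooled error mean square of the full ANOVA (df = error df),
#' Bonferroni-adjusted with family size m = 9. Cells with fewer than 2
#' observations are excluded with a warning.
#'
#' @param table A [cohort_table()].
#' @param metric Metric name.
#' @return Data frame: `comparison`, `group`, `eccentricity`, `estimate`,
#'   `t`, `df`, `p`, `p_adj`.
#' @export
pairwise_posthoc <- function(table, metric) {
  fit <- fit_two_way_anova(table, metric)
  means <- fit$cell_means
  ns <- fit$cell_n
  mse <- fit$mse
  df <- fit$df_error
  groups <- rownames(means); eccs <- colnames(means)
  rows <- list()
  add <- function(label, grp, ecc, m1, m2, n1, n2) {
    if (n1 < 2L || n2 < 2L) {
      warning("cell with n < 2 excluded from post hoc: ", label)
      return()
    }
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    tv <- (m1 - m2) / se
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = label, group = grp, eccentricity = ecc,
      estimate = m1 - m2, t = tv, df = df,
      p = 2 * stats::pt(-abs(tv), df), stringsAsFactors = FALSE)
  }
  for (g in groups) {
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      e1 <- eccs[pair[1]]; e2 <- eccs[pair[2]]
      add(sprintf("%s: %sdeg vs %sdeg", g, e1, e2), g,
          paste(e1, "vs", e2),
          means[g, e1], means[g, e2], ns[g, e1], ns[g, e2])
    }
  }
  for (e in eccs) {
    add(sprintf("control vs CHM @ %sdeg", e), "control vs CHM", e,
        means["control", e], means["CHM", e],
        ns["control", e], ns["CHM", e])
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p, m = 9L)
  out
}

#' Per-cell summary grid (mean, SD, n)
#'
#' Group-level summaries in the 2 groups x 3 eccentricities layout for
#' every metric present, including empty cells (n = 0).
#'
#' @param table A [cohort_table()].
#' @return Data frame: `metric`, `group`, `eccentricity_deg`, `mean`, `sd`,
#'   `n`. `sd` is NA for cells with fewer than 2 observations.
#' @export
summary_table <- function(table) {
  stopifnot(inherits(table, "cohort_table"), nrow(table) > 0L)
  grid <- expand.grid(metric = unique(table$metric),
                      group = c("control", "CHM"),
                      eccentricity_deg = c(1, 2, 4),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    v <- table$value[table$metric == grid$metric[i] &
                       table$group == grid$group[i] &
                       table$eccentricity_deg == grid$eccentricity_deg[i]]
    data.frame(grid[i, ],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$metric, out$eccentricity_deg,
                   match(out$group, c("control", "CHM"))), ]
  rownames(out) <- NULL
  out
}

#' Space-filling feasibility check
#'
#' Fraction of retinal area that a mosaic at the given density would occupy
#' if every cone had the given mean inner-segment area:
#' `occupancy% = density (cells/mm^2) x mean area (um^2) x 1e-4`. An
#' occupancy above 100% is physically impossible (the hypothetical mosaic
#' would overfill the available space); below 100% the slack is the upper
#' bound on intercone space that such a mosaic could exhibit.
#'
#' @param density_cells_mm2 Cone density in cells/mm^2 (> 0).
#' @param mean_area_um2 Mean per-cone area in um^2 (> 0).
#' @return A list of class `space_filling`: `occupancy_pct`, `feasible`,
#'   and either `overfill_pct` (occupancy - 100, when infeasible) or
#'   `max_intercone_pct` (100 - occupancy).
#' @export
space_filling_check <- function(density_cells_mm2, mean_area_um2) {
  if (!is.finite(density_cells_mm2) || density_cells_mm2 <= 0 ||
      !is.finite(mean_area_um2) || mean_area_um2 <= 0) {
    stop("density and mean area must be positive")
  }
  occ <- density_cells_mm2 * mean_area_um2 * 1e-4
  if (occ > 100) {
    structure(list(occupancy_pct = occ, feasible = FALSE,
                   overfill_pct = occ - 100), class = "space_filling")
  } else {
    structure(list(occupancy_pct = occ, feasible = TRUE,
                   max_intercone_pct = 100 - occ), class = "space_filling")
  }
}

#' @export
print.space_filling <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("occupancy %.1f%% (feasible; intercone space at most %.1f%%)\n",
                x$occupancy_pct, x$max_intercone_pct))
  } else {
    cat(sprintf("occupancy %.1f%%: not physically possible (overfilled by %.0f%%)\n",
                x$occupancy_pct, x$overfill_pct))
  }
  invisible(x)
}
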