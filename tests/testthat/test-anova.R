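balanced_table <- function(values, reps = 2) {
  grid <- expand.grid(rep = seq_len(reps),
                      eccentricity_deg = c(1, 2, 4),
                      group = c("control", "CHM"))
  cohort_table(data.frame(
    subject_id = sprintf("S%02d", seq_len(nrow(grid))),
    group = as.character(grid$group),
    eccentricity_deg = grid$eccentricity_deg,
    metric = "m", value = values))
}

test_that("cohort tables validate structure and reject duplicates", {
  df <- data.frame(subject_id = c("a", "a"), group = "control",
                   eccentricity_deg = c(1, 1), metric = "m", value = 1:2)
  expect_error(cohort_table(df), "more than one row")
  df2 <- data.frame(subject_id = "a", group = "ctrl",
                    eccentricity_deg = 1, metric = "m", value = 1)
  expect_error(cohort_table(df2), "control")
  df3 <- data.frame(subject_id = "a", group = "control",
                    eccentricity_deg = 3, metric = "m", value = 1)
  expect_error(cohort_table(df3), "1, 2 or 4")
})

test_that("the 71-observation unbalanced design gives error df 65", {
  tab <- simulate_cohort_metrics(seed = 5)
  fit <- fit_two_way_anova(tab, "density")
  expect_identical(fit$n_obs, 71L)
  expect_identical(fit$df_error, 65L)
  eff <- fit$effects
  expect_identical(eff$df[eff$effect == "group"], 1L)
  expect_identical(eff$df[eff$effect == "eccentricity"], 2L)
  expect_identical(eff$df[eff$effect == "interaction"], 2L)
})

test_that("type III equals the classical closed form on balanced designs", {
  # fixed toy set: values 1..12, 2 reps per cell
  tab <- balanced_table(1:12)
  fit <- fit_two_way_anova(tab, "m")
  d <- tab
  oracle <- oracle_balanced_anova(data.frame(group = d$group,
                                             ecc = d$eccentricity_deg,
                                             value = d$value))
  eff <- fit$effects
  expect_equal(eff$sum_sq[eff$effect == "group"], oracle$group)
  expect_equal(eff$sum_sq[eff$effect == "eccentricity"], oracle$eccentricity)
  expect_equal(eff$sum_sq[eff$effect == "interaction"], oracle$interaction)
  expect_equal(eff$sum_sq[eff$effect == "error"], oracle$error)
  # SS decomposition is exact on balanced data
  expect_equal(sum(eff$sum_sq), oracle$total)

  # random balanced tables
  for (s in 1:5) {
    set.seed(s)
    tab <- balanced_table(rnorm(6 * 3) * 10 + 50, reps = 3)
    fit <- fit_two_way_anova(tab, "m")
    d <- tab
    oracle <- oracle_balanced_anova(data.frame(group = d$group,
                                               ecc = d$eccentricity_deg,
                                               value = d$value))
    eff <- fit$effects
    expect_equal(eff$sum_sq[eff$effect == "group"], oracle$group)
    expect_equal(eff$sum_sq[eff$effect == "eccentricity"], oracle$eccentricity)
    expect_equal(eff$sum_sq[eff$effect == "interaction"], oracle$interaction)
    expect_equal(sum(eff$sum_sq), oracle$total)
  }
})

test_that("unbalanced type III matches an independent implementation", {
  skip_if_not_installed("car")
  tab <- simulate_cohort_metrics(seed = 17)
  fit <- fit_two_way_anova(tab, "area")
  d <- as.data.frame(tab[tab$metric == "area", ])
  d$g <- factor(d$group); d$e <- factor(d$eccentricity_deg)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  ca <- car::Anova(stats::lm(value ~ g * e, data = d), type = 3)
  eff <- fit$effects
  expect_equal(eff$sum_sq[eff$effect == "group"], ca[["Sum Sq"]][2])
  expect_equal(eff$sum_sq[eff$effect == "eccentricity"], ca[["Sum Sq"]][3])
  expect_equal(eff$sum_sq[eff$effect == "interaction"], ca[["Sum Sq"]][4])
  expect_equal(eff$sum_sq[eff$effect == "error"], ca[["Sum Sq"]][5])
  expect_equal(eff$F[eff$effect == "group"], ca[["F value"]][2])
  expect_equal(eff$p[eff$effect == "group"], ca[["Pr(>F)"]][2])
})

test_that("degenerate ANOVA inputs are handled", {
  # empty cell: no CHM at 4 degrees at all
  tab <- simulate_cohort_metrics(n_chm = 4, n_missing_chm4 = 4, seed = 2)
  expect_error(fit_two_way_anova(tab, "density"), "CHM x 4 deg")
  # constant response
  tabc <- balanced_table(rep(1, 12))
  expect_warning(fit <- fit_two_way_anova(tabc, "m"), "zero residual")
  expect_equal(fit$effects$sum_sq[1:3], rep(0, 3))
  # too few observations
  small <- cohort_table(data.frame(
    subject_id = sprintf("s%d", 1:6),
    group = rep(c("control", "CHM"), 3),
    eccentricity_deg = rep(c(1, 2, 4), each = 2),
    metric = "m", value = rnorm(6)))
  expect_error(fit_two_way_anova(small, "m"), "more than 6")
  expect_error(fit_two_way_anova(tab, "nope"), "not present")
})

test_that("Bonferroni adjustment is a capped multiplication", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(0, 10), 0)
  p <- runif(5)
  adj <- bonferroni_adjust(p, 9)
  expect_true(all(adj >= p))                        # never decreases
  expect_equal(bonferroni_adjust(adj[adj == 1], 9), adj[adj == 1])  # idempotent on capped
  expect_error(bonferroni_adjust(1.2, 3), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "m must be")
})

test_that("post hoc emits nine adjusted cell-mean contrasts", {
  # injected group effect far exceeding the noise at every eccentricity
  strong <- default_presets()
  strong$density_sd <- 1000
  strong$density_mean[strong$group == "CHM"] <-
    strong$density_mean[strong$group == "control"] - 15000
  tab <- simulate_cohort_metrics(presets = strong, seed = 23)
  ph <- pairwise_posthoc(tab, "density")
  expect_identical(nrow(ph), 9L)
  expect_true(all(ph$p_adj >= ph$p))
  bg <- ph[grepl("control vs CHM", ph$comparison), ]
  expect_identical(nrow(bg), 3L)
  expect_true(all(bg$p_adj < 0.05))
})

test_that("post hoc on a null construction is non-significant between groups", {
  # identical group distributions: copy control values onto CHM subjects
  set.seed(9)
  base <- expand.grid(subject_id = sprintf("C%02d", 1:12),
                      eccentricity_deg = c(1, 2, 4))
  base$value <- rnorm(nrow(base), 100 + 5 * base$eccentricity_deg, 3)
  chm <- base
  chm$subject_id <- sub("C", "P", chm$subject_id)
  df <- rbind(cbind(base, group = "control"), cbind(chm, group = "CHM"))
  df$metric <- "m"
  ph <- pairwise_posthoc(cohort_table(df), "m")
  bg <- ph[grepl("control vs CHM", ph$comparison), ]
  expect_true(all(bg$p_adj == 1))   # identical cell means -> t = 0
})

test_that("summary table covers every cell including empty ones", {
  tab <- simulate_cohort_metrics(n_control = 3, n_chm = 2,
                                 n_missing_chm4 = 2, seed = 3)
  s <- summary_table(tab)
  expect_identical(nrow(s), 4L * 6L)      # 4 metrics x 6 cells
  empty <- s[s$group == "CHM" & s$eccentricity_deg == 4, ]
  expect_true(all(empty$n == 0L))
  # single-observation cells report SD as NA
  one <- cohort_table(data.frame(
    subject_id = sprintf("s%d", 1:7),
    group = c(rep("control", 4), rep("CHM", 3)),
    eccentricity_deg = c(1, 2, 4, 2, 1, 2, 4),
    metric = "m", value = rnorm(7)))
  s1 <- summary_table(one)
  expect_true(is.na(s1$sd[s1$group == "control" & s1$eccentricity_deg == 1]))
})

test_that("space-filling check reports occupancy, overfill and slack", {
  sf <- space_filling_check(63000, 20)
  expect_equal(sf$occupancy_pct, 126)
  expect_false(sf$feasible)
  expect_equal(sf$overfill_pct, 26)

  sf2 <- space_filling_check(63000, 12)
  expect_equal(sf2$occupancy_pct, 75.6)
  expect_true(sf2$feasible)
  expect_equal(sf2$max_intercone_pct, 24.4)

  sf3 <- space_filling_check(1e-4, 1)
  expect_lt(sf3$occupancy_pct, 1e-6)

  expect_error(space_filling_check(-1, 10), "positive")
  expect_error(space_filling_check(100, 0), "positive")
})
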