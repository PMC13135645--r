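test_that("packaged cohort has the documented composition", {
  tab <- load_avf_cohort()
  expect_equal(nrow(tab), 17L)
  expect_equal(as.integer(table(tab$outcome)[c("S", "U")]), c(13L, 4L))
  expect_equal(as.integer(table(tab$fistula_type)[c("RCF", "BCF", "BBF")]),
               c(10L, 6L, 1L))
})

test_that("high-flow dichotomy is inclusive at 1000 ml/min and splits 8/9", {
  fake <- data.frame(venous_outflow_ml_min = c(1000, 999.9, NA))
  expect_identical(dichotomize_flow(fake), c("High", "Low", NA))
  tab <- load_avf_cohort()
  cat_ <- dichotomize_flow(tab)
  expect_identical(cat_, tab$outflow_category)
  expect_equal(as.integer(table(cat_)[c("High", "Low")]), c(8L, 9L))
})

test_that("group summaries use the population-SD convention", {
  tab <- load_avf_cohort()
  gs <- group_summary(tab, "outcome")
  faD <- gs[gs$variable == "fa_diameter_mm", ]
  expect_equal(round(faD$mean[faD$group == "S"], 2), 4.71)
  expect_equal(round(faD$sd[faD$group == "S"], 2), 1.45)
  # the sample-SD convention would give 1.51 instead
  x <- tab$fa_diameter_mm[tab$outcome == "S"]
  expect_equal(round(sd(x), 2), 1.51)
  ang <- gs[gs$variable == "anastomosis_angle_deg", ]
  expect_equal(round(ang$sd[ang$group == "S"], 1), 20.9)
  # degenerate single-record group: SD 0
  one <- tab[tab$fistula_type != "BBF" | tab$patient_id == "#45", ]
  one$fistula_type[one$patient_id != "#45"] <- "RCF"
  gs1 <- group_summary(one, "fistula_type")
  expect_equal(gs1$sd[gs1$group == "other"][1], 0)
})

test_that("pairwise AUC handles separation, ties, and matches the brute-force oracle", {
  expect_equal(mw_auc(c(1, 2, 3, 10, 11), c("a", "a", "a", "b", "b"),
                      positive = "b")$auc, 1)
  expect_equal(mw_auc(rep(2, 6), rep(c("a", "b"), 3), positive = "b")$auc, 0.5)
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    vals <- sample(round(rnorm(n), sample(0:2, 1)))
    labs <- sample(c("P", "N"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    r <- mw_auc(vals, labs, positive = "P")
    expect_equal(r$auc_raw, oracle_auc(vals, labs, "P"), tolerance = 1e-12)
    # monotone invariance
    r2 <- mw_auc(exp(vals / 2), labs, positive = "P")
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
    # label swap leaves the oriented AUC unchanged
    r3 <- mw_auc(vals, labs, positive = "N")
    expect_equal(r3$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation on the cohort", {
  skip_if_not_installed("pROC")
  tab <- load_avf_cohort()
  for (v in c("anastomosis_angle_deg", "fa_curvature", "fa_diameter_mm")) {
    ours <- mw_auc(tab[[v]], tab$outflow_category)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      tab$outflow_category, tab[[v]], levels = c("Low", "High"),
      direction = "auto")))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("empirical ROC curves are monotone from (0,0) to (1,1)", {
  tab <- load_avf_cohort()
  r <- mw_auc(tab$fa_diameter_mm, tab$outflow_category)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("combined logistic score reduces, separates, and dominates in-sample", {
  tab <- load_avf_cohort()
  # single variable: equals the single-variable AUC (monotone invariance)
  c1 <- combined_auc(tab, "fa_diameter_mm", tab$outflow_category)
  expect_equal(c1$auc, mw_auc(tab$fa_diameter_mm, tab$outflow_category)$auc,
               tolerance = 1e-9)
  # linearly separable toy data (penalised fallback still separates)
  toy <- data.frame(a = c(1:5, 11:15), b = rnorm(10))
  lab <- rep(c("Low", "High"), each = 5)
  ct <- combined_auc(toy, c("a", "b"), lab)
  expect_equal(ct$auc, 1)
  expect_true(ct$penalised)
  # in-sample dominance over each constituent variable
  vars <- c("fa_curvature", "fa_diameter_mm", "dv_diameter_mm")
  comb <- combined_auc(tab, vars, tab$outflow_category)
  singles <- vapply(vars, function(v)
    mw_auc(tab[[v]], tab$outflow_category)$auc, 0)
  expect_gte(comb$auc, max(singles) - 1e-9)
  # seeded bootstrap interval is reproducible and covers the estimate
  cb <- combined_auc(tab, vars, tab$outflow_category,
                     resampling = "bootstrap", n_boot = 200, seed = 3)
  cb2 <- combined_auc(tab, vars, tab$outflow_category,
                      resampling = "bootstrap", n_boot = 200, seed = 3)
  expect_identical(cb$ci, cb2$ci)
  expect_true(cb$ci[1] <= cb$auc && cb$auc <= cb$ci[2])
})

test_that("group comparison p-values behave at the null and under large shifts", {
  same <- data.frame(outcome = rep(c("S", "U"), each = 6),
                     venous_outflow_ml_min = rep(c(500, 700, 900), 4),
                     fa_diameter_mm = rep(4, 12))
  cg <- compare_groups(same, "outcome")
  expect_equal(cg$p_value[cg$variable == "venous_outflow_ml_min"], 1)
  expect_true(is.na(cg$p_value[cg$variable == "fa_diameter_mm"]))
  set.seed(13)
  shifted <- data.frame(outcome = rep(c("S", "U"), each = 20),
                        fa_diameter_mm = c(rnorm(20, 8), rnorm(20, 5)))
  for (m in c("ranksum", "welch")) {
    p <- compare_groups(shifted, "outcome", method = m)
    expect_lt(p$p_value, 0.001)
  }
  tab <- load_avf_cohort()
  p_angle <- compare_groups(tab, "fistula_type",
                            variables = "anastomosis_angle_deg")$p_value
  expect_lt(p_angle, 0.05)
})

test_that("cohort-generator group shifts reproduce the closed-form normal AUC", {
  spec <- cohort_spec(n_per_group = 400, seed = 21,
                      group_means = list(High = c(x = 0.8), Low = c(x = 0)),
                      group_sds = list(High = c(x = 1), Low = c(x = 1)))
  tab <- generate_cohort(spec)
  a <- mw_auc(tab$x, tab$latent_group, positive = "High")$auc
  expected <- pnorm(0.8 / sqrt(2))
  # Hanley-McNeil standard error of the empirical AUC
  q1 <- expected / (2 - expected)
  q2 <- 2 * expected^2 / (1 + expected)
  se <- sqrt((expected * (1 - expected) + 399 * (q1 - expected^2) +
                399 * (q2 - expected^2)) / (400 * 400))
  expect_lt(abs(a - expected), 3 * se)
})
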