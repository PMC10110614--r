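test_that("normality screening separates Gaussian from bimodal samples", {
  ok_gauss <- 0; ok_bimodal <- 0
  for (s in 1:100) {
    set.seed(s)
    g <- stats::rnorm(50)
    b <- c(stats::rnorm(25, -4, 0.5), stats::rnorm(25, 4, 0.5))
    if (shapiro_normality(g) > 0.05) ok_gauss <- ok_gauss + 1
    if (shapiro_normality(b) < 0.05) ok_bimodal <- ok_bimodal + 1
  }
  expect_gte(ok_gauss, 90)
  expect_gte(ok_bimodal, 90)
  expect_error(shapiro_normality(c(1, 2)), "at least 3")
  expect_error(shapiro_normality(rep(1, 10)), "constant")
})

test_that("the pooled t test reproduces its closed form", {
  # a = {1,2,3}, b = {4,5,6}: equal variances, pooled sd 1, se = sqrt(2/3)
  tt <- pairwise_ttest(c(1, 2, 3), c(4, 5, 6))
  se <- sqrt(1 * (1 / 3 + 1 / 3))
  t_hand <- (2 - 5) / se
  p_hand <- 2 * stats::pt(t_hand, df = 4)
  expect_equal(tt$t, t_hand, tolerance = 1e-6)       # -3.6742
  expect_equal(tt$p, p_hand, tolerance = 1e-6)       # 0.02131
  expect_equal(tt$df, 4)
  # identical samples: t = 0, p = 1
  tt0 <- pairwise_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$t, 0); expect_equal(tt0$p, 1)
  # antisymmetry in the sample order
  tt_sw <- pairwise_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(tt_sw$t, -tt$t)
  expect_equal(tt_sw$p, tt$p)
  expect_error(pairwise_ttest(1, c(1, 2)), "at least 2")
})

test_that("Bonferroni thresholds are alpha over m at 4 decimals", {
  expect_equal(bonferroni_threshold(0.05, 3), 0.0167)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.5, 3), "alpha")
})

test_that("chi-squared and ANOVA match their textbook forms", {
  # proportional table: statistic 0, p 1
  c0 <- categorical_chi2(matrix(c(10, 20, 10, 20), 2, 2))
  expect_equal(c0$statistic, 0); expect_equal(c0$p, 1)
  # [[10,20],[20,10]]: Pearson statistic by hand (uncorrected)
  tab <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2_hand <- sum((tab - expected)^2 / expected)
  c1 <- categorical_chi2(tab)
  expect_equal(c1$statistic, x2_hand, tolerance = 1e-12)  # 6.6667
  expect_equal(c1$p, stats::pchisq(x2_hand, 1, lower.tail = FALSE),
               tolerance = 1e-9)                          # 0.009823
  expect_error(categorical_chi2(matrix(c(0, 0, 5, 5), 2, 2)), "degenerate")

  a0 <- anova_groups(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3),
                          g3 = c(1, 2, 3)))
  expect_equal(a0$F, 0); expect_equal(a0$p, 1)
  # cross-check against aov on distinct data
  set.seed(51)
  smp <- list(a = stats::rnorm(8), b = stats::rnorm(8, 1), c = stats::rnorm(8))
  a1 <- anova_groups(smp)
  ref <- summary(stats::aov(y ~ g, data.frame(
    y = unlist(smp), g = factor(rep(names(smp), each = 8)))))[[1]]
  expect_equal(a1$p, ref[["Pr(>F)"]][1], tolerance = 1e-12)
})

test_that("group comparisons flag shifts and respect the correction", {
  set.seed(52)
  base <- 100
  tab <- data.frame(
    id = sprintf("e%02d", 1:60),
    group = rep(c("control", "NoDR", "mildDR"), each = 20),
    A_PID = c(stats::rnorm(20, base, 5), stats::rnorm(20, base, 5),
              stats::rnorm(20, base * 1.08, 5)))
  res <- compare_groups(tab, "A_PID")
  expect_equal(nrow(res), 3)
  shifted <- res[res$group1 == "control" & res$group2 == "mildDR", ]
  expect_lt(shifted$p, 0.05)
  expect_true(nzchar(shifted$stars))
  # dagger flags are a subset of stars at the corrected threshold
  expect_true(all(!res$bonferroni | res$p < 0.05))
  expect_equal(attr(res, "bonferroni_threshold"), 0.0167)

  # identical groups: nothing flagged
  tab0 <- tab; tab0$A_PID <- rep(tab$A_PID[1:20], 3)
  res0 <- compare_groups(tab0, "A_PID")
  expect_true(all(res0$stars == ""))
  expect_false(any(res0$bonferroni))

  # row order of the table does not matter
  res_sh <- compare_groups(tab[sample(nrow(tab)), ], "A_PID")
  expect_equal(res_sh, res, tolerance = 1e-12, ignore_attr = TRUE)

  # percent change is relative to the first group's mean
  tab2 <- data.frame(group = rep(c("a", "b"), each = 3),
                     AA = c(99, 100, 101, 102.6, 103.6, 104.6))
  expect_equal(compare_groups(tab2, "AA")$percent_change, 3.6,
               tolerance = 1e-9)
  expect_error(compare_groups(tab, "nope"), "not present")
})

test_that("missing feature values are dropped pairwise with a count", {
  set.seed(53)
  tab <- data.frame(group = rep(c("a", "b"), each = 10),
                    AVAR = c(stats::rnorm(10), stats::rnorm(10)))
  tab$AVAR[c(3, 15)] <- NA
  res <- compare_groups(tab, "AVAR")
  expect_equal(res$n_dropped, 2)
  expect_false(is.na(res$p))
})

test_that("type-I error stays nominal under the null", {
  # pooled over seeds and pairs; feature values drawn from one Gaussian
  set.seed(54)
  flags <- 0; total <- 0
  for (rep in 1:300) {
    tab <- data.frame(group = rep(c("g1", "g2", "g3"), each = 20),
                      f = stats::rnorm(60))
    res <- compare_groups(tab, "f")
    flags <- flags + sum(res$p < 0.05)
    total <- total + nrow(res)
  }
  expect_gte(flags / total, 0.03)
  expect_lte(flags / total, 0.07)
})

test_that("the full-feature report runs over every biomarker column", {
  set.seed(55)
  tab <- simulate_cohort(cohort_config(seed = 3))
  res <- compare_all_features(tab)
  expect_equal(nrow(res), 7 * 3)
  expect_setequal(unique(res$feature),
                  c("AA", "VA", "AVAR", "T_PID", "A_PID", "V_PID",
                    "AV_PIDR"))
})
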