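test_that("signed test-retest difference is the symmetric percentage", {
  expect_equal(signed_td(5, 5), 0)
  expect_equal(signed_td(110, 90), 20)
  expect_equal(signed_td(90, 110), -20)
  # antisymmetry and boundedness for random positive pairs
  set.seed(3)
  a <- rlnorm(50); b <- rlnorm(50)
  expect_equal(signed_td(a, b), -signed_td(b, a))
  expect_true(all(abs(signed_td(a, b)) < 200))
  expect_error(signed_td(1, -1), "non-zero")
})

test_that("MA-TD takes the median absolute difference with its category", {
  same <- ma_td(c(4, 5, 6), c(4, 5, 6))
  expect_equal(same$ma_td, 0)
  expect_equal(same$category, "low")
  # absolute TDs {3,5,8,12,20} -> median 8, "low"; pairs constructed by
  # inverting signed_td at fixed test value
  d <- c(3, 5, 8, 12, 20)
  test <- rep(100, 5)
  retest <- test * (200 - d) / (200 + d)
  tds <- abs(signed_td(test, retest))
  expect_equal(sort(round(tds, 9)), c(3, 5, 8, 12, 20))
  m <- ma_td(test, retest)
  expect_equal(m$ma_td, 8)
  expect_equal(m$category, "low")
  # category boundaries are left-closed
  expect_equal(ma_td(110, 90)$category, "very high")
  expect_equal(ma_td(105, 95)$ma_td, 10)
  expect_equal(ma_td(105, 95)$category, "moderate")
})

test_that("BS-CV averages the two per-session coefficients of variation", {
  expect_equal(bs_cv(c(8, 10, 12), c(8, 10, 12)), 20)
  expect_equal(bs_cv(c(5, 5, 5), c(7, 7, 7)), 0)
  # sessions with CVs 10 and 14 average to 12
  s1 <- c(90, 100, 110); sd1 <- sd(s1) / mean(s1) * 100
  s2 <- s1 * 1.5
  scale2 <- 14 / (sd(s2) / mean(s2) * 100)
  s2 <- mean(s2) + (s2 - mean(s2)) * scale2 * 1.4
  # construct exactly: session CVs 10 and 14
  mk <- function(cv) { x <- c(-1, 0, 1); 100 + x * cv / (sd(x) / 1) }
  a <- mk(10); b <- mk(14)
  expect_equal(sd(a) / mean(a) * 100, 10, tolerance = 1e-12)
  expect_equal(bs_cv(a, b), 12, tolerance = 1e-12)
  # scale invariance
  expect_equal(bs_cv(3 * a, 3 * b), bs_cv(a, b), tolerance = 1e-12)
  expect_error(bs_cv(5, 5), "2 subjects")
})

test_that("one-way single-measures ICC matches the ANOVA oracle", {
  test <- c(10, 20, 30, 40, 50)
  retest <- c(12, 19, 33, 38, 52)
  r <- icc_oneway(test, retest)
  # independent oracle: one-way ANOVA via aov()
  df <- data.frame(
    y = c(test, retest),
    subj = factor(rep(seq_along(test), 2))
  )
  tab <- summary(stats::aov(y ~ subj, df))[[1]]
  ms_bs <- tab["subj", "Mean Sq"]
  ms_ws <- tab["Residuals", "Mean Sq"]
  expect_equal(r$ms_bs, ms_bs, tolerance = 1e-12)
  expect_equal(r$ms_ws, ms_ws, tolerance = 1e-12)
  expect_equal(r$icc, (ms_bs - ms_ws) / (ms_bs + ms_ws), tolerance = 1e-12)

  # retest == test with spread: ICC = 1
  expect_equal(icc_oneway(test, test)$icc, 1)
  # pure within-subject noise around a common mean: ICC <= 0 on this
  # constructed worst case
  expect_lte(icc_oneway(c(9, 11, 10), c(11, 9, 10))$icc, 0)
  expect_error(icc_oneway(5, 5), "2 subjects")
  expect_error(icc_oneway(c(1, 1), c(1, 1)), "Zero total variance")
})

test_that("ICC equals the ANOVA oracle on random instances", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    test <- rnorm(n, 10, 2)
    retest <- test + rnorm(n, 0, runif(1, 0.1, 3))
    r <- icc_oneway(test, retest)
    df <- data.frame(y = c(test, retest), subj = factor(rep(1:n, 2)))
    tab <- summary(stats::aov(y ~ subj, df))[[1]]
    icc_oracle <- (tab[1, 3] - tab[2, 3]) / (tab[1, 3] + tab[2, 3])
    expect_equal(r$icc, icc_oracle, tolerance = 1e-12)
  }
})

test_that("region summaries reproduce published medians and IQRs", {
  v1 <- c(acg = 0.91, fusiform = 0.71, hippocampus = 0.89,
          inferior_frontal = 0.88, insula = 0.90, occipital = 0.59)
  s1 <- summarize_by_region(v1, digits = 2)
  expect_equal(s1$median_display, 0.89)
  expect_equal(c(s1$q25_display, s1$q75_display), c(0.75, 0.90))

  v2 <- c(acg = 0.59, fusiform = 0.68, hippocampus = 0.95,
          inferior_frontal = 0.87, insula = 0.74, occipital = 0.63)
  s2 <- summarize_by_region(v2, digits = 2)
  expect_equal(s2$median_display, 0.71)
  expect_equal(c(s2$q25_display, s2$q75_display), c(0.64, 0.84))

  # six identical values: degenerate median and IQR
  v3 <- setNames(rep(4, 6), names(v1))
  s3 <- summarize_by_region(v3)
  expect_equal(c(s3$median, s3$q25, s3$q75), c(4, 4, 4))

  expect_error(summarize_by_region(v1[-1]), "Missing regions")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(24.5), 25)
  expect_equal(round_half_up(0.695, 2), 0.70)
  expect_equal(round_half_up(-0.465, 2), -0.47)
  expect_equal(round_half_up(0.885, 2), 0.89)
})

test_that("heterogeneity ratio categories use left-closed intervals", {
  expect_equal(heterogeneity_ratio(2.0, 1.0)$category, "very high")
  expect_equal(heterogeneity_ratio(1.8, 1.0)$category, "high")
  expect_equal(heterogeneity_ratio(1.5, 1.0)$category, "moderate")
  expect_equal(heterogeneity_ratio(1.0, 1.0)$category, "low")
  expect_equal(heterogeneity_ratio(9, 4)$ratio, 2.25)
  expect_error(heterogeneity_ratio(2, 0), "positive")
})

test_that("outlier rules differ between regional and voxelwise variants", {
  expect_false(flag_outliers(5, 20, "regional"))
  expect_true(flag_outliers(-0.1, 20, "regional"))
  expect_true(flag_outliers(5, 60, "regional"))
  expect_false(flag_outliers(5, 60, "voxelwise"))
  expect_true(flag_outliers(5, 120, "voxelwise"))
  expect_false(flag_outliers(5, NA, "regional"))
})
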