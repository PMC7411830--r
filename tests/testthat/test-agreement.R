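test_that("CV percent follows its definition and guards", {
  expect_equal(cv_percent(770, 94), 100 * 94 / 770)
  expect_equal(cv_percent(500, 0), 0)
  expect_error(cv_percent(0, 10), "positive mean")
  expect_error(cv_percent(100, -1), ">= 0")
})

test_that("Hedges's g reproduces printed summary-statistics cells", {
  # between-device effect sizes recomputed from published bias/SD/n rows
  expect_equal(round(hedges_g_from_summary(-3.80, 80.8, 81.1, 18, 18), 3), -0.046)
  expect_equal(round(hedges_g_from_summary(2.19, 17.3, 17.4, 18, 18), 3), 0.123)
  expect_equal(hedges_g_from_summary(0, 10, 12, 18, 18), 0)
  expect_error(hedges_g_from_summary(1, 0, 0, 18, 18), "pooled SD")
  expect_equal(hedges_g_from_summary(0, 0, 0, 18, 18), 0)
})

test_that("summary-based and raw-sample Hedges's g agree to 1e-12", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(18, 50, 15); y <- rnorm(18, 45, 14)
    expect_equal(hedges_g(x, y),
                 hedges_g_from_summary(mean(x) - mean(y), sd(x), sd(y), 18, 18),
                 tolerance = 1e-12)
  }
})

test_that("LCCC matches its moment-formula oracle and boundary cases", {
  x <- c(1, 2, 3, 4); y <- c(1.1, 2.1, 2.9, 4.2)
  got <- lccc(x, y, gate = FALSE)$estimate
  # direct evaluation of the concordance formula as oracle
  n <- 4
  oracle <- 2 * (sum((x - mean(x)) * (y - mean(y))) / n) /
    (sum((x - mean(x))^2) / n + sum((y - mean(y))^2) / n + (mean(x) - mean(y))^2)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(round(got, 4), 0.9931)
  expect_equal(lccc(x, x)$estimate, 1)
  z <- c(-2, -1, 1, 2)
  expect_equal(lccc(z, -z)$estimate, -1)
  expect_equal(lccc(rep(3, 5), rep(3, 5), gate = FALSE)$estimate, 1)
  expect_error(lccc(rep(3, 5), 1:5), "zero variance")
  expect_error(lccc(1:4, 1:5), "equal length")
})

test_that("LCCC magnitude never exceeds |Pearson r| and is shift-sensitive", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(30); y <- 0.8 * x + rnorm(30, 0, 0.5)
    l0 <- lccc(x, y, gate = FALSE)$estimate
    expect_lte(abs(l0), abs(cor(x, y)) + 1e-12)
    # adding a constant to one series strictly lowers concordance, not r
    l_shift <- lccc(x, y + 2, gate = FALSE)$estimate
    expect_lt(abs(l_shift), abs(l0))
    expect_equal(cor(x, y + 2), cor(x, y), tolerance = 1e-12)
  }
})

test_that("the Shapiro-Wilk gate marks non-normal metrics unavailable", {
  set.seed(1)
  xn <- rnorm(20, 50, 5)
  yn <- xn + rnorm(20, 0, 1)
  expect_true(lccc(xn, yn)$available)
  x_skew <- exp(rnorm(20, 0, 2))  # grossly lognormal
  res <- lccc(x_skew, xn)
  expect_false(res$available)
  expect_lte(res$normality_x, 0.05)
})

test_that("Bland-Altman matches the hand-worked example and identities", {
  ba <- bland_altman(c(10, 12, 14), c(9, 13, 13))
  expect_equal(ba$bias, 1 / 3, tolerance = 1e-9)
  expect_equal(ba$sd_diff, sd(c(1, -1, 1)), tolerance = 1e-9)
  expect_equal(ba$loa_upper, 1 / 3 + 1.96 * ba$sd_diff)
  expect_equal(ba$loa_lower, 1 / 3 - 1.96 * ba$sd_diff)
  expect_equal(round(c(ba$loa_upper, ba$loa_lower), 3), c(2.597, -1.930))
  # identical series: all-zero differences
  x <- c(50, 60, 70, 80)
  b0 <- bland_altman(x, x)
  expect_equal(c(b0$bias, b0$sd_diff, b0$ba_ratio), c(0, 0, 0))
  # constant offset: sd_diff collapses to zero for any offset
  for (c0 in c(-3, 5, 120)) {
    bo <- bland_altman(x + c0, x)
    expect_equal(bo$bias, c0)
    expect_equal(bo$sd_diff, 0)
    expect_equal(c(bo$loa_upper, bo$loa_lower), c(c0, c0))
  }
  expect_error(bland_altman(c(-10, -12, -14), c(10, 12, 14)), "mean of means")
})

test_that("Bland-Altman CIs use the t-based standard errors", {
  set.seed(3)
  x <- rnorm(18, 50, 8); y <- rnorm(18, 48, 8)
  ba <- bland_altman(x, y)
  tq <- qt(0.975, 17)
  expect_equal(ba$bias_ci[2] - ba$bias, tq * ba$sd_diff / sqrt(18))
  expect_equal(ba$loa_upper_ci[2] - ba$loa_upper, tq * ba$sd_diff * sqrt(3 / 18))
})

test_that("BA ratio reproduces printed cells from summary inputs", {
  expect_equal(round(ba_ratio_from_summary(4.58, 16.2, 11.5), 3), 0.648)
  expect_equal(round(ba_ratio_from_summary(45.4, 279, 220), 3), 0.357)
  expect_equal(ba_ratio_from_summary(0, 100, 100), 0)
  expect_error(ba_ratio_from_summary(1, -5, 3), "mean of means")
})

test_that("agreement labels follow the published thresholds", {
  expect_equal(classify_agreement(0.995, 0.05)$lccc_label, "almost perfect")
  expect_equal(classify_agreement(0.97, 0.05)$lccc_label, "substantial-to-moderate")
  expect_equal(classify_agreement(0.944, 0.05)$lccc_label, "poor")
  expect_equal(classify_agreement(NA, 0.05)$lccc_label, "n/a")
  expect_equal(classify_agreement(0.99, 0.042)$ba_label, "good")
  expect_equal(classify_agreement(0.99, 0.145)$ba_label, "moderate")
  expect_equal(classify_agreement(0.99, 0.331)$ba_label, "poor")
  # boundary convention: exactly 0.1 is moderate, exactly 0.2 is poor
  expect_equal(classify_agreement(0.99, 0.1)$ba_label, "moderate")
  expect_equal(classify_agreement(0.99, 0.2)$ba_label, "poor")
})

test_that("agreement_table assembles coherent per-metric rows", {
  set.seed(5)
  subjects <- sprintf("S%02d", 1:12)
  truth <- rnorm(12, 40, 10)
  feats <- rbind(
    feature_long(truth + rnorm(12, 2, 1), subjects, "ppg", "rest", "rmssd"),
    feature_long(truth, subjects, "ecg", "rest", "rmssd"),
    feature_long(truth * 20, subjects, "ppg", "rest", "lf"),
    feature_long(truth * 20 + rnorm(12, 0, 5), subjects, "ecg", "rest", "lf")
  )
  tab <- agreement_table(feats, task = "rest", metrics = c("rmssd", "lf"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n, c(12L, 12L))
  expect_gt(tab$bias[tab$metric == "rmssd"], 0)
  expect_equal(tab$loa_upper, tab$bias + 1.96 * tab$sd_diff)
  expect_true(all(tab$ba_ratio >= 0))
  expect_true(all(tab$lccc_label %in%
                    c("almost perfect", "substantial-to-moderate", "poor", "n/a")))
})
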