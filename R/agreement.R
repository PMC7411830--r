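#' Coefficient of variation, percent
#'
#' @param mean,sd summary statistics of a metric; `mean` must be positive.
#' @return 100*sd/mean.
#' @export
cv_percent <- function(mean, sd) {
  if (mean <= 0) stop("cv_percent requires a positive mean")
  if (sd < 0) stop("sd must be >= 0")
  100 * sd / mean
}

#' Hedges's g from group summary statistics
#'
#' Cohen's d (mean difference over the pooled SD, (n-1)-weighted pooling)
#' multiplied by the small-sample correction J = 1 - 3/(4*(n_a + n_b) - 9).
#' With equal group sizes the pooled SD reduces to sqrt((sd_a^2 + sd_b^2)/2),
#' which is how printed between-device effect sizes are reproduced from
#' published summary rows.
#'
#' @param mean_diff difference of group means (a minus b), metric units.
#' @param sd_a,sd_b group SDs.
#' @param n_a,n_b group sizes (>= 2).
#' @return Hedges's g, dimensionless.
#' @export
hedges_g_from_summary <- function(mean_diff, sd_a, sd_b, n_a, n_b) {
  if (n_a < 2 || n_b < 2) stop("group sizes must be >= 2")
  if (sd_a < 0 || sd_b < 0) stop("SDs must be >= 0")
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (pooled == 0) {
    if (mean_diff == 0) return(0)
    stop("pooled SD is zero with a nonzero mean difference")
  }
  j <- 1 - 3 / (4 * (n_a + n_b) - 9)
  mean_diff / pooled * j
}

#' Hedges's g from two raw samples
#'
#' Convenience wrapper computing group summaries and delegating to
#' [hedges_g_from_summary()], so the raw-sample and summary-based paths are
#' identical by construction.
#'
#' @param x,y numeric samples (device a, device b).
#' @return Hedges's g.
#' @export
hedges_g <- function(x, y) {
  hedges_g_from_summary(mean(x) - mean(y), sd(x), sd(y), length(x), length(y))
}

#' Lin's concordance correlation coefficient with a normality gate
#'
#' LCCC = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2) with population
#' (1/n) moments. Unlike Pearson's r it penalises location and scale shift,
#' so it measures agreement rather than association. Following the practice
#' of reporting "-" for non-normal metrics, the estimate is marked
#' unavailable when either variable fails the Shapiro-Wilk test at
#' p <= 0.05 (the numeric estimate is still returned for inspection).
#'
#' @param x,y equal-length paired samples (length >= 4).
#' @param gate apply the Shapiro-Wilk availability gate (default TRUE).
#' @return list with `estimate`, `available`, `normality_x`, `normality_y`
#'   (Shapiro-Wilk p-values).
#' @export
lccc <- function(x, y, gate = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("lccc requires at least 4 pairs")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    # both constant with equal means: perfect agreement by convention
    est <- 1
  } else if (sx2 == 0 || sy2 == 0) {
    stop("lccc undefined: one variable has zero variance")
  } else {
    est <- 2 * sxy / denom
  }
  px <- if (sx2 > 0) shapiro.test(x)$p.value else NA_real_
  py <- if (sy2 > 0) shapiro.test(y)$p.value else NA_real_
  available <- !gate || (is.na(px) || px > 0.05) && (is.na(py) || py > 0.05)
  list(estimate = est, available = available,
       normality_x = px, normality_y = py)
}

#' Bland-Altman agreement analysis on paired samples
#'
#' Differences are taken as `x - y` (test device minus reference). Reports
#' the bias (mean difference), the sample SD of the differences, the limits
#' of agreement bias +/- 1.96*SD, 95% confidence intervals for the bias
#' (t * SD/sqrt(n)) and for each limit (t * SD * sqrt(3/n), the classical
#' approximation), the Bland-Altman ratio (half the LoA range over the mean
#' of the two method means) and the Shapiro-Wilk p-value of the differences
#' (reported, not gating).
#'
#' @param x,y equal-length paired samples (length >= 3).
#' @return list with `bias`, `sd_diff`, `loa_upper`, `loa_lower`, `bias_ci`,
#'   `loa_upper_ci`, `loa_lower_ci`, `ba_ratio`, `normality_diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("bland_altman requires at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  sd_diff <- sd(d)
  loa_u <- bias + 1.96 * sd_diff
  loa_l <- bias - 1.96 * sd_diff
  tq <- qt(0.975, n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(3 / n)
  mean_of_means <- (mean(x) + mean(y)) / 2
  if (mean_of_means <= 0) stop("Bland-Altman ratio undefined: mean of means <= 0")
  p_d <- if (sd_diff > 0) shapiro.test(d)$p.value else NA_real_
  list(
    bias = bias, sd_diff = sd_diff,
    loa_upper = loa_u, loa_lower = loa_l,
    bias_ci = c(bias - tq * se_bias, bias + tq * se_bias),
    loa_upper_ci = c(loa_u - tq * se_loa, loa_u + tq * se_loa),
    loa_lower_ci = c(loa_l - tq * se_loa, loa_l + tq * se_loa),
    ba_ratio = 1.96 * sd_diff / mean_of_means,
    normality_diff = p_d
  )
}

#' Bland-Altman ratio from summary statistics
#'
#' Half the limits-of-agreement range (1.96 * SD of the differences) divided
#' by the mean of the two method means.
#'
#' @param sd_diff SD of the paired differences.
#' @param mean_a,mean_b the two method means.
#' @return the BA ratio, dimensionless.
#' @export
ba_ratio_from_summary <- function(sd_diff, mean_a, mean_b) {
  if (sd_diff < 0) stop("sd_diff must be >= 0")
  denom <- (mean_a + mean_b) / 2
  if (denom <= 0) stop("BA ratio undefined: mean of means <= 0")
  1.96 * sd_diff / denom
}

#' Categorical agreement labels
#'
#' LCCC labels (conservative reading of McBride's guideline): almost perfect
#' above 0.99, substantial-to-moderate in (0.95, 0.99], poor below 0.95,
#' `n/a` when the LCCC is unavailable. BA-ratio labels: good below 0.1,
#' moderate in [0.1, 0.2), poor at or above 0.2 (a ratio of exactly 0.1 is
#' moderate).
#'
#' @param lccc LCCC estimate in [-1, 1], or NA when unavailable.
#' @param ba_ratio Bland-Altman ratio, >= 0.
#' @return list with `lccc_label` and `ba_label`.
#' @export
classify_agreement <- function(lccc, ba_ratio) {
  lccc_label <- if (is.na(lccc)) {
    "n/a"
  } else if (lccc > 0.99) {
    "almost perfect"
  } else if (lccc > 0.95) {
    "substantial-to-moderate"
  } else {
    "poor"
  }
  if (is.na(ba_ratio) || ba_ratio < 0) stop("ba_ratio must be a non-negative number")
  ba_label <- if (ba_ratio < 0.1) "good" else if (ba_ratio < 0.2) "moderate" else "poor"
  list(lccc_label = lccc_label, ba_label = ba_label)
}

#' Per-metric agreement battery over a cohort feature table
#'
#' For each HRV metric, pairs the per-subject values of the test device
#' against the reference device within one task and computes the full
#' agreement row: per-device mean/SD, CV difference (test minus reference),
#' Hedges's g, gated LCCC, Bland-Altman bias/LoA/ratio, and the categorical
#' labels.
#'
#' @param features long-format data frame with columns `subject`, `device`,
#'   `task`, `metric`, `value`.
#' @param task which task to analyse.
#' @param device_a,device_b test and reference device names.
#' @param metrics metrics to include, in row order.
#' @return data frame, one row per metric.
#' @export
agreement_table <- function(features, task,
                            device_a = "ppg", device_b = "ecg",
                            metrics = c("mean_int", "sdnn", "pnn50", "rmssd",
                                        "lf", "hf", "sd1", "sd2")) {
  stopifnot(all(c("subject", "device", "task", "metric", "value") %in% names(features)))
  sub <- features[features$task == task & features$metric %in% metrics, ]
  rows <- lapply(metrics, function(m) {
    a <- sub[sub$metric == m & sub$device == device_a, ]
    b <- sub[sub$metric == m & sub$device == device_b, ]
    common <- intersect(a$subject, b$subject)
    x <- a$value[match(common, a$subject)]
    y <- b$value[match(common, b$subject)]
    lc <- lccc(x, y)
    ba <- bland_altman(x, y)
    labels <- classify_agreement(if (lc$available) lc$estimate else NA_real_,
                                 ba$ba_ratio)
    data.frame(
      metric = m, n = length(common),
      mean_a = mean(x), sd_a = sd(x), mean_b = mean(y), sd_b = sd(y),
      cv_diff = cv_percent(mean(x), sd(x)) - cv_percent(mean(y), sd(y)),
      hedges_g = hedges_g(x, y),
      lccc = lc$estimate, lccc_available = lc$available,
      normality_a = lc$normality_x, normality_b = lc$normality_y,
      bias = ba$bias, sd_diff = ba$sd_diff,
      loa_upper = ba$loa_upper, loa_lower = ba$loa_lower,
      ba_ratio = ba$ba_ratio, normality_diff = ba$normality_diff,
      lccc_label = labels$lccc_label, ba_label = labels$ba_label,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
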