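#' Paired Wilcoxon signed-rank test with direction
#'
#' Two-sided signed-rank test on paired rest/stress samples. Zero differences
#' are dropped before ranking (standard convention). With at most 12 nonzero
#' differences the exact null is obtained by full enumeration of all 2^n sign
#' assignments (midranks for tied absolute differences, so exactness is kept
#' under ties); with 13-25 untied differences the standard exact distribution
#' is used; otherwise the normal approximation with continuity correction.
#' Direction is the sign of the median paired difference, stress minus rest:
#' a decrease under stress is reported as a down arrow.
#'
#' @param rest,stress equal-length paired samples (by subject), length >= 6.
#' @return list with `p_value`, `direction` (one of `"down"`, `"up"`, `"eq"`),
#'   and `n_effective` (nonzero differences used).
#' @export
wilcoxon_paired <- function(rest, stress) {
  if (length(rest) != length(stress)) stop("samples must be paired (equal length)")
  if (length(rest) < 6L) stop("at least 6 pairs are required")
  d <- stress - rest
  md <- median(d)
  direction <- if (md < 0) "down" else if (md > 0) "up" else "eq"
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    return(list(p_value = 1, direction = "eq", n_effective = 0L))
  }
  n <- length(nz)
  if (n <= 12L) {
    # full enumeration of sign assignments, midranks under ties
    r <- rank(abs(nz))
    w_obs <- sum(r[nz > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
  } else {
    use_exact <- n <= 25L && !any(duplicated(abs(nz)))
    p <- suppressWarnings(
      wilcox.test(stress, rest, paired = TRUE, exact = use_exact,
                  correct = !use_exact)$p.value
    )
  }
  list(p_value = min(1, p), direction = direction, n_effective = n)
}

#' Common-language effect size
#'
#' The probability that a value sampled at random from `rest` exceeds one
#' sampled at random from `stress`, with ties counted half, evaluated over
#' all cross pairs.
#'
#' @param rest,stress non-empty numeric samples.
#' @return probability in [0, 1].
#' @export
cles <- function(rest, stress) {
  if (length(rest) == 0L || length(stress) == 0L) stop("samples must be non-empty")
  gt <- outer(rest, stress, `>`)
  eq <- outer(rest, stress, `==`)
  mean(gt + 0.5 * eq)
}

#' Rest-versus-stress comparison table per device
#'
#' For each device and metric, pairs the per-subject feature values of the
#' two tasks and reports direction, two-sided Wilcoxon signed-rank p-value,
#' significance at p < 0.05 and the common-language effect size
#' P(rest > stress). SD1 is excluded (redundant with RMSSD); the LF/HF ratio
#' is included. Subjects missing either task record are dropped with a
#' warning.
#'
#' @param features long-format data frame with columns `subject`, `device`,
#'   `task`, `metric`, `value`; tasks `"rest"` and `"stress"`.
#' @param metrics metrics to compare, in row order.
#' @return data frame, one row per (device, metric).
#' @export
compare_tasks <- function(features,
                          metrics = c("mean_int", "sdnn", "pnn50", "rmssd",
                                      "lf", "hf", "lf_hf", "sd2")) {
  stopifnot(all(c("subject", "device", "task", "metric", "value") %in% names(features)))
  devices <- unique(features$device)
  rows <- list()
  for (dev in devices) {
    for (m in metrics) {
      r <- features[features$device == dev & features$metric == m &
                      features$task == "rest", ]
      s <- features[features$device == dev & features$metric == m &
                      features$task == "stress", ]
      common <- intersect(r$subject, s$subject)
      dropped <- length(union(r$subject, s$subject)) - length(common)
      if (dropped > 0) {
        warning(sprintf("%s/%s: dropped %d subject(s) missing a task record",
                        dev, m, dropped))
      }
      x <- r$value[match(common, r$subject)]
      y <- s$value[match(common, s$subject)]
      w <- wilcoxon_paired(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        device = dev, metric = m, n = length(common),
        direction = w$direction, p_value = w$p_value,
        significant = w$p_value < 0.05,
        cles = cles(x, y),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Box-plot summary following the study's plotting convention
#'
#' Median, 25th/75th percentiles, whisker limits at quartile +/- 1.5*IQR,
#' and the values falling outside those limits (outliers).
#'
#' @param values numeric sample.
#' @return list with `q1`, `median`, `q3`, `lo_whisker`, `hi_whisker`,
#'   `outliers`.
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0L) stop("empty sample")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(q1 = q[1], median = q[2], q3 = q[3],
       lo_whisker = lo, hi_whisker = hi,
       outliers = values[values < lo | values > hi])
}
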