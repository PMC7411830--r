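#' Flag abnormal interbeat intervals
#'
#' An interval is abnormal if it lies outside the plausible range
#' (350-1350 ms, reason `"range"`) or if it deviates by strictly more than
#' 20% from the mean of its two original neighbours (reason `"deviation"`;
#' the first and last intervals are tested by the range rule only). Flags are
#' computed in a single pass against the original, uncorrected neighbours.
#' An interval caught by both rules is reported once, as `"range"`.
#'
#' @param series numeric intervals, ms.
#' @param lower,upper plausible range bounds, ms.
#' @param dev_frac neighbour-deviation fraction (strict inequality).
#' @return data frame with columns `index` and `reason`, sorted by index.
#' @export
flag_abnormal <- function(series, lower = 350, upper = 1350, dev_frac = 0.20) {
  check_intervals(series, 1L)
  n <- length(series)
  range_bad <- which(series < lower | series > upper)
  dev_bad <- integer(0)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    m <- (series[i - 1L] + series[i + 1L]) / 2
    dev_bad <- i[abs(series[i] - m) > dev_frac * m]
  }
  dev_bad <- setdiff(dev_bad, range_bad)
  df <- data.frame(
    index = c(range_bad, dev_bad),
    reason = rep(c("range", "deviation"), c(length(range_bad), length(dev_bad))),
    stringsAsFactors = FALSE
  )
  df[order(df$index), , drop = FALSE]
}

#' Repair flagged intervals by linear interpolation
#'
#' Each maximal run of flagged intervals is replaced by values interpolated
#' linearly between the nearest unflagged neighbour on each side. Runs
#' touching either end of the series have no anchor on one side; they are
#' trimmed and reported as unrepairable spans (mirroring the handling of
#' terminal recording gaps).
#'
#' @param series numeric intervals, ms.
#' @param flags data frame from [flag_abnormal()], or an integer vector of
#'   flagged indices.
#' @return the corrected numeric series, with attribute `unrepairable` (a
#'   list of trimmed `c(start, end)` spans, possibly empty).
#' @export
correct_intervals <- function(series, flags) {
  check_intervals(series, 1L)
  idx <- if (is.data.frame(flags)) flags$index else as.integer(flags)
  idx <- sort(unique(idx))
  if (length(idx) == 0L) {
    out <- series
    attr(out, "unrepairable") <- list()
    return(out)
  }
  n <- length(series)
  if (any(idx < 1L | idx > n)) stop("flag indices out of range")
  if (length(idx) == n) stop("all intervals flagged: nothing to interpolate from")
  flagged <- rep(FALSE, n)
  flagged[idx] <- TRUE
  out <- series
  unrepairable <- list()
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  drop <- rep(FALSE, n)
  for (k in which(runs$values)) {
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == n) {
      unrepairable[[length(unrepairable) + 1L]] <- c(s, e)
      drop[s:e] <- TRUE
    } else {
      left <- series[s - 1L]; right <- series[e + 1L]
      j <- seq_len(e - s + 1L)
      out[s:e] <- left + (right - left) * j / (e - s + 2L)
    }
  }
  out <- out[!drop]
  attr(out, "unrepairable") <- unrepairable
  out
}

#' One-pass quality-control summary of an interval series
#'
#' Runs [flag_abnormal()] then [correct_intervals()] and reports the counts
#' in the style of a per-device error table: total intervals, flagged
#' indices with reasons, and the percentage flagged rounded to two decimals.
#'
#' @param series numeric intervals, ms.
#' @param ... passed to [flag_abnormal()] (bounds, deviation fraction).
#' @return list with `n_total`, `flags`, `n_flagged`, `pct_flagged`,
#'   `corrected` and `unrepairable_spans`.
#' @export
qc_summary <- function(series, ...) {
  check_intervals(series, 1L)
  flags <- flag_abnormal(series, ...)
  corrected <- correct_intervals(series, flags)
  list(
    n_total = length(series),
    flags = flags,
    n_flagged = nrow(flags),
    pct_flagged = round(100 * nrow(flags) / length(series), 2),
    corrected = as.numeric(corrected),
    unrepairable_spans = attr(corrected, "unrepairable")
  )
}
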