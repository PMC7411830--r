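#' Time-domain HRV metrics
#'
#' Mean interval, SDNN (sample SD, n-1 denominator), pNN50 (percentage of
#' successive differences strictly greater than 50 ms in absolute value) and
#' RMSSD (root mean square of successive differences).
#'
#' @param series numeric intervals, ms.
#' @return list with `mean_int`, `sdnn`, `pnn50`, `rmssd`.
#' @export
time_domain <- function(series) {
  check_intervals(series, 2L)
  d <- diff(series)
  list(
    mean_int = mean(series),
    sdnn = sd(series),
    pnn50 = 100 * mean(abs(d) > 50),
    rmssd = sqrt(mean(d^2))
  )
}

#' Lomb-Scargle periodogram for unevenly sampled series
#'
#' Classical tau-shifted Lomb-Scargle normalised so that (after the rescaling
#' applied in [spectral_bands()]) band integrals are in ms^2. Frequencies are
#' processed in blocks to bound memory.
#'
#' @param t sample times, s.
#' @param y sample values (centred internally).
#' @param freqs frequency grid, Hz (all > 0).
#' @return numeric vector of raw periodogram powers, one per frequency.
#' @export
lomb_scargle <- function(t, y, freqs) {
  stopifnot(length(t) == length(y), all(freqs > 0))
  y <- y - mean(y)
  p <- numeric(length(freqs))
  block <- 256L
  for (i0 in seq(1L, length(freqs), by = block)) {
    i1 <- min(i0 + block - 1L, length(freqs))
    w <- 2 * pi * freqs[i0:i1]
    wt <- outer(t, w)                       # n x m
    s2 <- colSums(sin(2 * wt)); c2 <- colSums(cos(2 * wt))
    tau_w <- atan2(s2, c2) / 2              # omega * tau
    arg <- sweep(wt, 2L, tau_w, `-`)
    ca <- cos(arg); sa <- sin(arg)
    yc <- colSums(y * ca); ys <- colSums(y * sa)
    cc <- colSums(ca^2); ss <- colSums(sa^2)
    p[i0:i1] <- 0.5 * (yc^2 / cc + ifelse(ss > 0, ys^2 / ss, 0))
  }
  p
}

#' Frequency-domain HRV metrics from the Lomb-Scargle periodogram
#'
#' The mean-centred intervals are evaluated at their cumulative beat times
#' (interval i assigned to the time of its terminating beat, first beat at
#' t = x1), and the Lomb-Scargle periodogram is computed on a fixed grid
#' (default 0.003-0.4 Hz, step 0.0005 Hz). The spectrum is rescaled so its
#' trapezoidal integral over the full grid equals the sample variance of the
#' intervals, making band integrals absolute powers in ms^2. LF is the
#' integral over 0.04-0.15 Hz and HF over 0.15-0.4 Hz; the very-low-frequency
#' band is computed as part of the grid but not reported.
#'
#' @param series numeric intervals, ms; at least 30 intervals spanning at
#'   least 60 s.
#' @param f_min,f_max,df frequency grid, Hz.
#' @param lf_band,hf_band band edges, Hz.
#' @return list with `lf`, `hf` (ms^2), `lf_hf` (NA when `hf` is 0), and the
#'   grid `freq`/`power` for plotting.
#' @export
spectral_bands <- function(series, f_min = 0.003, f_max = 0.4, df = 0.0005,
                           lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4)) {
  check_intervals(series, 30L)
  t <- cumsum(series) / 1000
  if (max(t) - min(t) < 60) stop("record must span at least 60 s for spectral analysis")
  v <- var(series)
  freqs <- seq(f_min, f_max, by = df)
  if (v == 0) {
    return(list(lf = 0, hf = 0, lf_hf = NA_real_,
                freq = freqs, power = numeric(length(freqs))))
  }
  p <- lomb_scargle(t, series, freqs)
  total <- trapz(freqs, p)
  scale <- if (total > 0) v / total else 0
  p <- p * scale
  band_power <- function(band) {
    in_band <- freqs >= band[1] & freqs <= band[2]
    trapz(freqs[in_band], p[in_band])
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  list(lf = lf, hf = hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_,
       freq = freqs, power = p)
}

#' Poincare plot dispersion metrics SD1 and SD2
#'
#' From the lag-1 scatter of (x[i], x[i+1]): SD1, the dispersion across the
#' identity line, is RMSSD/sqrt(2) (the mean successive difference is treated
#' as zero, the standard short-term convention, which makes the identity
#' exact); SD2, the dispersion along the identity line, is the population SD
#' of (x[i] + x[i+1])/sqrt(2).
#'
#' @param series numeric intervals, ms; length >= 3.
#' @return list with `sd1` and `sd2`, ms.
#' @export
poincare <- function(series) {
  check_intervals(series, 3L)
  d <- diff(series)
  s <- (series[-length(series)] + series[-1]) / sqrt(2)
  list(
    sd1 = sqrt(mean(d^2)) / sqrt(2),
    sd2 = sqrt(mean((s - mean(s))^2))
  )
}

#' Full nine-metric short-term HRV feature set
#'
#' @param series numeric intervals, ms (a five-minute record in typical use).
#' @return one-row data frame: `mean_int`, `sdnn`, `pnn50`, `rmssd`, `lf`,
#'   `hf`, `lf_hf`, `sd1`, `sd2`.
#' @export
hrv_features <- function(series) {
  td <- time_domain(series)
  sp <- spectral_bands(series)
  pc <- poincare(series)
  data.frame(
    mean_int = td$mean_int, sdnn = td$sdnn, pnn50 = td$pnn50, rmssd = td$rmssd,
    lf = sp$lf, hf = sp$hf, lf_hf = sp$lf_hf,
    sd1 = pc$sd1, sd2 = pc$sd2
  )
}

#' Descriptive statistics of a pooled interval sample
#'
#' Minimum, maximum, mean, sample SD, skewness, excess kurtosis and the
#' coefficient of variation (100*SD/mean), as reported for pooled per-group
#' interval histograms.
#'
#' @param series numeric intervals, ms.
#' @return one-row data frame with `n`, `min`, `max`, `mean`, `sd`,
#'   `skewness`, `kurtosis`, `cv`.
#' @export
descriptives <- function(series) {
  check_intervals(series, 2L)
  m <- mean(series)
  s <- sd(series)
  z <- series - m
  m2 <- mean(z^2)
  data.frame(
    n = length(series), min = min(series), max = max(series),
    mean = m, sd = s,
    skewness = if (m2 > 0) mean(z^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(z^4) / m2^2 - 3 else 0,
    cv = 100 * s / m
  )
}
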