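#' Zero-phase 2nd-order Butterworth low-pass at 5 Hz
#'
#' Re-implements the sensor's front-end filter offline: a second-order
#' Butterworth low-pass (5 Hz cutoff by default) applied forward and backward
#' so the pass is zero-phase and the effective magnitude response is the
#' squared single-pass response. The input is reflection-padded (odd
#' extension) before filtering to suppress edge transients; output length
#' equals input length.
#'
#' @param samples numeric waveform samples.
#' @param fs sampling rate, Hz; must exceed twice the cutoff.
#' @param cutoff low-pass cutoff, Hz.
#' @return filtered samples, same length as the input.
#' @export
lowpass_5hz <- function(samples, fs, cutoff = 5) {
  if (fs <= 2 * cutoff) stop("fs must exceed twice the filter cutoff")
  n <- length(samples)
  if (n < 4L) stop("waveform too short to filter")
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  npad <- min(n - 1L, as.integer(round(fs)))  # up to 1 s of padding
  # odd (point-symmetric) extension at both ends
  left <- 2 * samples[1L] - samples[(npad + 1L):2L]
  right <- 2 * samples[n] - samples[(n - 1L):(n - npad)]
  ext <- c(left, samples, right)
  fwd <- signal::filter(bf, ext)
  bwd <- rev(signal::filter(bf, rev(fwd)))
  as.numeric(bwd[(npad + 1L):(npad + n)])
}

# sliding-window maximum, centered, O(n) (van Herk/Gil-Werman via blockwise
# prefix/suffix cummax); window length k is forced odd
running_max <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L || n == 0L) return(x)
  h <- (k - 1L) %/% 2L
  xp <- c(rep(-Inf, h), x, rep(-Inf, h + k))  # pad to cover edges + block slack
  m <- length(xp)
  nb <- ceiling(m / k)
  xp <- c(xp, rep(-Inf, nb * k - m))
  mat <- matrix(xp, nrow = k)
  fwd <- apply(mat, 2L, cummax)
  bwd <- apply(mat[k:1L, , drop = FALSE], 2L, cummax)[k:1L, , drop = FALSE]
  fwdv <- as.numeric(fwd); bwdv <- as.numeric(bwd)
  # window starting at position j (length k): max(bwd[j], fwd[j + k - 1])
  starts <- seq_len(n)  # padded index of window centered on x[i] starts at i
  pmax(bwdv[starts], fwdv[starts + k - 1L])
}

#' Detect PP intervals from a PPG waveform
#'
#' Re-implements the sensor's on-board interval detection: low-pass filter,
#' first derivative (forward difference scaled by `fs`), squaring, then peak
#' picking on the squared derivative above a dynamic threshold. The threshold
#' is `threshold_frac` times the rolling maximum of the squared derivative
#' over a sliding window (2 s by default), recomputed per sample, so detection
#' is invariant to any positive rescaling of the waveform. The default
#' fraction (0.3) leaves headroom for beat-to-beat pulse-amplitude variation:
#' squaring doubles relative amplitude swings, so a +/-20% amplitude swing
#' already drops a weak beat to ~0.44 of a neighbouring strong one. Of peaks
#' closer than the refractory period (350 ms, cohering with the lower
#' physiological plausibility bound on intervals) only the first is kept: the
#' systolic upstroke always precedes the diastolic decay, so this locks
#' detection onto the rising edge even when low-pass smearing leaves the two
#' edge peaks nearly equal.
#'
#' @param samples numeric waveform samples.
#' @param fs sampling rate, Hz.
#' @param threshold_frac fraction of the rolling maximum used as threshold.
#' @param window_s rolling-maximum window length, s.
#' @param refractory_ms minimum separation between detected beats, ms.
#' @return list with `beat_times` (ms), `intervals` (ms),
#'   `threshold_trace` and `status` (`"ok"` or `"no_peaks"`).
#' @export
detect_pp_intervals <- function(samples, fs, threshold_frac = 0.3,
                                window_s = 2, refractory_ms = 350) {
  if (length(samples) / fs < 2) stop("record must span at least 2 s")
  filt <- lowpass_5hz(samples, fs)
  d <- diff(filt) * fs
  sq <- d^2
  thr <- threshold_frac * running_max(sq, round(window_s * fs))
  # floor relative to the signal scale (not the derivative scale), so a
  # constant waveform whose derivative is pure rounding noise yields no
  # peaks while detection stays invariant to amplitude rescaling
  peak_floor <- (1e-8 * fs * max(abs(filt)))^2
  n <- length(sq)
  empty <- list(beat_times = numeric(0), intervals = numeric(0),
                threshold_trace = thr, status = "no_peaks")
  if (max(sq) <= peak_floor) {
    warning("no peaks found in squared derivative (flat signal)")
    return(empty)
  }
  i <- 2:(n - 1L)
  cand <- i[sq[i] >= thr[i] & sq[i] > peak_floor &
              sq[i] > sq[i - 1L] & sq[i] >= sq[i + 1L]]
  if (length(cand) == 0L) {
    warning("no peaks found above the dynamic threshold")
    return(empty)
  }
  refr <- refractory_ms * fs / 1000
  kept <- cand[1L]
  for (p in cand[-1L]) {
    if (p - kept[length(kept)] >= refr) kept <- c(kept, p)
  }
  beat_times <- kept / fs * 1000
  list(beat_times = beat_times,
       intervals = diff(beat_times),
       threshold_trace = thr,
       status = "ok")
}
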