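#' Configuration for the synthetic dual-sensor cohort generator
#'
#' Defines the study conditions emulated by the generator: paired five-minute
#' RR (ECG-like) and PP (PPG-like) interbeat records per subject, under a rest
#' and a mental-stress condition. Interval dynamics are modelled directly at
#' the interval level as a mean plus low-frequency (LF) and high-frequency
#' (HF) sinusoidal modulation plus white noise. The PP channel additionally
#' carries pulse-transit-time (PTT) jitter on each pulse arrival, which enters
#' the intervals as a first difference of white noise - the mechanism that
#' inflates short-term variability metrics (pNN50, RMSSD, HF) on the PPG side
#' far more than SDNN/LF/SD2.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param duration_s record length per task in seconds (five-minute tasks).
#' @param mean_rr baseline mean interbeat interval, ms; must lie in the
#'   physiologically plausible 350-1350 ms range.
#' @param a_lf,f_lf amplitude (ms) and frequency (Hz) of the LF modulation;
#'   `f_lf` must lie in the LF band 0.04-0.15 Hz.
#' @param a_hf,f_hf amplitude (ms) and frequency (Hz) of the HF
#'   (respiratory-like) modulation; `f_hf` must lie in the HF band
#'   (0.15, 0.4] Hz.
#' @param noise_sd SD of white interval noise, ms.
#' @param ptt_jitter_sd SD of the per-beat pulse-arrival jitter applied to the
#'   PP channel, ms. The default was calibrated so that the synthetic cohort
#'   reproduces the qualitative agreement pattern seen in earlobe-PPG
#'   validation studies (good agreement for mean/SDNN/LF/SD2, poor for
#'   pNN50/RMSSD/HF).
#' @param artifact_rate per-interval probability of an injected artifact on
#'   the PP channel (the RR channel receives half this rate); must be < 0.1.
#' @param stress_multipliers named list with elements `mean_rr` and
#'   `amplitude`: factors applied to the mean interval and to every
#'   modulation/noise amplitude under the stress condition (both < 1:
#'   shorter intervals, reduced variability).
#' @param mean_rr_between_sd between-subject SD of the subject-level mean
#'   interval, ms.
#' @param subject_cv between-subject coefficient of variation of the
#'   modulation amplitudes (lognormal).
#' @param max_true_lag maximum absolute device lag, in whole beats, injected
#'   between the RR and PP streams of a subject.
#' @param seed master seed; per-subject streams are spawned from it.
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_subjects = 18,
                             duration_s = 300,
                             mean_rr = 780,
                             a_lf = 35, f_lf = 0.10,
                             a_hf = 28, f_hf = 0.25,
                             noise_sd = 10,
                             ptt_jitter_sd = 8,
                             artifact_rate = 0.002,
                             stress_multipliers = list(mean_rr = 0.95, amplitude = 0.85),
                             mean_rr_between_sd = 60,
                             subject_cv = 0.25,
                             max_true_lag = 3,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), duration_s = duration_s,
    mean_rr = mean_rr, a_lf = a_lf, f_lf = f_lf, a_hf = a_hf, f_hf = f_hf,
    noise_sd = noise_sd, ptt_jitter_sd = ptt_jitter_sd,
    artifact_rate = artifact_rate, stress_multipliers = stress_multipliers,
    mean_rr_between_sd = mean_rr_between_sd, subject_cv = subject_cv,
    max_true_lag = as.integer(max_true_lag), seed = as.integer(seed)
  )
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (cfg$duration_s <= 0) stop("duration_s must be positive")
  if (cfg$mean_rr < 350 || cfg$mean_rr > 1350) {
    stop("mean_rr must lie within the plausible 350-1350 ms range")
  }
  if (cfg$f_lf < 0.04 || cfg$f_lf > 0.15) stop("f_lf must lie in the LF band [0.04, 0.15] Hz")
  if (cfg$f_hf <= 0.15 || cfg$f_hf > 0.4) stop("f_hf must lie in the HF band (0.15, 0.4] Hz")
  for (nm in c("a_lf", "a_hf", "noise_sd", "ptt_jitter_sd",
               "mean_rr_between_sd", "subject_cv")) {
    if (cfg[[nm]] < 0) stop(sprintf("%s must be >= 0", nm))
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate >= 0.1) {
    stop("artifact_rate must be in [0, 0.1)")
  }
  sm <- cfg$stress_multipliers
  if (!is.list(sm) || is.null(sm$mean_rr) || is.null(sm$amplitude) ||
      sm$mean_rr <= 0 || sm$amplitude < 0) {
    stop("stress_multipliers must provide positive 'mean_rr' and non-negative 'amplitude'")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate an RR (ECG-like) interbeat interval series
#'
#' Intervals follow `mean_rr + a_lf*sin(2*pi*f_lf*t) + a_hf*sin(2*pi*f_hf*t +
#' phi) + eps`, with `eps` white noise of SD `noise_sd`, the modulation
#' evaluated at the cumulative beat time at the start of each interval, and
#' the HF phase `phi` drawn uniformly once per series. The series is truncated
#' at `duration_s`. Under `condition = "stress"` the mean interval and every
#' amplitude are scaled by the configured stress multipliers.
#'
#' @param config a [synthetic_config()].
#' @param condition `"rest"` or `"stress"`.
#' @param seed optional override of `config$seed`.
#' @return numeric vector of intervals, ms.
#' @export
simulate_rr <- function(config, condition = c("rest", "stress"), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  condition <- match.arg(condition)
  mu <- config$mean_rr
  a_lf <- config$a_lf; a_hf <- config$a_hf; noise_sd <- config$noise_sd
  if (condition == "stress") {
    mu <- mu * config$stress_multipliers$mean_rr
    a_lf <- a_lf * config$stress_multipliers$amplitude
    a_hf <- a_hf * config$stress_multipliers$amplitude
    noise_sd <- noise_sd * config$stress_multipliers$amplitude
  }
  if (mu - a_lf - a_hf <= 0) {
    stop("modulation amplitudes a_lf + a_hf exceed the mean interval: intervals would be <= 0")
  }
  set.seed(seed)
  phi <- runif(1, 0, 2 * pi)
  dur_ms <- config$duration_s * 1000
  n_max <- ceiling(dur_ms / (mu - a_lf - a_hf)) + 1L
  eps <- rnorm(n_max, 0, noise_sd)
  intervals <- numeric(n_max)
  t_ms <- 0
  n <- 0L
  for (i in seq_len(n_max)) {
    t_s <- t_ms / 1000
    x <- mu + a_lf * sin(2 * pi * config$f_lf * t_s) +
      a_hf * sin(2 * pi * config$f_hf * t_s + phi) + eps[i]
    if (x <= 0) {
      stop("noise_sd produced a non-positive interval; reduce noise_sd relative to mean_rr")
    }
    t_ms <- t_ms + x
    if (t_ms > dur_ms) break
    n <- i
    intervals[i] <- x
  }
  intervals[seq_len(n)]
}

#' Derive a PP (PPG-like) series from an RR series by PTT jitter
#'
#' Each pulse arrival time is the beat time plus an independent Gaussian
#' pulse-transit-time term `eta` of SD `ptt_jitter_sd`, so the intervals become
#' `PP[i] = RR[i] + eta[i+1] - eta[i]`. The first-difference structure leaves
#' the total duration almost unchanged (it telescopes to `eta[n+1] - eta[1]`)
#' while inflating successive-difference statistics strongly:
#' `RMSSD(PP)^2 ~ RMSSD(RR)^2 + 6*sigma^2` but `SDNN(PP)^2 ~ SDNN(RR)^2 +
#' 2*sigma^2`.
#'
#' @param rr numeric RR intervals, ms.
#' @param ptt_jitter_sd SD of the per-beat arrival jitter, ms.
#' @param seed RNG seed.
#' @return numeric vector of PP intervals, same length as `rr`.
#' @export
derive_pp <- function(rr, ptt_jitter_sd, seed = 1L) {
  check_intervals(rr, 1L)
  if (ptt_jitter_sd < 0) stop("ptt_jitter_sd must be >= 0")
  if (ptt_jitter_sd == 0) return(rr)
  set.seed(seed)
  eta <- rnorm(length(rr) + 1L, 0, ptt_jitter_sd)
  pp <- rr + diff(eta)
  if (any(pp <= 0)) {
    stop("ptt_jitter_sd is too large: a derived PP interval would be <= 0")
  }
  pp
}

#' Inject artifacts into an interval series
#'
#' Interior intervals are independently corrupted with probability `rate`,
#' half by an out-of-range value (outside 350-1350 ms) and half by a spike
#' deviating well over 20% from the mean of its neighbours; both classes are
#' designed to be caught by [flag_abnormal()].
#'
#' @param series numeric intervals, ms.
#' @param rate per-interval corruption probability, in [0, 0.1).
#' @param seed RNG seed.
#' @return list with `intervals` (corrupted series) and `indices`
#'   (ground-truth corrupted positions, sorted).
#' @export
inject_artifacts <- function(series, rate, seed = 1L) {
  check_intervals(series, 1L)
  if (rate < 0 || rate >= 0.1) stop("rate must be in [0, 0.1)")
  n <- length(series)
  if (rate == 0 || n < 3L) return(list(intervals = series, indices = integer(0)))
  set.seed(seed)
  interior <- 2:(n - 1L)
  hit <- interior[runif(length(interior)) < rate]
  out <- series
  for (i in hit) {
    if (runif(1) < 0.5) {
      # out-of-range artifact: a dropped or doubled beat
      out[i] <- if (runif(1) < 0.5) runif(1, 150, 340) else runif(1, 1360, 2000)
    } else {
      # in-range spike deviating 30-60% from the neighbour mean
      m <- (series[i - 1L] + series[i + 1L]) / 2
      dev <- runif(1, 0.30, 0.60) * sample(c(-1, 1), 1)
      out[i] <- max(10, m * (1 + dev))
    }
  }
  list(intervals = out, indices = sort(hit))
}

#' Synthesize a PPG waveform from an interval series
#'
#' Places one smooth unimodal pulse template at each cumulative beat time and
#' adds white noise. The template is an asymmetric raised cosine - a fast
#' systolic upstroke (30% of the width) followed by a slower decay - so that,
#' as in a real pulse wave, the rising-edge slope dominates the derivative.
#' Only pulse timing is meaningful downstream.
#'
#' @param rr numeric intervals, ms.
#' @param fs sampling rate, Hz (>= 100).
#' @param pulse_width_s full width of the raised-cosine template, s; must be
#'   smaller than the shortest interval.
#' @param snr ratio of the unit pulse peak amplitude to the noise SD;
#'   `Inf` for a noise-free waveform.
#' @param amp_var fractional peak-to-peak amplitude variation across pulses
#'   (e.g. 0.2 for +/-20%).
#' @param seed RNG seed (noise and amplitude variation).
#' @return list with `samples`, `fs`, and `beat_times_ms` (ground truth
#'   template centres).
#' @export
synthesize_ppg <- function(rr, fs = 250, pulse_width_s = 0.15, snr = Inf,
                           amp_var = 0, seed = 1L) {
  if (length(rr) > 0) check_intervals(rr)
  if (fs < 100) stop("fs must be >= 100 Hz to resolve pulse timing")
  if (length(rr) > 0 && pulse_width_s >= min(rr) / 1000) {
    stop("pulse_width_s must be shorter than the shortest interval")
  }
  set.seed(seed)
  pad_s <- 0.5
  beat_t <- cumsum(rr) / 1000
  total_s <- if (length(rr)) max(beat_t) + pad_s else 2
  n <- ceiling(total_s * fs)
  t <- (seq_len(n) - 1L) / fs
  y <- numeric(n)
  amps <- 1 + runif(length(beat_t), -amp_var, amp_var)
  rise <- 0.3 * pulse_width_s   # systolic upstroke
  decay <- 0.7 * pulse_width_s  # diastolic decay
  for (k in seq_along(beat_t)) {
    i0 <- max(1L, floor((beat_t[k] - rise) * fs) + 1L)
    i1 <- min(n, ceiling((beat_t[k] + decay) * fs) + 1L)
    idx <- i0:i1
    u <- t[idx] - beat_t[k]
    up <- u >= -rise & u < 0
    dn <- u >= 0 & u < decay
    y[idx[up]] <- y[idx[up]] + amps[k] * 0.5 * (1 + cos(pi * u[up] / rise))
    y[idx[dn]] <- y[idx[dn]] + amps[k] * 0.5 * (1 + cos(pi * u[dn] / decay))
  }
  if (is.finite(snr)) y <- y + rnorm(n, 0, 1 / snr)
  list(samples = y, fs = fs, beat_times_ms = beat_t * 1000)
}

#' Simulate a full paired dual-sensor cohort
#'
#' For each subject draws a subject-level mean interval and modulation
#' amplitudes around the configured baselines, simulates rest and stress RR
#' series, derives the PP channel with PTT jitter, applies an integer device
#' lag (dropping leading beats of one channel) and injects artifacts. The
#' ground truth (lag, artifact indices, per-subject parameters) is carried in
#' each subject's `truth` record.
#'
#' @param config a [synthetic_config()].
#' @return list of subjects; each subject is a list with `subject_id`,
#'   `rr_rest`, `rr_stress`, `pp_rest`, `pp_stress` and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects * 8L)
  mean_rrs <- pmin(1200, pmax(500, rnorm(config$n_subjects, config$mean_rr,
                                         config$mean_rr_between_sd)))
  cv <- config$subject_cv
  a_lfs <- config$a_lf * exp(rnorm(config$n_subjects, -cv^2 / 2, cv))
  a_hfs <- config$a_hf * exp(rnorm(config$n_subjects, -cv^2 / 2, cv))
  lags <- sample(seq(-config$max_true_lag, config$max_true_lag),
                 config$n_subjects, replace = TRUE)
  lapply(seq_len(config$n_subjects), function(s) {
    cfg_s <- config
    cfg_s$mean_rr <- mean_rrs[s]
    cfg_s$a_lf <- a_lfs[s]
    cfg_s$a_hf <- a_hfs[s]
    sd0 <- sub_seeds[(s - 1L) * 8L + 1L]
    one_task <- function(condition, k) {
      rr <- simulate_rr(cfg_s, condition, seed = sub_seeds[(s - 1L) * 8L + k])
      pp <- derive_pp(rr, config$ptt_jitter_sd, seed = sub_seeds[(s - 1L) * 8L + k + 1L])
      # integer device lag: positive lag means the PP stream starts later
      lag <- lags[s]
      if (lag > 0) pp <- pp[-seq_len(lag)] else if (lag < 0) rr <- rr[-seq_len(-lag)]
      art_pp <- inject_artifacts(pp, config$artifact_rate,
                                 seed = sub_seeds[(s - 1L) * 8L + k + 2L])
      art_rr <- inject_artifacts(rr, config$artifact_rate / 2,
                                 seed = sub_seeds[(s - 1L) * 8L + k + 3L])
      list(rr = art_rr$intervals, pp = art_pp$intervals,
           artifact_idx_rr = art_rr$indices, artifact_idx_pp = art_pp$indices)
    }
    rest <- one_task("rest", 1L)
    stress <- one_task("stress", 5L)
    list(
      subject_id = sprintf("S%02d", s),
      rr_rest = rest$rr, pp_rest = rest$pp,
      rr_stress = stress$rr, pp_stress = stress$pp,
      truth = list(
        lag = lags[s], mean_rr = mean_rrs[s], a_lf = a_lfs[s], a_hf = a_hfs[s],
        artifact_idx = list(rr_rest = rest$artifact_idx_rr,
                            pp_rest = rest$artifact_idx_pp,
                            rr_stress = stress$artifact_idx_rr,
                            pp_stress = stress$artifact_idx_pp),
        seed = sd0
      )
    )
  })
}

#' Write a cohort to per-subject CSV files plus a JSON manifest
#'
#' One CSV per subject/device/task with columns `beat_index` (0-based) and
#' `interval_ms` (full double precision), and a `manifest.json` carrying the
#' ground-truth records.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(subjects = list())
  for (sub in cohort) {
    files <- list()
    for (ch in c("rr_rest", "pp_rest", "rr_stress", "pp_stress")) {
      x <- sub[[ch]]
      f <- file.path(dir, sprintf("%s_%s.csv", sub$subject_id, ch))
      con <- file(f, "w")
      writeLines("beat_index,interval_ms", con)
      writeLines(sprintf("%d,%.17g", seq_along(x) - 1L, x), con)
      close(con)
      files[[ch]] <- basename(f)
    }
    manifest$subjects[[sub$subject_id]] <- list(files = files, truth = sub$truth)
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the manifest and CSVs.
#' @return cohort in the same structure as [simulate_cohort()] returns.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(names(manifest$subjects), function(id) {
    entry <- manifest$subjects[[id]]
    out <- list(subject_id = id)
    for (ch in c("rr_rest", "pp_rest", "rr_stress", "pp_stress")) {
      df <- read.csv(file.path(dir, entry$files[[ch]]))
      out[[ch]] <- as.numeric(df$interval_ms)
    }
    out$truth <- entry$truth
    out
  })
}
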