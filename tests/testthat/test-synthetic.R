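test_that("degenerate no-modulation config yields a constant series of known length", {
  cfg <- synthetic_config(mean_rr = 800, a_lf = 0, a_hf = 0, noise_sd = 0)
  rr <- simulate_rr(cfg, "rest")
  expect_true(all(rr == 800))
  expect_length(rr, floor(300000 / 800))
})

test_that("generator output is a pure function of config and seed", {
  cfg <- synthetic_config(seed = 42L)
  expect_identical(simulate_rr(cfg, "rest"), simulate_rr(cfg, "rest"))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  expect_false(identical(simulate_rr(cfg, "rest", seed = 43L),
                         simulate_rr(cfg, "rest", seed = 42L)))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(f_lf = 0.2), "LF band")
  expect_error(synthetic_config(f_hf = 0.12), "HF band")
  expect_error(synthetic_config(mean_rr = 300), "350-1350")
  expect_error(synthetic_config(noise_sd = -1), ">= 0")
  expect_error(synthetic_config(artifact_rate = 0.2), "0.1")
  cfg <- synthetic_config(mean_rr = 400, a_lf = 250, a_hf = 200, noise_sd = 0)
  expect_error(simulate_rr(cfg, "rest"), "a_lf \\+ a_hf")
})

test_that("noise-free sinusoidal modulation meets the variance budget", {
  cfg <- synthetic_config(a_lf = 50, a_hf = 30, noise_sd = 0)
  rr <- simulate_rr(cfg, "rest")
  expect_equal(var(rr), (50^2 + 30^2) / 2, tolerance = 0.05)
})

test_that("stress condition shortens intervals and shrinks variability", {
  cfg <- synthetic_config(seed = 7L)
  rest <- simulate_rr(cfg, "rest")
  stress <- simulate_rr(cfg, "stress")
  expect_lt(mean(stress), mean(rest))
  expect_lt(sd(stress), sd(rest))
})

test_that("zero PTT jitter returns the RR series unchanged", {
  rr <- make_rr(seed = 3)
  expect_identical(derive_pp(rr, 0), rr)
})

test_that("PTT jitter telescopes: duration changes only by the edge term", {
  rr <- make_rr(seed = 4)
  sigma <- 8
  pp <- derive_pp(rr, sigma, seed = 11L)
  set.seed(11L)
  eta <- rnorm(length(rr) + 1L, 0, sigma)
  expect_equal(sum(pp) - sum(rr), eta[length(eta)] - eta[1L], tolerance = 1e-9)
})

test_that("PTT jitter inflates RMSSD by 6 sigma^2 and SDNN by 2 sigma^2", {
  # Monte-Carlo check of the first-difference jitter model on long series
  sigma <- 10
  cfg <- synthetic_config(duration_s = 4000, seed = 5L)
  rr <- simulate_rr(cfg, "rest", seed = 5L)
  expect_gte(length(rr), 5000)
  rmssd_rr <- time_domain(rr)$rmssd
  sdnn_rr <- time_domain(rr)$sdnn
  n_seeds <- 50
  inflated <- vapply(seq_len(n_seeds), function(s) {
    pp <- derive_pp(rr, sigma, seed = s)
    td <- time_domain(pp)
    c(td$rmssd^2, td$sdnn^2)
  }, numeric(2))
  expect_equal(mean(inflated[1, ]), rmssd_rr^2 + 6 * sigma^2, tolerance = 0.05)
  expect_equal(mean(inflated[2, ]), sdnn_rr^2 + 2 * sigma^2, tolerance = 0.05)
  # relative inflation is much stronger for RMSSD than for SDNN
  expect_gt(mean(inflated[1, ]) / rmssd_rr^2, mean(inflated[2, ]) / sdnn_rr^2)
})

test_that("artifact injection round-trips through QC flagging", {
  rr <- make_rr(seed = 6, duration_s = 800)
  expect_identical(inject_artifacts(rr, 0)$intervals, rr)
  expect_length(inject_artifacts(rr, 0)$indices, 0L)
  out <- inject_artifacts(rr, 0.01, seed = 9L)
  expect_gt(length(out$indices), 0L)
  expect_true(all(out$indices > 1 & out$indices < length(rr)))
  flags <- flag_abnormal(out$intervals)
  # every out-of-range injection must be flagged, with reason "range"
  oor <- out$indices[out$intervals[out$indices] < 350 | out$intervals[out$indices] > 1350]
  expect_true(all(oor %in% flags$index[flags$reason == "range"]))
  # overall sensitivity reported (deviation spikes can mask each other)
  sens <- mean(out$indices %in% flags$index)
  expect_gt(sens, 0.9)
})

test_that("synthetic PPG waveform places one template per beat and is recoverable", {
  w <- synthesize_ppg(rep(1000, 20), fs = 1000, snr = Inf)
  det <- detect_pp_intervals(w$samples, 1000)
  expect_true(all(abs(det$intervals - 1000) <= 2))
  # alternating beat lengths survive detection
  rr <- rep(c(800, 1000), 15)
  det2 <- detect_pp_intervals(synthesize_ppg(rr, fs = 1000)$samples, 1000)
  expect_equal(length(det2$intervals), length(rr) - 1)
  expect_true(all(abs(sort(unique(round(det2$intervals))) - c(800, 1000)) <= 2))
  # zero beats -> flat waveform
  expect_true(all(synthesize_ppg(numeric(0), fs = 250)$samples == 0))
  expect_error(synthesize_ppg(rep(800, 5), fs = 50), "fs")
  expect_error(synthesize_ppg(rep(100, 5), fs = 250, pulse_width_s = 0.15), "pulse_width")
})

test_that("cohort writes and reads back losslessly", {
  cfg <- synthetic_config(n_subjects = 2, duration_s = 60, seed = 8L)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    for (ch in c("rr_rest", "pp_rest", "rr_stress", "pp_stress")) {
      expect_identical(back[[i]][[ch]], cohort[[i]][[ch]])
    }
    expect_equal(back[[i]]$truth$lag, cohort[[i]]$truth$lag)
  }
})
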