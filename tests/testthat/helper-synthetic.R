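# shared fixtures: small synthetic waveforms and matching utilities

# F1 score of detected beat times against ground truth, allowing a constant
# detection offset (filter delay convention), matched at +/- tol_ms
beat_f1 <- function(detected_ms, truth_ms, tol_ms = 50) {
  if (length(detected_ms) == 0 || length(truth_ms) == 0) return(0)
  dd <- outer(detected_ms, truth_ms, `-`)
  off <- median(dd[abs(dd) < 200])
  adj <- detected_ms - off
  matched <- sum(vapply(truth_ms, function(tt) any(abs(adj - tt) < tol_ms), logical(1)))
  prec <- matched / length(detected_ms)
  rec <- matched / length(truth_ms)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# a modest rest-condition interval series for feature tests
make_rr <- function(seed = 1, duration_s = 300, ...) {
  cfg <- synthetic_config(duration_s = duration_s, ...)
  simulate_rr(cfg, "rest", seed = seed)
}

# long-format feature table for a tiny cohort, time-domain metrics only,
# used by comparison-layer tests that do not need spectra
feature_long <- function(values, subject, device, task, metric) {
  data.frame(subject = subject, device = device, task = task,
             metric = metric, value = values, stringsAsFactors = FALSE)
}
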