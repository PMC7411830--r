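#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end study pipeline: the synthetic cohort
#' generator (or a directory of interval CSVs), alignment search range, QC
#' bounds, and output location.
#'
#' @param synthetic a [synthetic_config()] (used in synthetic mode and as
#'   defaults elsewhere).
#' @param mode `"synthetic"` (generate the cohort) or `"files"` (read a
#'   cohort previously written with [write_cohort()] from `input_dir`).
#' @param input_dir cohort directory for file mode.
#' @param out_dir optional directory; when given, every intermediate artifact
#'   (cohort CSVs, feature table, report tables) is persisted there.
#' @param max_lag,min_overlap alignment search parameters, beats.
#' @param qc_lower,qc_upper,dev_frac artifact rules: plausible range (ms) and
#'   neighbour-deviation fraction.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            mode = c("synthetic", "files"),
                            input_dir = NULL, out_dir = NULL,
                            max_lag = 15, min_overlap = 30,
                            qc_lower = 350, qc_upper = 1350, dev_frac = 0.20) {
  mode <- match.arg(mode)
  stopifnot(inherits(synthetic, "synthetic_config"))
  if (mode == "files" && is.null(input_dir)) stop("file mode requires input_dir")
  if (qc_lower >= qc_upper) stop("qc_lower must be below qc_upper")
  structure(list(synthetic = synthetic, mode = mode,
                 input_dir = input_dir, out_dir = out_dir,
                 max_lag = max_lag, min_overlap = min_overlap,
                 qc_lower = qc_lower, qc_upper = qc_upper, dev_frac = dev_frac),
            class = "pipeline_config")
}

#' Run the full validation pipeline
#'
#' Executes, per subject and task: beat-level alignment of the PPG-derived PP
#' stream to the ECG-derived RR stream, artifact detection and repair on both
#' aligned channels, and HRV feature extraction; then assembles the
#' study-level tables: a QC error table, pooled descriptive statistics per
#' device and task, the per-task agreement battery, and the rest-versus-stress
#' comparison per device. Fully deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()].
#' @return list of class `study_report` with elements `qc_table`,
#'   `descriptive_table`, `agreement_rest`, `agreement_stress`,
#'   `comparison_table`, `features`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (config$mode == "synthetic") {
    simulate_cohort(config$synthetic)
  } else {
    read_cohort(config$input_dir)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (config$mode == "synthetic") {
      write_cohort(cohort, file.path(config$out_dir, "cohort"))
    }
  }
  feat_rows <- list()
  qc_counts <- list()
  pooled <- list()
  for (sub in cohort) {
    for (task in c("rest", "stress")) {
      rr <- sub[[paste0("rr_", task)]]
      pp <- sub[[paste0("pp_", task)]]
      al <- tryCatch(
        synchronize(rr, pp, max_lag = config$max_lag,
                    min_overlap = config$min_overlap),
        error = function(e) stop(sprintf("alignment failed for subject %s, task %s: %s",
                                         sub$subject_id, task, conditionMessage(e)))
      )
      for (dev in c("ecg", "ppg")) {
        x <- if (dev == "ecg") al$aligned_a else al$aligned_b
        qc <- tryCatch(
          qc_summary(x, lower = config$qc_lower, upper = config$qc_upper,
                     dev_frac = config$dev_frac),
          error = function(e) stop(sprintf("QC failed for subject %s, task %s, device %s: %s",
                                           sub$subject_id, task, dev, conditionMessage(e)))
        )
        key <- paste(dev, task, sep = ".")
        prev <- qc_counts[[key]]
        qc_counts[[key]] <- list(
          n = (if (is.null(prev)) 0 else prev$n) + qc$n_total,
          flagged = (if (is.null(prev)) 0 else prev$flagged) + qc$n_flagged
        )
        pooled[[key]] <- c(pooled[[key]], qc$corrected)
        f <- tryCatch(
          hrv_features(qc$corrected),
          error = function(e) stop(sprintf("feature extraction failed for subject %s, task %s, device %s: %s",
                                           sub$subject_id, task, dev, conditionMessage(e)))
        )
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          subject = sub$subject_id, device = dev, task = task,
          metric = names(f), value = as.numeric(f[1, ]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  features <- do.call(rbind, feat_rows)
  keys <- expand.grid(device = c("ecg", "ppg"), task = c("rest", "stress"),
                      stringsAsFactors = FALSE)
  qc_table <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    key <- paste(keys$device[i], keys$task[i], sep = ".")
    cnt <- qc_counts[[key]]
    data.frame(device = keys$device[i], task = keys$task[i],
               n_intervals = cnt$n, n_flagged = cnt$flagged,
               pct_flagged = round(100 * cnt$flagged / cnt$n, 2),
               stringsAsFactors = FALSE)
  }))
  descriptive_table <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    key <- paste(keys$device[i], keys$task[i], sep = ".")
    cbind(data.frame(device = keys$device[i], task = keys$task[i],
                     stringsAsFactors = FALSE),
          descriptives(pooled[[key]]))
  }))
  report <- list(
    qc_table = qc_table,
    descriptive_table = descriptive_table,
    agreement_rest = agreement_table(features, task = "rest"),
    agreement_stress = agreement_table(features, task = "stress"),
    comparison_table = compare_tasks(features),
    features = features,
    provenance = list(seed = config$synthetic$seed,
                      mode = config$mode,
                      config = unclass(config$synthetic))
  )
  class(report) <- "study_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Persist a study report as CSV tables plus a JSON summary
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("qc_table", "descriptive_table", "agreement_rest",
            "agreement_stress", "comparison_table", "features")
  for (nm in tabs) {
    write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(report[c(tabs, "provenance")],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
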