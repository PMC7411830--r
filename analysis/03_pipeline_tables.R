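#!/usr/bin/env Rscript
# Run the full validation pipeline on the cohort written by
# 01_simulate_cohort.R: beat-level alignment, artifact QC, HRV feature
# extraction, the per-task agreement battery, and the rest-vs-stress
# comparison. Writes every study table under results/pipeline/.

suppressPackageStartupMessages(library(prvagree))

cohort_dir <- "results/cohort"
if (!dir.exists(cohort_dir)) stop("run analysis/01_simulate_cohort.R first")

cfg <- pipeline_config(synthetic = synthetic_config(seed = 20260930L),
                       mode = "files", input_dir = cohort_dir,
                       out_dir = "results/pipeline")
report <- run_pipeline(cfg)

message("QC error table (per device and task):")
print(report$qc_table)
message("Agreement at rest (bias, BA ratio, labels):")
print(report$agreement_rest[, c("metric", "bias", "ba_ratio", "lccc",
                                "lccc_label", "ba_label")])
message("Rest-vs-stress comparison (PPG device):")
print(report$comparison_table[report$comparison_table$device == "ppg",
                              c("metric", "direction", "p_value", "cles")])
message("All tables written to results/pipeline/")
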