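#!/usr/bin/env Rscript
# 02 — Quality control.
#
# Applies the QC cascade to the simulated cohort: protein below-LOD filter
# (>25%), sample below-LOD filter (>10%, across retained proteins), protein
# then sample missingness filters (>20% each), and removal of measurement
# dates whose daily mean NPX has |z| > 3. Writes the filtered dataset and
# the stage-by-stage audit report.

suppressPackageStartupMessages({
  library(npxdiff)
  library(dplyr)
})

cohort <- read_npx_csv("results/cohort.csv")
qc <- run_qc(cohort$npx, cohort$meta, qc_thresholds())
print(qc$report)

readr::write_tsv(
  qc$report$stages %>%
    mutate(removed = vapply(removed, function(r)
      paste(as.character(r), collapse = ";"), character(1))),
  "results/qc_report.tsv")
readr::write_tsv(qc$report$daily, "results/qc_daily_means.tsv")
write_npx_csv(qc$npx, qc$meta, "results/post_qc.csv")
message(sprintf("retained %d samples x %d proteins -> results/post_qc.csv",
                qc$report$final$n_samples, qc$report$final$n_proteins))
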