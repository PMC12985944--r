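#!/usr/bin/env Rscript
# 03 — Covariate adjustment.
#
# Regresses each protein's NPX values on age, sex and the numeric collection
# date (days since the earliest retained date) by OLS, per protein with
# case-wise deletion, and keeps the residuals as covariate-adjusted
# abundance. Writes the per-protein coefficient table and the adjusted
# sample-by-protein matrix.

suppressPackageStartupMessages(library(npxdiff))

post <- read_npx_csv("results/post_qc.csv")
meta <- dates_to_numeric(post$meta)
adjusted <- residualize_all(post$npx, meta)
print(adjusted)

readr::write_tsv(adjusted$coefficients, "results/adjust_coefficients.tsv")
wide <- tidyr::pivot_wider(adjusted$residuals, names_from = "protein",
                           values_from = "residual")
readr::write_tsv(wide, "results/adjusted_wide.tsv")
message(sprintf("age coefficient, median across proteins: %.4f NPX/year",
                stats::median(adjusted$coefficients$age, na.rm = TRUE)))
message(sprintf("date coefficient, median: %.6f NPX/day",
                stats::median(adjusted$coefficients$date_numeric, na.rm = TRUE)))
message("wrote results/adjust_coefficients.tsv, results/adjusted_wide.tsv")
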