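#!/usr/bin/env Rscript
# 04 — Differential protein abundance.
#
# Tests every adjusted protein for a case-control difference (pooled-variance
# two-sample t on the residuals; effect = case - control mean difference),
# applies Benjamini-Hochberg FDR over all tested proteins, and repeats the
# analysis within each panel with within-panel multiplicity. Writes the
# global and per-panel result tables, both sorted by p.

suppressPackageStartupMessages({
  library(npxdiff)
  library(dplyr)
})

post <- read_npx_csv("results/post_qc.csv")
meta <- dates_to_numeric(post$meta)
adjusted <- residualize_all(post$npx, meta)

dpa <- run_dpa(adjusted, meta, npx = post$npx, q_threshold = 0.05)
readr::write_tsv(tibble::as_tibble(dpa), "results/results.tsv")
message(sprintf("%d proteins tested; %d significant at q < 0.05",
                nrow(dpa), sum(dpa$significant)))
message("top of the table:")
print(head(tibble::as_tibble(dpa), 10), width = 100)

panel <- run_panel_dpa(adjusted, meta, post$npx, q_threshold = 0.05)
readr::write_tsv(bind_rows(lapply(panel, tibble::as_tibble),
                           .id = "panel_stratum"),
                 "results/results_per_panel.tsv")
for (pn in names(panel))
  message(sprintf("  panel %-16s %4d tested, %d significant (within-panel FDR)",
                  pn, nrow(panel[[pn]]), sum(panel[[pn]]$significant)))
message("wrote results/results.tsv, results/results_per_panel.tsv")
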