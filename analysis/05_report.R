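#!/usr/bin/env Rscript
# 05 — Result surfaces.
#
# Derives the data products behind the standard figures from the result
# table: volcano coordinates, the top-10 group-mean heatmap matrix, per-group
# boxplot summaries of the top proteins, and the significant-symbol list in
# the one-symbol-per-line format external PPI tools ingest. Renders a volcano
# PNG when ggplot2 is available.

suppressPackageStartupMessages({
  library(npxdiff)
  library(dplyr)
})

dpa <- readr::read_tsv("results/results.tsv", show_col_types = FALSE)
post <- read_npx_csv("results/post_qc.csv")

volcano <- make_volcano(dpa, q_threshold = 0.05)
readr::write_tsv(tibble::as_tibble(volcano), "results/volcano.tsv")

heatmap <- make_heatmap_matrix(dpa, post$npx, post$meta, k = 10)
readr::write_tsv(heatmap, "results/heatmap.tsv")
message("top-10 group-mean heatmap matrix:")
print(heatmap)

box <- make_boxplot_summaries(post$npx, post$meta, heatmap$protein)
readr::write_tsv(box %>% mutate(outliers = vapply(outliers, function(o)
  paste(signif(o, 6), collapse = ";"), character(1))),
  "results/boxplots.tsv")

syms <- export_significant_symbols(dpa, threshold = 0.05,
                                   path = "results/significant_symbols.txt")
message(sprintf("%d significant symbols -> results/significant_symbols.txt",
                length(syms)))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  gg <- plot_volcano(volcano)
  ggplot2::ggsave("results/volcano.png", gg, width = 7, height = 5, dpi = 150)
  message("wrote results/volcano.png")
}
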