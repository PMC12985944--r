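Package: npxdiff
Title: Differential Abundance Analysis for Olink NPX Plasma Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quality control and two-group differential abundance analysis for
    Olink-style normalized protein expression (NPX) data at population scale.
    Implements the limit-of-detection and missingness quality-control cascade,
    measurement-date outlier detection, per-protein ordinary least-squares
    residualization on age, sex and collection date, pooled-variance group
    comparison with Benjamini-Hochberg step-up false discovery rate control,
    panel-stratified re-analysis, and the data products behind volcano plots,
    heatmaps and boxplots. Ships a seeded synthetic cohort generator that
    emulates the statistical structure of UK Biobank Olink Explore data
    (censoring below detection limits, sporadic missingness, covariate effects
    and temporal batch artifacts) so the whole pipeline is testable without
    access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
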