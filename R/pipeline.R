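#' Run the full pipeline end to end
#'
#' Simulate (or accept) a cohort, run the QC cascade, residualize on age, sex
#' and date, test every protein, and build the report tables. With `out_dir`
#' set, all data artifacts are written as plain-text files together with a
#' manifest recording the seed, a configuration hash and stage-level counts;
#' rerunning with an identical configuration reproduces identical data
#' outputs (the simulator is the only seeded stage — QC, adjustment and
#' testing are deterministic).
#'
#' @param config A [sim_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-built `list(npx, meta)` to analyse instead of
#'   simulating.
#' @param thresholds A [qc_thresholds()].
#' @param q_threshold Significance threshold on the q-value.
#' @param test `"pooled"` or `"welch"`, passed to the testing stage.
#' @param heatmap_k Number of top proteins in the heatmap matrix.
#' @param per_panel Whether to run the panel-stratified re-analysis.
#' @param out_dir Optional output directory for artifacts.
#' @return Invisibly, a list with `cohort`, `qc` (filtered data + report),
#'   `adjusted`, `dpa`, `panel_dpa`, `volcano`, `heatmap`, `boxplots`,
#'   `significant_symbols` and `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL,
                         thresholds = qc_thresholds(), q_threshold = 0.05,
                         test = "pooled", heatmap_k = 10L, per_panel = TRUE,
                         out_dir = NULL) {
  simulated <- is.null(cohort)
  if (simulated) cohort <- generate_cohort(config)

  qc <- run_qc(cohort$npx, cohort$meta, thresholds)
  adjusted <- residualize_all(qc$npx, qc$meta)
  dpa <- run_dpa(adjusted, qc$meta, npx = qc$npx, q_threshold = q_threshold,
                 test = test)
  panel_dpa <- if (per_panel)
    run_panel_dpa(adjusted, qc$meta, qc$npx, q_threshold = q_threshold,
                  test = test) else NULL

  volcano <- make_volcano(dpa, q_threshold = q_threshold)
  k <- min(heatmap_k, nrow(dpa))
  heatmap <- make_heatmap_matrix(dpa, qc$npx, qc$meta, k = k)
  boxplots <- make_boxplot_summaries(qc$npx, qc$meta,
                                     top_proteins(dpa, k)$protein)
  symbols <- export_significant_symbols(dpa, threshold = q_threshold)

  manifest <- list(
    package_version = as.character(utils::packageVersion("npxdiff")),
    seed = if (simulated) config$seed else NA_integer_,
    config_hash = if (simulated) rlang::hash(config) else NA_character_,
    q_threshold = q_threshold,
    test = test,
    stages = qc$report$stages %>% select(-"removed"),
    final_n_samples = qc$report$final$n_samples,
    final_n_proteins = qc$report$final$n_proteins,
    n_tested = nrow(dpa),
    n_significant = sum(dpa$significant)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
    write_npx_csv(cohort$npx, cohort$meta, file.path(out_dir, "cohort.csv"))
    w(qc$report$stages %>% mutate(removed = vapply(
        .data$removed, function(r) paste(as.character(r), collapse = ";"),
        character(1))), "qc_report.tsv")
    w(adjusted$coefficients, "adjust_coefficients.tsv")
    w(as_tibble(dpa), "results.tsv")
    if (!is.null(panel_dpa))
      w(bind_rows(lapply(panel_dpa, as_tibble), .id = "panel_stratum"),
        "results_per_panel.tsv")
    w(as_tibble(volcano), "volcano.tsv")
    w(heatmap, "heatmap.tsv")
    w(boxplots %>% mutate(outliers = vapply(
        .data$outliers, function(o) paste(signif(o, 6), collapse = ";"),
        character(1))), "boxplots.tsv")
    writeLines(symbols, file.path(out_dir, "significant_symbols.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(cohort = cohort, qc = qc, adjusted = adjusted, dpa = dpa,
                 panel_dpa = panel_dpa, volcano = volcano, heatmap = heatmap,
                 boxplots = boxplots, significant_symbols = symbols,
                 manifest = manifest))
}

#' Published chronic-periodontitis reference results
#'
#' Summary statistics for the 29 plasma proteins reported as differentially
#' abundant (FDR below 1e-4) between chronic periodontitis cases and healthy
#' controls in a population-scale UK Biobank Olink Explore analysis of 2151
#' proteins (2251 controls vs 90 cases). Columns mirror a standard
#' differential-abundance table: raw group means (`mean_nor`, `mean_cp`),
#' adjusted effect size, p-value, per-protein group sizes and the published
#' BH FDR. These 29 rows are the complete set below the selection threshold,
#' i.e. the 29 smallest p-values of the 2151 tests, which is what makes the
#' FDR column re-derivable via [bh_adjust()] with `m_total = 2151`.
#'
#' @return A tibble of 29 rows with attribute `m_total = 2151`.
#' @export
periodontitis_reference <- function() {
  path <- system.file("extdata", "periodontitis_reference.csv",
                      package = "npxdiff", mustWork = TRUE)
  out <- readr::read_csv(path, col_types = readr::cols(
    protein = readr::col_character(), full_name = readr::col_character(),
    mean_nor = readr::col_double(), mean_cp = readr::col_double(),
    effect = readr::col_double(), p_value = readr::col_double(),
    n_nor = readr::col_integer(), n_cp = readr::col_integer(),
    fdr = readr::col_double()))
  attr(out, "m_total") <- 2151L
  out
}
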