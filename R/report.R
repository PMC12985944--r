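#' Volcano-plot data table
#'
#' One row per tested protein with the effect size on x, `-log10(p)` on y, and
#' the significance flag at `q_threshold`. `effect_guide`, if given, is a
#' purely cosmetic |effect| guide value echoed into the table attributes for
#' plotting vertical reference lines; it plays no role in the flags.
#'
#' @param dpa A `dpa_result` tibble.
#' @param q_threshold Significance threshold on the q-value.
#' @param effect_guide Optional absolute-effect guide line value.
#' @return Tibble `protein, panel, effect, neg_log10_p, q_value, significant`.
#' @export
make_volcano <- function(dpa, q_threshold = 0.05, effect_guide = NULL) {
  if (nrow(dpa) == 0L) stop("empty differential-abundance table", call. = FALSE)
  out <- tibble(protein = dpa$protein, panel = dpa$panel, effect = dpa$effect,
                neg_log10_p = -log10(dpa$p_value), q_value = dpa$q_value,
                significant = dpa$q_value < q_threshold)
  attr(out, "q_threshold") <- q_threshold
  attr(out, "effect_guide") <- effect_guide
  out
}

#' Heatmap matrix of top differential proteins
#'
#' Selects the `k` smallest-p proteins and computes each group's mean raw NPX
#' (unadjusted, over all non-missing measurements of retained samples),
#' matching a top-k group-mean heatmap.
#'
#' @param dpa A `dpa_result` tibble.
#' @param npx Post-QC NPX table.
#' @param meta Per-sample metadata with `group`.
#' @param k Number of top proteins (default 10).
#' @return Tibble `protein, mean_normal, mean_case`, rows in ascending p
#'   order.
#' @export
make_heatmap_matrix <- function(dpa, npx, meta, k = 10L) {
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (k > nrow(dpa)) stop("`k` exceeds the number of tested proteins",
                          call. = FALSE)
  top <- top_proteins(dpa, k)
  grp <- meta$group[match(npx$sample_id, meta$sample_id)]
  sub <- npx %>%
    mutate(group = grp) %>%
    filter(.data$protein %in% top$protein, !is.na(.data$npx))
  cells <- sub %>%
    group_by(.data$protein, .data$group) %>%
    summarise(mean_npx = mean(.data$npx), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "mean_npx",
                       names_prefix = "mean_")
  top %>% select("protein") %>% left_join(cells, by = "protein")
}

#' Per-protein, per-group boxplot summaries
#'
#' Five-number summaries (min, Q1, median, Q3, max; linear-interpolation
#' quantiles, R type 7) of raw NPX by group, plus observations flagged as
#' outliers by the 1.5 IQR rule (outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`).
#'
#' @param npx Post-QC NPX table.
#' @param meta Per-sample metadata with `group`.
#' @param proteins Character vector of proteins to summarize.
#' @return Tibble `protein, group, n, min, q1, median, q3, max, n_outliers,
#'   outliers` (list column of outlying values). Groups with zero
#'   observations for a protein are omitted with a warning.
#' @export
make_boxplot_summaries <- function(npx, meta, proteins) {
  missing_prot <- setdiff(proteins, unique(npx$protein))
  if (length(missing_prot) > 0L)
    stop("protein(s) not in table: ", paste(missing_prot, collapse = ", "),
         call. = FALSE)
  grp <- meta$group[match(npx$sample_id, meta$sample_id)]
  sub <- npx %>%
    mutate(group = grp) %>%
    filter(.data$protein %in% proteins, !is.na(.data$npx))
  empty <- tidyr::expand_grid(protein = proteins,
                              group = levels(meta$group)) %>%
    dplyr::anti_join(sub %>% distinct(.data$protein, .data$group) %>%
                       mutate(group = as.character(.data$group)),
                     by = c("protein", "group"))
  if (nrow(empty) > 0L)
    warning(sprintf("%d protein-group combination(s) with no observations omitted",
                    nrow(empty)), call. = FALSE)
  sub %>%
    group_by(.data$protein, .data$group) %>%
    summarise(n = dplyr::n(),
              min = min(.data$npx),
              q1 = quantile(.data$npx, 0.25, type = 7, names = FALSE),
              median = quantile(.data$npx, 0.5, type = 7, names = FALSE),
              q3 = quantile(.data$npx, 0.75, type = 7, names = FALSE),
              max = max(.data$npx),
              outliers = list(.data$npx[.data$npx < q1 - 1.5 * (q3 - q1) |
                                          .data$npx > q3 + 1.5 * (q3 - q1)]),
              .groups = "drop") %>%
    mutate(n_outliers = lengths(.data$outliers)) %>%
    select("protein", "group", "n", "min", "q1", "median", "q3", "max",
           "n_outliers", "outliers")
}

#' Export significant protein symbols
#'
#' Writes (or returns) the symbols of proteins significant at `threshold`,
#' one per line, sorted by ascending p-value — the input format expected by
#' external protein-protein interaction tools.
#'
#' @param dpa A `dpa_result` tibble.
#' @param threshold Significance threshold on the q-value.
#' @param path Optional output file; when `NULL` nothing is written.
#' @return Character vector of symbols, invisibly when `path` is given.
#' @export
export_significant_symbols <- function(dpa, threshold = 0.05, path = NULL) {
  sel <- dpa %>% filter(.data$q_value < threshold) %>%
    arrange(.data$p_value, .data$protein)
  symbols <- sel$protein
  if (!is.null(path)) {
    writeLines(symbols, path)
    return(invisible(symbols))
  }
  symbols
}

#' Volcano plot (optional rendering)
#'
#' Best-effort ggplot2 rendering of a [make_volcano()] table; the tested
#' artifact is the table, not the pixels.
#'
#' @param volcano A [make_volcano()] table.
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  gg <- ggplot2::ggplot(volcano,
                        ggplot2::aes(x = .data$effect, y = .data$neg_log10_p,
                                     colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "red3")) +
    ggplot2::labs(x = "Effect size (adjusted NPX, case - control)",
                  y = expression(-log[10](p)), colour = "Significant") +
    ggplot2::theme_minimal()
  guide <- attr(volcano, "effect_guide")
  if (!is.null(guide))
    gg <- gg + ggplot2::geom_vline(xintercept = c(-guide, guide),
                                   linetype = "dashed", colour = "grey40")
  gg
}
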