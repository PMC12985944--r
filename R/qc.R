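#' Quality-control thresholds
#'
#' Thresholds for the NPX quality-control cascade. Every "max fraction"
#' threshold is applied with strict inequality: an entity whose fraction
#' exceeds the threshold is removed, an entity exactly at it is retained
#' ("more than X%" semantics).
#'
#' @param protein_lod_max_frac Remove proteins with more than this fraction of
#'   non-missing measurements below the LOD (default 0.25).
#' @param sample_lod_max_frac Remove samples with more than this fraction of
#'   values below the LOD across retained proteins (default 0.10).
#' @param protein_missing_max_frac Remove proteins with more than this
#'   fraction of missing values (default 0.20).
#' @param sample_missing_max_frac Remove samples with more than this fraction
#'   of missing values across retained proteins (default 0.20).
#' @param date_z_cutoff Flag measurement dates whose daily mean NPX has
#'   absolute z-score greater than this cutoff (default 3).
#' @return A validated list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(protein_lod_max_frac = 0.25,
                          sample_lod_max_frac = 0.10,
                          protein_missing_max_frac = 0.20,
                          sample_missing_max_frac = 0.20,
                          date_z_cutoff = 3.0) {
  fracs <- c(protein_lod_max_frac, sample_lod_max_frac,
             protein_missing_max_frac, sample_missing_max_frac)
  if (any(!is.finite(fracs)) || any(fracs <= 0) || any(fracs > 1))
    stop("QC fractions must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(date_z_cutoff) || date_z_cutoff <= 0)
    stop("`date_z_cutoff` must be positive", call. = FALSE)
  structure(list(protein_lod_max_frac = protein_lod_max_frac,
                 sample_lod_max_frac = sample_lod_max_frac,
                 protein_missing_max_frac = protein_missing_max_frac,
                 sample_missing_max_frac = sample_missing_max_frac,
                 date_z_cutoff = date_z_cutoff),
            class = "qc_thresholds")
}

frac_below_lod <- function(npx, by) {
  npx %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    summarise(n_obs = sum(!is.na(.data$npx)),
              n_below = sum(.data$below_lod),
              .groups = "drop") %>%
    mutate(frac = ifelse(.data$n_obs > 0, .data$n_below / .data$n_obs, NA_real_))
}

#' Filter proteins by below-LOD fraction
#'
#' Removes proteins for which more than `max_frac` of their non-missing
#' measurements fall below the assay limit of detection. Missing cells are
#' excluded from the denominator; a protein with zero non-missing measurements
#' cannot be assessed and is removed, reported separately as degenerate.
#'
#' @param npx Long-format NPX tibble with `below_lod` flags.
#' @param max_frac Maximum tolerated below-LOD fraction (strict `>` removes).
#' @return `list(npx = filtered table, removed = protein ids over threshold,
#'   degenerate = protein ids with no usable measurements)`.
#' @export
filter_proteins_by_lod <- function(npx, max_frac = 0.25) {
  st <- frac_below_lod(npx, "protein")
  removed <- st$protein[!is.na(st$frac) & st$frac > max_frac]
  degenerate <- st$protein[st$n_obs == 0L]
  list(npx = npx %>% filter(!.data$protein %in% c(removed, degenerate)),
       removed = removed, degenerate = degenerate)
}

#' Filter samples by below-LOD fraction
#'
#' As [filter_proteins_by_lod()] but along the sample axis; intended to run
#' after protein-level LOD filtering so fractions are computed across retained
#' proteins only.
#'
#' @inheritParams filter_proteins_by_lod
#' @param max_frac Maximum tolerated below-LOD fraction per sample.
#' @return `list(npx, removed, degenerate)` with sample ids.
#' @export
filter_samples_by_lod <- function(npx, max_frac = 0.10) {
  st <- frac_below_lod(npx, "sample_id")
  removed <- st$sample_id[!is.na(st$frac) & st$frac > max_frac]
  degenerate <- st$sample_id[st$n_obs == 0L]
  list(npx = npx %>% filter(!.data$sample_id %in% c(removed, degenerate)),
       removed = removed, degenerate = degenerate)
}

#' Filter proteins then samples by missingness
#'
#' Single-pass missingness filtering in the stated order: proteins with more
#' than `protein_max` missing values are removed first; sample missingness is
#' then computed across the retained proteins and samples above `sample_max`
#' are removed. The two passes are not iterated to a joint fixpoint.
#'
#' @param npx Long-format NPX tibble (one row per sample-protein cell, missing
#'   measurements as `NA`).
#' @param protein_max,sample_max Maximum tolerated missing fractions
#'   (strict `>` removes).
#' @return `list(npx, removed_proteins, removed_samples)`.
#' @export
filter_by_missingness <- function(npx, protein_max = 0.20, sample_max = 0.20) {
  pstat <- npx %>% group_by(.data$protein) %>%
    summarise(frac = mean(is.na(.data$npx)), .groups = "drop")
  removed_proteins <- pstat$protein[pstat$frac > protein_max]
  out <- npx %>% filter(!.data$protein %in% removed_proteins)

  sstat <- out %>% group_by(.data$sample_id) %>%
    summarise(frac = mean(is.na(.data$npx)), .groups = "drop")
  removed_samples <- sstat$sample_id[sstat$frac > sample_max]
  out <- out %>% filter(!.data$sample_id %in% removed_samples)

  if (nrow(out) == 0L)
    stop("missingness filtering removed the entire table", call. = FALSE)
  list(npx = out, removed_proteins = removed_proteins,
       removed_samples = removed_samples)
}

#' Detect outlier measurement dates from daily mean NPX
#'
#' Pools all non-missing NPX measurements per calendar date, computes each
#' date's mean, standardizes the daily means (sample SD, denominator n-1,
#' self-inclusive), and flags dates with `|z| > z_cutoff`.
#'
#' @param npx Long-format NPX tibble carrying a `date` column (run on the
#'   post-filter table).
#' @param z_cutoff Absolute z-score above which a date is an outlier.
#' @return `list(outlier_dates = Date vector, daily = tibble(date, mean_npx,
#'   n_obs, z))`. When all daily means are equal (zero SD) no date is flagged
#'   and a warning is issued.
#' @export
detect_outlier_dates <- function(npx, z_cutoff = 3.0) {
  daily <- npx %>%
    filter(!is.na(.data$npx)) %>%
    group_by(.data$date) %>%
    summarise(mean_npx = mean(.data$npx), n_obs = dplyr::n(), .groups = "drop") %>%
    arrange(.data$date)
  if (nrow(daily) < 3L)
    stop("date-outlier detection needs at least 3 distinct measurement dates",
         call. = FALSE)
  s <- sd(daily$mean_npx)
  if (!is.finite(s) || s == 0) {
    warning("all daily mean NPX values are equal; no date outliers detectable",
            call. = FALSE)
    daily$z <- 0
  } else {
    daily$z <- (daily$mean_npx - mean(daily$mean_npx)) / s
  }
  list(outlier_dates = daily$date[abs(daily$z) > z_cutoff], daily = daily)
}

#' Convert measurement dates to a numeric covariate
#'
#' Adds `date_numeric`, the integer number of days since the earliest
#' measurement date present in `meta`. Run after outlier-date removal so the
#' origin is the earliest date of the filtered dataset.
#'
#' @param meta Per-sample metadata with a `date` column.
#' @return `meta` with an added integer `date_numeric` column (0 for the
#'   earliest date).
#' @export
dates_to_numeric <- function(meta) {
  if (any(is.na(meta$date)))
    stop("missing measurement date for sample(s): ",
         paste(head(meta$sample_id[is.na(meta$date)], 10L), collapse = ", "),
         call. = FALSE)
  meta %>% mutate(date_numeric = as.integer(.data$date - min(.data$date)))
}

qc_stage_record <- function(stage, entity, n_before, removed) {
  tibble(stage = stage, entity = entity,
         n_before = n_before, n_removed = length(removed),
         n_after = n_before - length(removed),
         removed = list(removed))
}

#' Run the full quality-control cascade
#'
#' Applies, in order: protein below-LOD filter, sample below-LOD filter,
#' protein missingness filter, sample missingness filter, date-outlier removal
#' (all samples on a flagged date are dropped), then date-to-numeric covariate
#' construction on the filtered metadata. Every stage is recorded in an audit
#' report with counts before/removed/after and the removed entity ids.
#'
#' Re-running QC on its own output removes nothing further at the threshold
#' filters; the date z-score stage, however, standardizes over whatever dates
#' remain and can in principle flag a new date on a second pass.
#'
#' @param npx Long-format NPX tibble.
#' @param meta Per-sample metadata.
#' @param thresholds A [qc_thresholds()] object.
#' @return `list(npx, meta, report)` where `meta` carries `date_numeric` and
#'   `report` is a `qc_report`: `$stages` (one record per stage), `$daily`
#'   (per-date mean and z), `$final` (retained dimensions).
#' @export
run_qc <- function(npx, meta, thresholds = qc_thresholds()) {
  stages <- list()
  n_prot <- function(x) dplyr::n_distinct(x$protein)
  n_samp <- function(x) dplyr::n_distinct(x$sample_id)

  f1 <- filter_proteins_by_lod(npx, thresholds$protein_lod_max_frac)
  stages[[1]] <- qc_stage_record("protein_lod", "protein", n_prot(npx),
                                 c(f1$removed, f1$degenerate))
  f2 <- filter_samples_by_lod(f1$npx, thresholds$sample_lod_max_frac)
  stages[[2]] <- qc_stage_record("sample_lod", "sample", n_samp(f1$npx),
                                 c(f2$removed, f2$degenerate))
  f3 <- filter_by_missingness(f2$npx, thresholds$protein_missing_max_frac,
                              thresholds$sample_missing_max_frac)
  stages[[3]] <- qc_stage_record("protein_missingness", "protein",
                                 n_prot(f2$npx), f3$removed_proteins)
  stages[[4]] <- qc_stage_record("sample_missingness", "sample",
                                 n_samp(f2$npx) , f3$removed_samples)
  cur <- f3$npx

  n_dates <- dplyr::n_distinct(cur$date)
  if (n_dates >= 3L) {
    det <- detect_outlier_dates(cur, thresholds$date_z_cutoff)
    daily <- det$daily
    out_dates <- det$outlier_dates
  } else {
    warning("fewer than 3 distinct dates; skipping date-outlier detection",
            call. = FALSE)
    daily <- tibble(date = as.Date(character()), mean_npx = double(),
                    n_obs = integer(), z = double())
    out_dates <- as.Date(character())
  }
  stages[[5]] <- qc_stage_record("date_outlier", "date", n_dates, out_dates)
  cur <- cur %>% filter(!.data$date %in% out_dates)

  meta_f <- meta %>%
    filter(.data$sample_id %in% unique(cur$sample_id)) %>%
    dates_to_numeric()

  report <- structure(
    list(stages = bind_rows(stages), daily = daily,
         thresholds = thresholds,
         final = list(n_samples = n_samp(cur), n_proteins = n_prot(cur))),
    class = "qc_report")
  list(npx = cur, meta = meta_f, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  for (i in seq_len(nrow(x$stages))) {
    r <- x$stages[i, ]
    cat(sprintf("  %-20s %ss: %d -> removed %d -> %d\n",
                r$stage, r$entity, r$n_before, r$n_removed, r$n_after))
  }
  cat(sprintf("  retained: %d samples x %d proteins\n",
              x$final$n_samples, x$final$n_proteins))
  invisible(x)
}
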