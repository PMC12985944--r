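#' Generate a synthetic NPX cohort
#'
#' Draws a complete case-control cohort from the generative model
#' \deqn{NPX_{ij} = \mu_j + \beta^{age}_j z(age_i) + \beta^{sex}_j sex_i +
#'       \beta^{date}_j t_i + \delta_j \, case_i + s\,[date_i = d^*] +
#'       \varepsilon_{ij},\qquad \varepsilon_{ij} \sim N(0, \sigma_j^2)}
#' where \eqn{z(age)} is age standardized within the cohort, \eqn{t} counts
#' days since the earliest sampled date, \eqn{\delta_j} is the true group
#' effect, and \eqn{s} is an additive shift applied to the designated aberrant
#' date \eqn{d^*} (the latest sampled date). Measurements are then blanked
#' completely at random at `missing_rate`, and below-LOD flags are set where a
#' present value falls under the assay's limit of detection. Values below the
#' LOD are retained as generated (flagged, not truncated or imputed), which is
#' what fraction-based LOD filtering consumes.
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#' \describe{
#'   \item{npx}{Long-format tibble with one row per (sample, protein):
#'     `sample_id`, `protein`, `panel`, `npx` (NA when missing), `lod`,
#'     `below_lod`, `date`.}
#'   \item{meta}{Per-sample tibble: `sample_id`, `participant_id`, `age`,
#'     `sex` (0 = female, 1 = male), `group` (factor, normal/case), `date`.}
#'   \item{truth}{Generative ground truth: per-protein `effect_sizes` and the
#'     designated `outlier_date` (NA when the shift is disabled).}
#' }
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be created by sim_config()", call. = FALSE)
  set.seed(config$seed)

  n_s <- config$n_controls + config$n_cases
  n_p <- config$n_proteins

  sample_id <- sprintf("S%05d", seq_len(n_s))
  participant_id <- sprintf("P%05d", seq_len(n_s))
  group <- factor(rep(c("normal", "case"), c(config$n_controls, config$n_cases)),
                  levels = c("normal", "case"))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n_s,
                replace = TRUE)
  sex <- rbinom(n_s, 1L, config$sex_ratio)
  all_dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  date <- sample(all_dates, n_s, replace = TRUE)

  z_age <- if (sd(age) > 0) (age - mean(age)) / sd(age) else rep(0, n_s)
  t_days <- as.numeric(date - min(date))
  case <- as.numeric(group == "case")

  outlier_date <- as.Date(NA)
  shift_ind <- rep(0, n_s)
  if (config$outlier_date_shift != 0) {
    outlier_date <- max(date)
    shift_ind <- as.numeric(date == outlier_date)
  }

  protein <- sprintf("PROT%04d", seq_len(n_p))
  panel <- sample(config$panel_labels, n_p, replace = TRUE)

  # sample-by-protein mean surface plus per-protein Gaussian noise
  M <- outer(rep(1, n_s), config$protein_mean) +
    outer(z_age, config$beta_age) +
    outer(sex, config$beta_sex) +
    outer(t_days, config$beta_date) +
    outer(case, config$effect_sizes) +
    config$outlier_date_shift * outer(shift_ind, rep(1, n_p)) +
    matrix(rnorm(n_s * n_p, sd = rep(config$protein_sd, each = n_s)), n_s, n_p)

  if (config$missing_rate > 0)
    M[runif(n_s * n_p) < config$missing_rate] <- NA_real_

  npx_val <- as.vector(M)
  lod_col <- rep(config$lod, each = n_s)
  npx <- tibble(
    sample_id = rep(sample_id, times = n_p),
    protein = rep(protein, each = n_s),
    panel = rep(panel, each = n_s),
    npx = npx_val,
    lod = lod_col,
    below_lod = !is.na(npx_val) & npx_val < lod_col,
    date = rep(date, times = n_p)
  )
  meta <- tibble(sample_id = sample_id, participant_id = participant_id,
                 age = age, sex = sex, group = group, date = date)

  list(npx = npx, meta = meta,
       truth = list(effect_sizes = stats::setNames(config$effect_sizes, protein),
                    outlier_date = outlier_date))
}
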