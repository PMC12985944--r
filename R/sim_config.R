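#' Configuration for the synthetic NPX cohort generator
#'
#' Builds and validates the full parameterization of a synthetic plasma
#' proteomics cohort. Defaults emulate the structure of a population-scale
#' Olink Explore case-control extract: a heavily imbalanced two-group design
#' (2251 controls vs 90 cases), assays spread over five panel categories,
#' modest covariate effects of age, sex and measurement date, per-assay
#' censoring just below the limit of detection, sporadic missingness, and one
#' aberrant measurement date carrying an additive NPX shift.
#'
#' Per-protein parameters (`effect_sizes`, `beta_age`, `beta_sex`, `beta_date`,
#' `protein_mean`, `protein_sd`, `lod`) may be given as scalars, which are
#' recycled to `n_proteins`, or as vectors of length `n_proteins`.
#'
#' @param n_controls Number of control ("normal") participants.
#' @param n_cases Number of case participants.
#' @param n_proteins Number of assays. The default (200) is a desk-scale size;
#'   population-scale runs use up to 2151.
#' @param panel_labels Panel category names assigned (uniformly at random) to
#'   proteins.
#' @param effect_sizes True case-minus-control group effect per protein, in NPX
#'   units (0 = null protein).
#' @param beta_age Covariate coefficient on standardized age (NPX per SD of
#'   age).
#' @param beta_sex Covariate coefficient on sex (NPX; sex coded female = 0,
#'   male = 1).
#' @param beta_date Covariate coefficient on days since the earliest
#'   measurement date (NPX per day).
#' @param protein_mean Baseline NPX level per protein.
#' @param protein_sd Residual standard deviation per protein; strictly
#'   positive.
#' @param lod Per-assay limit of detection, NPX units. The default,
#'   `protein_mean - 2.326 * protein_sd`, censors about 1% of measurements.
#' @param missing_rate Probability, in `[0, 1)`, that any single measurement is
#'   missing completely at random.
#' @param date_range Length-2 vector (coercible to `Date`) spanning the
#'   measurement dates, sampled uniformly per participant.
#' @param outlier_date_shift Additive NPX shift applied to every measurement on
#'   one designated date (the latest sampled date); 0 disables the artifact.
#' @param age_range Length-2 integer range of ages (years), sampled uniformly.
#' @param sex_ratio Proportion of male participants.
#' @param seed Integer random seed; identical configurations (including the
#'   seed) generate identical cohorts.
#'
#' @return A validated list of class `sim_config` with all per-protein fields
#'   expanded to length `n_proteins`.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_controls = 50, n_cases = 10, n_proteins = 20, seed = 1)
#' cohort <- generate_cohort(cfg)
sim_config <- function(n_controls = 2251,
                       n_cases = 90,
                       n_proteins = 200,
                       panel_labels = c("cardiometabolic", "inflammation",
                                        "neurology", "oncology", "unknown"),
                       effect_sizes = 0,
                       beta_age = 0.1,
                       beta_sex = 0.1,
                       beta_date = 3e-4,
                       protein_mean = 0,
                       protein_sd = 1,
                       lod = protein_mean - 2.326 * protein_sd,
                       missing_rate = 0.01,
                       date_range = c("2021-01-01", "2021-12-31"),
                       outlier_date_shift = 1.0,
                       age_range = c(40L, 69L),
                       sex_ratio = 0.48,
                       seed = 1L) {
  stop_cfg <- function(msg) stop("invalid simulation configuration: ", msg,
                                 call. = FALSE)

  for (nm in c("n_controls", "n_cases", "n_proteins")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != as.integer(v))
      stop_cfg(sprintf("`%s` must be a positive integer", nm))
  }
  if (!is.character(panel_labels) || length(panel_labels) < 1L)
    stop_cfg("`panel_labels` must be a non-empty character vector")
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      missing_rate < 0 || missing_rate >= 1)
    stop_cfg("`missing_rate` must lie in [0, 1)")
  if (length(age_range) != 2L || age_range[1] > age_range[2])
    stop_cfg("`age_range` must be an increasing length-2 range")
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1)
    stop_cfg("`sex_ratio` must lie in [0, 1]")
  date_range <- tryCatch(as.Date(date_range),
                         error = function(e) stop_cfg("unparseable `date_range`"))
  if (length(date_range) != 2L || any(is.na(date_range)) ||
      date_range[1] > date_range[2])
    stop_cfg("`date_range` must be two ordered parseable dates")
  if (!is.numeric(outlier_date_shift) || length(outlier_date_shift) != 1L)
    stop_cfg("`outlier_date_shift` must be a single number")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_cfg("`seed` must be a single integer")

  recycle <- function(x, nm) {
    if (!is.numeric(x)) stop_cfg(sprintf("`%s` must be numeric", nm))
    if (length(x) == 1L) return(rep(x, n_proteins))
    if (length(x) != n_proteins)
      stop_cfg(sprintf("`%s` has length %d; expected 1 or n_proteins = %d",
                       nm, length(x), n_proteins))
    x
  }
  effect_sizes <- recycle(effect_sizes, "effect_sizes")
  beta_age     <- recycle(beta_age, "beta_age")
  beta_sex     <- recycle(beta_sex, "beta_sex")
  beta_date    <- recycle(beta_date, "beta_date")
  protein_mean <- recycle(protein_mean, "protein_mean")
  protein_sd   <- recycle(protein_sd, "protein_sd")
  lod          <- recycle(lod, "lod")
  if (any(protein_sd <= 0)) stop_cfg("`protein_sd` must be strictly positive")

  structure(
    list(n_controls = as.integer(n_controls),
         n_cases = as.integer(n_cases),
         n_proteins = as.integer(n_proteins),
         panel_labels = panel_labels,
         effect_sizes = effect_sizes,
         beta_age = beta_age, beta_sex = beta_sex, beta_date = beta_date,
         protein_mean = protein_mean, protein_sd = protein_sd, lod = lod,
         missing_rate = missing_rate,
         date_range = date_range,
         outlier_date_shift = outlier_date_shift,
         age_range = as.integer(age_range),
         sex_ratio = sex_ratio,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  samples:  %d controls + %d cases\n", x$n_controls, x$n_cases))
  cat(sprintf("  proteins: %d across %d panels\n",
              x$n_proteins, length(x$panel_labels)))
  cat(sprintf("  non-null effects: %d (|delta| range %.3g-%.3g NPX)\n",
              sum(x$effect_sizes != 0),
              if (any(x$effect_sizes != 0)) min(abs(x$effect_sizes[x$effect_sizes != 0])) else 0,
              max(abs(x$effect_sizes))))
  cat(sprintf("  dates %s..%s, outlier shift %.3g NPX; missing rate %.3g; seed %d\n",
              format(x$date_range[1]), format(x$date_range[2]),
              x$outlier_date_shift, x$missing_rate, x$seed))
  invisible(x)
}
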