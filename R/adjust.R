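#' Residualize one protein's NPX values on age, sex and date
#'
#' Fits ordinary least squares of `values` on an intercept, age, sex and the
#' numeric collection date, and returns the residuals as covariate-adjusted
#' abundance. Rows with a missing value or missing covariate are dropped
#' case-wise before fitting. A rank-deficient design (e.g. a single sex left
#' after deletion) is handled by pivoting: the aliased column is dropped from
#' the fit and reported in `dropped`.
#'
#' @param values Numeric NPX vector for one protein.
#' @param age,sex,date_numeric Covariate vectors aligned with `values`.
#' @param min_n Minimum number of complete rows required (default 5); below it
#'   the protein is skipped (returns `NULL` with a warning).
#' @return `NULL` if skipped, otherwise a list with `residuals` (aligned with
#'   the input; `NA` where a row was dropped), `coefficients` (named; `NA` for
#'   aliased terms), `n` (rows used), `dropped` (aliased term names) and
#'   `used` (logical row mask).
#' @export
residualize_protein <- function(values, age, sex, date_numeric, min_n = 5L) {
  n_in <- length(values)
  if (length(age) != n_in || length(sex) != n_in || length(date_numeric) != n_in)
    stop("covariate vectors must match `values` in length", call. = FALSE)
  used <- complete.cases(values, age, sex, date_numeric)
  n <- sum(used)
  if (n < min_n) {
    warning(sprintf("only %d complete rows (< %d); protein skipped", n, min_n),
            call. = FALSE)
    return(NULL)
  }
  X <- cbind("(Intercept)" = 1, age = age[used], sex = sex[used],
             date_numeric = date_numeric[used])
  fit <- lm.fit(X, values[used])
  coefs <- fit$coefficients
  res <- rep(NA_real_, n_in)
  res[used] <- fit$residuals
  list(residuals = res, coefficients = coefs, n = n,
       dropped = names(coefs)[is.na(coefs)], used = used)
}

#' Residualize every protein in a cohort
#'
#' Applies [residualize_protein()] independently to each protein in the
#' (post-QC) NPX table, using age, sex and `date_numeric` from `meta`. The
#' group label is deliberately not part of the design: the group contrast is
#' estimated downstream on the residuals.
#'
#' @param npx Long-format NPX tibble after QC.
#' @param meta Per-sample metadata carrying `age`, `sex` and `date_numeric`
#'   (from [dates_to_numeric()] / [run_qc()]).
#' @param min_n Minimum complete rows per protein; proteins below it are
#'   skipped and listed in `skipped`.
#' @return An `npx_adjusted` list: `residuals` (tibble `sample_id`, `protein`,
#'   `residual`, complete rows only), `coefficients` (per-protein tibble of
#'   fitted terms, `n` and any dropped columns), `skipped` (proteins with too
#'   few complete rows).
#' @export
residualize_all <- function(npx, meta, min_n = 5L) {
  if (!"date_numeric" %in% names(meta))
    stop("`meta` lacks `date_numeric`; run run_qc() or dates_to_numeric() first",
         call. = FALSE)
  if (nrow(npx) == 0L) stop("empty NPX table", call. = FALSE)

  mi <- match(npx$sample_id, meta$sample_id)
  age <- meta$age[mi]; sex <- meta$sex[mi]; dnum <- meta$date_numeric[mi]

  idx <- split(seq_len(nrow(npx)), npx$protein)
  res_sid <- vector("list", length(idx)); res_val <- vector("list", length(idx))
  res_prot <- character(0)
  coef_rows <- vector("list", length(idx))
  skipped <- character(0)
  k <- 0L
  for (prot in names(idx)) {
    rows <- idx[[prot]]
    fit <- withCallingHandlers(
      residualize_protein(npx$npx[rows], age[rows], sex[rows], dnum[rows],
                          min_n = min_n),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(fit)) {
      skipped <- c(skipped, prot)
      next
    }
    k <- k + 1L
    res_sid[[k]] <- npx$sample_id[rows][fit$used]
    res_val[[k]] <- fit$residuals[fit$used]
    res_prot <- c(res_prot, prot)
    coef_rows[[k]] <- tibble(
      protein = prot, n = fit$n,
      intercept = fit$coefficients[["(Intercept)"]],
      age = fit$coefficients[["age"]],
      sex = fit$coefficients[["sex"]],
      date_numeric = fit$coefficients[["date_numeric"]],
      dropped = paste(fit$dropped, collapse = ","))
  }
  if (k == 0L) stop("no protein had enough complete rows to adjust",
                    call. = FALSE)
  if (length(skipped) > 0L)
    warning(sprintf("%d protein(s) skipped (fewer than %d complete rows): %s",
                    length(skipped), min_n,
                    paste(head(skipped, 5L), collapse = ", ")), call. = FALSE)
  res_sid <- res_sid[seq_len(k)]; res_val <- res_val[seq_len(k)]
  structure(
    list(residuals = tibble(
           sample_id = unlist(res_sid, use.names = FALSE),
           protein = rep(res_prot, lengths(res_val)),
           residual = unlist(res_val, use.names = FALSE)),
         coefficients = bind_rows(coef_rows[seq_len(k)]),
         skipped = skipped),
    class = "npx_adjusted")
}

#' @export
print.npx_adjusted <- function(x, ...) {
  cat(sprintf("<npx_adjusted> %d proteins, %d residual rows (%d skipped)\n",
              nrow(x$coefficients), nrow(x$residuals), length(x$skipped)))
  invisible(x)
}
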