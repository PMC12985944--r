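#' Group effect and p-value for one protein
#'
#' Computes the differential-abundance summary for a single protein from its
#' covariate-adjusted residuals: effect = mean(case) - mean(control), with a
#' two-sided two-sample t-test p-value (pooled variance by default, which is
#' equivalent to the OLS group-coefficient t-test; Welch optional). Raw group
#' mean NPX values are computed alongside for reporting when `npx_raw` is
#' supplied, over the same rows that enter the test.
#'
#' Degenerate case: when the pooled variance is exactly zero the p-value is 1
#' for a zero effect and the smallest representable positive double otherwise,
#' with `degenerate = TRUE`.
#'
#' @param residuals Numeric vector of adjusted values.
#' @param groups Vector of group labels, values `"normal"` and `"case"`.
#' @param npx_raw Optional vector of unadjusted NPX values aligned with
#'   `residuals`, used only for the reported raw group means.
#' @param test `"pooled"` (default) or `"welch"`.
#' @return A list `(effect, p_value, n_nor, n_cp, mean_nor, mean_cp,
#'   degenerate)`, or `NULL` with a warning when either group has fewer than
#'   two non-missing residuals.
#' @export
effect_and_pvalue <- function(residuals, groups, npx_raw = NULL,
                              test = c("pooled", "welch")) {
  test <- match.arg(test)
  ok <- !is.na(residuals)
  is_case <- groups == "case"
  x_nor <- residuals[ok & !is_case]
  x_cp <- residuals[ok & is_case]
  n1 <- length(x_nor); n2 <- length(x_cp)
  if (n1 < 2L || n2 < 2L) {
    warning(sprintf("group too small for testing (n_nor=%d, n_cp=%d)", n1, n2),
            call. = FALSE)
    return(NULL)
  }
  m1 <- mean(x_nor); m2 <- mean(x_cp)
  effect <- m2 - m1
  v1 <- stats::var(x_nor); v2 <- stats::var(x_cp)
  if (test == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  degenerate <- !is.finite(se) || se == 0
  if (degenerate) {
    p <- if (effect == 0) 1 else .Machine$double.xmin
  } else {
    p <- 2 * pt(-abs(effect / se), df)
    if (p == 0) p <- .Machine$double.xmin
  }
  mean_nor <- NA_real_; mean_cp <- NA_real_
  if (!is.null(npx_raw)) {
    mean_nor <- mean(npx_raw[ok & !is_case], na.rm = TRUE)
    mean_cp <- mean(npx_raw[ok & is_case], na.rm = TRUE)
  }
  list(effect = effect, p_value = p, n_nor = n1, n_cp = n2,
       mean_nor = mean_nor, mean_cp = mean_cp, degenerate = degenerate)
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' Computes BH q-values: with the p-values sorted ascending,
#' `q_(i) = min(1, min_{j >= i} p_(j) * m_total / j)`, mapped back to the
#' input order. `m_total` may exceed the length of `p_values`, which adjusts a
#' subset of the smallest p-values against the full number of tests performed
#' (as when re-deriving a published table's FDR column from its printed
#' p-values). Ties are handled by a stable sort, so identical p-values receive
#' identical q-values.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param m_total Total number of tests; must be at least `length(p_values)`.
#' @return Numeric vector of q-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.001, 0.01, 0.04), m_total = 3)
bh_adjust <- function(p_values, m_total = length(p_values)) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (m_total < length(p_values))
    stop("`m_total` must be at least length(p_values)", call. = FALSE)
  o <- order(p_values)
  raw <- p_values[o] * m_total / seq_along(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(raw))))
  q <- numeric(length(p_values))
  q[o] <- q_sorted
  q
}

#' Differential protein abundance over all tested proteins
#'
#' Runs [effect_and_pvalue()] per protein on the adjusted residuals, applies
#' [bh_adjust()] with `m_total` equal to the number of proteins actually
#' tested (overridable), and flags significance at `q_threshold`. Raw group
#' mean NPX values and the protein's panel are joined in from `npx`.
#'
#' @param adjusted An `npx_adjusted` object from [residualize_all()].
#' @param meta Per-sample metadata with `group`.
#' @param npx Optional post-QC NPX table supplying raw values and panel
#'   labels; without it raw means and panels are `NA`.
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @param test Passed to [effect_and_pvalue()].
#' @param m_total Override for the BH test count (>= number tested).
#' @return A `dpa_result` tibble sorted by ascending p-value with columns
#'   `protein, panel, mean_nor, mean_cp, effect, p_value, n_nor, n_cp,
#'   q_value, significant`. The number of tests used for BH is stored in
#'   `attr(, "m_total")`.
#' @export
run_dpa <- function(adjusted, meta, npx = NULL, q_threshold = 0.05,
                    test = c("pooled", "welch"), m_total = NULL) {
  test <- match.arg(test)
  resid <- adjusted$residuals
  if (nrow(resid) == 0L) stop("no adjusted values to test", call. = FALSE)
  grp <- as.character(meta$group[match(resid$sample_id, meta$sample_id)])

  raw <- rep(NA_real_, nrow(resid))
  panel_map <- NULL
  if (!is.null(npx)) {
    key <- paste(resid$sample_id, resid$protein)
    raw <- npx$npx[match(key, paste(npx$sample_id, npx$protein))]
    panel_map <- npx %>% distinct(.data$protein, .data$panel)
  }

  idx <- split(seq_len(nrow(resid)), resid$protein)
  rows <- vector("list", length(idx))
  skipped <- character(0)
  k <- 0L
  for (prot in names(idx)) {
    i <- idx[[prot]]
    st <- withCallingHandlers(
      effect_and_pvalue(resid$residual[i], grp[i], npx_raw = raw[i], test = test),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(st)) {
      skipped <- c(skipped, prot)
      next
    }
    k <- k + 1L
    rows[[k]] <- tibble(protein = prot, mean_nor = st$mean_nor,
                        mean_cp = st$mean_cp, effect = st$effect,
                        p_value = st$p_value, n_nor = st$n_nor,
                        n_cp = st$n_cp)
  }
  if (k == 0L) stop("no testable protein (each needs >= 2 samples per group)",
                    call. = FALSE)
  if (length(skipped) > 0L)
    warning(sprintf("%d protein(s) skipped in testing: %s", length(skipped),
                    paste(head(skipped, 5L), collapse = ", ")), call. = FALSE)
  out <- bind_rows(rows[seq_len(k)])
  m <- if (is.null(m_total)) nrow(out) else m_total
  out$q_value <- bh_adjust(out$p_value, m_total = m)
  out$significant <- out$q_value < q_threshold
  out$panel <- if (is.null(panel_map)) NA_character_ else
    panel_map$panel[match(out$protein, panel_map$protein)]
  out <- out %>%
    select("protein", "panel", "mean_nor", "mean_cp", "effect", "p_value",
           "n_nor", "n_cp", "q_value", "significant") %>%
    arrange(.data$p_value, .data$protein)
  attr(out, "m_total") <- m
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("dpa_result", class(out))
  out
}

#' Panel-stratified differential abundance
#'
#' Repeats the differential analysis within each panel category, with the BH
#' test count equal to the panel size (within-panel FDR). Effects and
#' p-values are identical to the global analysis; only the q-values (and thus
#' significance flags) depend on the stratification. Proteins without a panel
#' label are grouped under `"unknown"`.
#'
#' @inheritParams run_dpa
#' @param npx Post-QC NPX table supplying the panel map (required here).
#' @return Named list of `dpa_result` tibbles, one per non-empty panel.
#' @export
run_panel_dpa <- function(adjusted, meta, npx, q_threshold = 0.05,
                          test = c("pooled", "welch")) {
  test <- match.arg(test)
  panel_map <- npx %>% distinct(.data$protein, .data$panel) %>%
    mutate(panel = ifelse(is.na(.data$panel), "unknown", .data$panel))
  out <- list()
  for (pn in sort(unique(panel_map$panel))) {
    prots <- panel_map$protein[panel_map$panel == pn]
    sub <- adjusted
    sub$residuals <- adjusted$residuals %>% filter(.data$protein %in% prots)
    if (nrow(sub$residuals) == 0L) {
      warning(sprintf("panel '%s' has no adjusted proteins; skipped", pn),
              call. = FALSE)
      next
    }
    out[[pn]] <- run_dpa(sub, meta, npx = npx, q_threshold = q_threshold,
                         test = test)
  }
  out
}

#' Top proteins by p-value
#'
#' @param dpa A `dpa_result` tibble.
#' @param k Number of proteins to keep.
#' @return The `k` smallest-p rows in ascending p order.
#' @export
top_proteins <- function(dpa, k = 10L) {
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  head(dpa %>% arrange(.data$p_value, .data$protein), k)
}
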