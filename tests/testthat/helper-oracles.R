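# Independent oracles and constructed fixtures shared across the suite.

# Brute-force BH step-up straight from the definition: for the i-th smallest
# p-value, q_(i) = min(1, min over j >= i of p_(j) * m / j), with explicit
# loops and no reuse of the package's cummin trick.
bh_brute <- function(p, m_total = length(p)) {
  o <- order(p)
  ps <- p[o]
  k <- length(ps)
  q_sorted <- numeric(k)
  for (i in seq_len(k)) {
    cand <- Inf
    for (j in i:k) cand <- min(cand, ps[j] * m_total / j)
    q_sorted[i] <- min(1, cand)
  }
  q <- numeric(k)
  q[o] <- q_sorted
  q
}

# Least-squares via the normal equations, independent of lm.fit's QR path.
ols_normal_equations <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(beta = drop(beta), residuals = drop(y - X %*% beta))
}

# Brute-force recount of every QC fraction from raw flags/NA patterns.
recount_lod_removed <- function(npx, by, max_frac) {
  ids <- unique(npx[[by]])
  removed <- character(0)
  for (id in ids) {
    sub <- npx[npx[[by]] == id, ]
    n_obs <- sum(!is.na(sub$npx))
    if (n_obs > 0 && sum(sub$below_lod) / n_obs > max_frac)
      removed <- c(removed, id)
  }
  removed
}

recount_missing_removed <- function(npx, by, max_frac) {
  ids <- unique(npx[[by]])
  removed <- character(0)
  for (id in ids) {
    sub <- npx[npx[[by]] == id, ]
    if (mean(is.na(sub$npx)) > max_frac) removed <- c(removed, id)
  }
  removed
}

# Random full-grid NPX table with controllable censoring and missingness,
# used for the recount-equivalence property tests.
random_npx_table <- function(n_samples = 50, n_proteins = 50,
                             below_rate = 0.2, missing_rate = 0.15,
                             n_dates = 8, seed = 1) {
  set.seed(seed)
  sid <- sprintf("S%03d", seq_len(n_samples))
  prot <- sprintf("P%03d", seq_len(n_proteins))
  dates <- as.Date("2021-06-01") + sample.int(n_dates, n_samples,
                                              replace = TRUE)
  val <- rnorm(n_samples * n_proteins)
  val[runif(length(val)) < below_rate] <- -5      # below the LOD of -2
  val[runif(length(val)) < missing_rate] <- NA
  tibble::tibble(
    sample_id = rep(sid, times = n_proteins),
    protein = rep(prot, each = n_samples),
    panel = "unknown",
    npx = val,
    lod = -2,
    below_lod = !is.na(val) & val < -2,
    date = rep(dates, times = n_proteins)
  )
}

# Fixture with hand-countable QC violations, built so the cascade removes, in
# order: 3 proteins (>25% below LOD), 1 sample (>10% below LOD), 2 proteins
# (>20% missing), 1 sample (>20% missing), 1 date (|z| > 3).
# 20 samples x 12 proteins; LOD = -1 everywhere; below-LOD cells set to -2.
make_qc_fixture <- function() {
  n_s <- 20L; n_p <- 12L
  sid <- sprintf("S%02d", seq_len(n_s))
  prot <- sprintf("P%02d", seq_len(n_p))
  # deterministic small "noise" so daily SDs are nonzero but tiny
  base <- function(i, j) 0.01 * (((i * 7 + j * 3) %% 11) - 5)
  M <- outer(seq_len(n_s), seq_len(n_p), base)

  # 14 distinct dates among the samples surviving to the date stage
  # (S03..S20); the designated aberrant date d14 carries only S20.
  dates <- as.Date("2022-03-01") +
    c(1, 2,                              # S01, S02 (removed earlier)
      rep(1:13, length.out = 17),        # S03..S19
      14)                                # S20 -> aberrant date
  M[20, ] <- M[20, ] + 5                 # shift every S20 measurement

  # proteins P01-P03: 8/20 below LOD (40% > 25%)
  for (j in 1:3) M[1:8, j] <- -2
  # sample S01: 2 below-LOD cells among the 9 retained proteins (22% > 10%)
  M[1, 4:5] <- -2
  # proteins P04, P05: 5 missing cells among S02..S20 (5/19 = 26% > 20%)
  M[3:7, 4] <- NA
  M[3:7, 5] <- NA
  # sample S02: 2 missing cells among the 7 final proteins (2/7 = 29% > 20%)
  M[2, 6:7] <- NA

  val <- as.vector(M)
  npx <- tibble::tibble(
    sample_id = rep(sid, times = n_p),
    protein = rep(prot, each = n_s),
    panel = rep(rep(c("inflammation", "oncology"), length.out = n_p),
                each = n_s),
    npx = val,
    lod = -1,
    below_lod = !is.na(val) & val < -1,
    date = rep(dates, times = n_p)
  )
  meta <- tibble::tibble(
    sample_id = sid,
    participant_id = sprintf("PP%02d", seq_len(n_s)),
    age = rep(c(45L, 52L, 60L, 67L), length.out = n_s),
    sex = rep(c(0L, 1L), length.out = n_s),
    group = factor(rep(c("normal", "case"), c(14, 6)),
                   levels = c("normal", "case")),
    date = dates
  )
  list(npx = npx, meta = meta,
       expected = list(proteins_lod = c("P01", "P02", "P03"),
                       samples_lod = "S01",
                       proteins_missing = c("P04", "P05"),
                       samples_missing = "S02",
                       outlier_dates = as.Date("2022-03-01") + 14))
}

# Small clean cohort for smoke tests: no censoring, no missingness, no
# aberrant date, null effects unless stated.
clean_config <- function(...) {
  args <- utils::modifyList(
    list(n_controls = 60, n_cases = 20, n_proteins = 15,
         missing_rate = 0, outlier_date_shift = 0, lod = -10, seed = 1),
    list(...))
  do.call(sim_config, args)
}
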