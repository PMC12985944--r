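test_that("identical groups give a zero effect and p = 1", {
  x <- c(1, 2, 3, 1, 2, 3)
  grp <- rep(c("normal", "case"), each = 3)
  st <- effect_and_pvalue(x, grp)
  expect_equal(st$effect, 0)
  expect_equal(st$p_value, 1)
})

test_that("the 3-vs-3 toy matches the hand-computed pooled t-test", {
  resid <- c(-1, 0, 1, 0, 1, 2)
  grp <- rep(c("normal", "case"), each = 3)
  st <- effect_and_pvalue(resid, grp)
  expect_equal(st$effect, 1.0)
  # pooled variance 1, se = sqrt(1/3 + 1/3), t = sqrt(3/2), df = 4
  p_hand <- 2 * pt(-1 / sqrt(2 / 3), df = 4)
  expect_equal(st$p_value, p_hand, tolerance = 1e-12)
  # and agrees with stats::t.test as an independent route
  tt <- t.test(resid[grp == "case"], resid[grp == "normal"],
               var.equal = TRUE)
  expect_equal(st$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(st$n_nor, 3L)
  expect_equal(st$n_cp, 3L)
})

test_that("Welch option matches stats::t.test(var.equal = FALSE)", {
  set.seed(6)
  x <- c(rnorm(12, sd = 1), rnorm(30, sd = 3))
  grp <- rep(c("case", "normal"), c(12, 30))
  st <- effect_and_pvalue(x, grp, test = "welch")
  tt <- t.test(x[grp == "case"], x[grp == "normal"])
  expect_equal(st$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("degenerate zero-variance inputs are flagged, not mis-scored", {
  grp <- rep(c("normal", "case"), each = 3)
  same <- effect_and_pvalue(rep(1, 6), grp)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  apart <- effect_and_pvalue(rep(c(0, 1), each = 3), grp)
  expect_true(apart$degenerate)
  expect_gt(apart$p_value, 0)
  expect_lt(apart$p_value, 1e-100)
  expect_warning(expect_null(effect_and_pvalue(1:3, c("normal", "normal",
                                                      "case"))),
                 "too small")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  set.seed(13)
  for (i in 1:1000) {
    k <- sample(1:12, 1)
    p <- runif(k)
    m <- k + sample(0:20, 1)
    expect_identical(bh_adjust(p, m), bh_brute(p, m))
  }
  # and agrees with stats::p.adjust when m_total = length(p)
  p <- runif(50)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
})

test_that("BH q-values keep their defining properties", {
  set.seed(14)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))   # monotone step-up
  # permutation invariance of the p -> q mapping
  perm <- sample.int(40)
  expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-15)
  # ties receive identical q
  pt_ties <- c(0.01, 0.5, 0.01, 0.2)
  qt <- bh_adjust(pt_ties)
  expect_identical(qt[1], qt[3])
  # saturation and validation
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(runif(10), m_total = 5), "m_total")
})

test_that("published 29-protein q-values re-derive from their p-values", {
  ref <- periodontitis_reference()
  q <- bh_adjust(ref$p_value, m_total = attr(ref, "m_total"))
  # headline value: smallest p times 2151
  expect_equal(q[ref$protein == "GDF15"], 1.31e-15 * 2151, tolerance = 1e-12)
  expect_equal(signif(q[ref$protein == "GDF15"], 3), 2.82e-12)
  # step-up minimum: ranks 10-12 share rank 12's value
  shared <- q[ref$protein %in% c("RNASE1", "TNFRSF1A", "LGALS9")]
  expect_equal(unname(shared), rep(8.67e-8 * 2151 / 12, 3), tolerance = 1e-12)
  expect_equal(signif(shared, 3), rep(1.55e-5, 3), tolerance = 1e-12)
})

test_that("run_dpa orders by p, controls FDR labels, and handles m = 1", {
  ch <- generate_cohort(clean_config(n_proteins = 25, seed = 31))
  qc <- run_qc(ch$npx, ch$meta)
  adj <- residualize_all(qc$npx, qc$meta)
  dpa <- run_dpa(adj, qc$meta, npx = qc$npx)
  expect_identical(nrow(dpa), 25L)
  expect_false(is.unsorted(dpa$p_value))
  expect_true(all(dpa$q_value >= dpa$p_value - 1e-15))
  expect_identical(dpa$significant, dpa$q_value < 0.05)
  expect_identical(dpa$n_nor + dpa$n_cp,
                   as.integer(table(adj$residuals$protein)[dpa$protein]))

  # a single tested protein has q = p
  one <- adj
  one$residuals <- adj$residuals[adj$residuals$protein == "PROT0001", ]
  d1 <- run_dpa(one, qc$meta)
  expect_equal(d1$q_value, d1$p_value)
})

test_that("injected effects are found with the power the noncentral t predicts", {
  # 10 true effects (delta 0.5, sigma 1) among 200 proteins at n = 500/50.
  # Closed-form oracle: noncentrality delta / sqrt(1/500 + 1/50) ~ 3.37,
  # so per-protein detection probability at raw p < 0.05 is ~0.92.
  ncp <- 0.5 / sqrt(1 / 500 + 1 / 50)
  df <- 548
  tcrit <- qt(0.975, df)
  power <- 1 - (pt(tcrit, df, ncp) - pt(-tcrit, df, ncp))
  true_pos <- sprintf("PROT%04d", 1:10)
  deltas <- c(rep(0.5, 10), rep(0, 190))

  hits <- 0L; n_sig_q <- integer(0); top_is_true <- logical(0)
  effects <- numeric(0)
  for (s in 1:5) {
    cfg <- sim_config(n_controls = 500, n_cases = 50, n_proteins = 200,
                      effect_sizes = deltas, missing_rate = 0,
                      outlier_date_shift = 0, lod = -10, seed = 100 + s)
    ch <- generate_cohort(cfg)
    qc <- run_qc(ch$npx, ch$meta)
    adj <- residualize_all(qc$npx, qc$meta)
    dpa <- run_dpa(adj, qc$meta, npx = qc$npx)
    is_true <- dpa$protein %in% true_pos
    hits <- hits + sum(dpa$p_value[is_true] < 0.05)
    n_sig_q <- c(n_sig_q, sum(dpa$q_value[is_true] < 0.05))
    top_is_true <- c(top_is_true, dpa$protein[1] %in% true_pos)
    effects <- c(effects, dpa$effect[is_true])
  }
  rate <- hits / 50
  expect_lt(abs(rate - power), 3.5 * sqrt(power * (1 - power) / 50))
  # the true signals dominate the ranking and survive FDR control
  expect_true(all(top_is_true))
  expect_gte(mean(n_sig_q), 5)
  # effect estimates are centred on the injected 0.5
  expect_equal(mean(effects), 0.5, tolerance = 3 * 0.148 / sqrt(50))
})

test_that("p-values are uniform under label permutation of fixed data", {
  set.seed(23)
  x <- rnorm(60)
  grp0 <- rep(c("normal", "case"), c(45, 15))
  p <- replicate(1000, {
    effect_and_pvalue(x, sample(grp0))$p_value
  })
  alpha_hat <- mean(p < 0.05)
  expect_lt(abs(alpha_hat - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("panel-stratified analysis changes only the q-values", {
  ch <- generate_cohort(clean_config(n_proteins = 30, seed = 41))
  qc <- run_qc(ch$npx, ch$meta)
  adj <- residualize_all(qc$npx, qc$meta)
  global <- run_dpa(adj, qc$meta, npx = qc$npx)
  per_panel <- run_panel_dpa(adj, qc$meta, qc$npx)
  combined <- dplyr::bind_rows(lapply(per_panel, tibble::as_tibble))
  m <- match(global$protein, combined$protein)
  expect_equal(global$effect, combined$effect[m], tolerance = 1e-12)
  expect_equal(global$p_value, combined$p_value[m], tolerance = 1e-12)
  # within-panel m equals the panel size
  for (pn in names(per_panel))
    expect_identical(attr(per_panel[[pn]], "m_total"),
                     nrow(per_panel[[pn]]))
})

test_that("a protein can be panel-significant but not globally significant", {
  # constructed two-panel setting: one modest signal inside a 2-protein
  # panel, diluted among 40 null proteins globally
  set.seed(56)
  n1 <- 60; n2 <- 20
  grp <- rep(c("normal", "case"), c(n1, n2))
  sid <- sprintf("S%03d", seq_len(n1 + n2))
  meta <- tibble::tibble(sample_id = sid, participant_id = sid,
                         age = 50L, sex = 0L,
                         group = factor(grp, c("normal", "case")),
                         date = as.Date("2022-01-01"),
                         date_numeric = 0L)
  prots <- sprintf("P%02d", 1:42)
  panel <- c("small", "small", rep("big", 40))
  resid_rows <- lapply(seq_along(prots), function(j) {
    y <- rnorm(n1 + n2, sd = 1)
    if (j == 1) y <- y + 0.7 * (grp == "case")
    tibble::tibble(sample_id = sid, protein = prots[j], residual = y)
  })
  adj <- structure(list(residuals = dplyr::bind_rows(resid_rows),
                        coefficients = tibble::tibble(protein = prots),
                        skipped = character(0)),
                   class = "npx_adjusted")
  npx <- tibble::tibble(sample_id = rep(sid, times = 42),
                        protein = rep(prots, each = n1 + n2),
                        panel = rep(panel, each = n1 + n2),
                        npx = adj$residuals$residual, lod = -10,
                        below_lod = FALSE, date = as.Date("2022-01-01"))
  global <- run_dpa(adj, meta, npx = npx)
  stratified <- run_panel_dpa(adj, meta, npx)
  p1_global <- global[global$protein == "P01", ]
  p1_panel <- stratified$small[stratified$small$protein == "P01", ]
  expect_equal(p1_global$p_value, p1_panel$p_value, tolerance = 1e-12)
  # q differs by the multiplicity base: 42 vs 2 tests
  expect_gt(p1_global$q_value, p1_panel$q_value)
  expect_true(p1_panel$significant)
  expect_false(p1_global$significant)
})
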