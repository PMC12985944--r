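---
title: "Methods: QC and differential abundance for population-scale NPX proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC and differential abundance for population-scale NPX proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npxdiff)
```

## The analysis problem

Olink Explore proteomics reports relative protein abundance as NPX
(Normalized Protein eXpression), a log2-scale unit. In a population
case-control setting — thousands of participants, ~2000 assays, and a case
group one to two orders of magnitude smaller than the control group — the
question per protein is whether mean abundance differs between groups after
removing the nuisance structure that plasma proteomics is known to carry:
age and sex effects, drift with the measurement date, values censored below
each assay's limit of detection (LOD), and sporadic missingness.

`npxdiff` implements that analysis as a fixed, auditable cascade:
quality control, per-protein covariate residualization, two-group testing
with Benjamini-Hochberg (BH) FDR control, and panel-stratified re-analysis.

## Quality control

The cascade runs in a fixed order, because later denominators are defined
"across the retained proteins":

1. proteins with **more than 25%** of non-missing measurements below LOD are
   removed;
2. samples with **more than 10%** below-LOD values across retained proteins
   are removed;
3. proteins with **more than 20%** missing values are removed;
4. samples with **more than 20%** missing values across retained proteins
   are removed;
5. measurement dates whose daily mean NPX (pooled over all non-missing
   measurements on that date) has absolute z-score **greater than 3** are
   removed with all their samples.

Numerical conventions, chosen once and applied everywhere:

* **Strict inequalities.** "More than X%" means strictly greater: an entity
  exactly at a threshold is retained. The boundary is tested explicitly.
* **Denominators.** Below-LOD fractions are computed over non-missing
  measurements only, so a cell is never penalized twice (once as missing,
  once as censored). An entity with zero non-missing measurements cannot be
  assessed; it is removed and reported separately as degenerate.
* **Single pass, no fixpoint.** Each missingness filter runs once, protein
  axis before sample axis. Iterating to a joint fixpoint would be more
  aggressive but describes a different procedure.
* **Daily z-scores** use the sample standard deviation (denominator n − 1)
  of the daily means, self-inclusive (no leave-one-out). Pooling all
  measurements per date (rather than averaging per-sample means) weights
  samples by their non-missing counts; with near-complete data the two
  coincide. If all daily means are equal the standard deviation is zero, no
  date is flagged, and a warning is raised. At least 3 distinct dates are
  required; below that the stage is skipped with a warning.
* **Below-LOD values are flagged, not altered.** The only use of the LOD in
  this analysis is fraction-based filtering, so censored values keep their
  measured NPX. No imputation at any stage.
* **Idempotence.** Re-running the cascade on its own output removes nothing
  at the threshold filters. The date stage is the one exception by
  construction: z-scores are relative to the retained dates, so a second
  pass can in principle flag a new date. `run_qc` runs the stage once.

After filtering, dates are converted to the integer number of days since
the earliest date *of the filtered set*, the form in which date enters the
regression.

Every stage is recorded in a `qc_report` (counts before/removed/after plus
the removed identifiers), and the filters are verified against brute-force
recounts of every fraction on randomized 50×50 tables over 100 seeds.

## Covariate adjustment

For each protein \(j\), NPX values are regressed by OLS on an intercept,
age (years, untransformed), sex (0 = female, 1 = male) and numeric date:

\[ y_{ij} = \beta_0 + \beta_1 \mathrm{age}_i + \beta_2 \mathrm{sex}_i +
   \beta_3 t_i + e_{ij} \]

and the residuals \(r_{ij}\) are the covariate-adjusted abundances. Design
choices:

* **Per-protein case-wise deletion.** Rows missing the value or a covariate
  are dropped for that protein only, so per-protein n varies. Proteins with
  fewer than 5 complete rows are skipped with a warning.
* **Rank deficiency** (e.g. a single sex remaining after deletion) is
  handled by QR pivoting: the aliased column is dropped for that protein
  and logged. The remaining adjustment is preserved.
* **No standardization** of age or date: residuals are invariant to affine
  rescaling of covariates, so this only affects coefficient units (the
  generator's age effect is specified per SD of age; the fitted
  coefficient is per year, i.e. divided by sd(age)).
* **Group is never in the design.** The group contrast is estimated on the
  residuals downstream. This two-step procedure can differ slightly from
  the joint model when covariates correlate with group; the two-step form
  is the procedure implemented, and the Welch/pooled options below apply to
  its second step.

Residuals are tested for exact agreement (1e-8) with an independent
normal-equations solve, centring, orthogonality to each covariate, and
idempotence (residualizing residuals is the identity).

## Testing and FDR

Per protein, effect size = mean(case residuals) − mean(control residuals),
in NPX units. The default p-value is the two-sided pooled-variance
two-sample t-test on residuals — identical to the t-test of the group
coefficient in an OLS with the group indicator — with Welch's test as an
option. No empirical-Bayes variance moderation is applied: with ~2200 vs
~90 complete observations per protein, the per-protein variance estimate
has hundreds of degrees of freedom and moderation is immaterial; the plain
test is fully specified and exactly reproducible. Zero pooled variance is
flagged as degenerate (p = 1 for a zero effect, the smallest positive
double otherwise, so downstream BH input stays in (0, 1]).

BH q-values are computed by the step-up rule
\(q_{(i)} = \min(1, \min_{j \ge i} p_{(j)} m / j)\) with stable tie
handling (equal p ⇒ equal q). `bh_adjust()` accepts `m_total ≥ length(p)`,
which adjusts a subset of the smallest p-values against the full test
count — exactly what is needed to re-derive a published table's FDR column
from its printed p-values, and verified against a brute-force loop
implementation on all vectors of length ≤ 12.

The packaged reference table (`periodontitis_reference()`) carries the 29
proteins reported significant in a UK Biobank chronic-periodontitis plasma
analysis of 2151 QC-passing proteins. Re-deriving its q-values reproduces
20 of 29 printed values to 3 significant figures; the other 9 agree within
0.5%, the discrepancy being exactly the rounding of the printed
3-significant-figure p-values that feed the computation.

**Panel stratification.** The re-analysis within each panel reuses the same
effects and p-values and changes only the multiplicity base: within-panel
FDR with m = panel size. That is the natural reading of running the
differential analysis "within each panel"; reusing global q-values instead
would make the stratified run a pure re-plot. The choice is configurable by
calling `run_dpa` on a panel subset with an `m_total` override.

**Significance thresholds.** q < 0.05 is the default call. The reference
table's own selection cut sits at 1e-4 (its largest printed FDR is
8.48e-5); the threshold is a parameter everywhere, never hard-coded.

## The synthetic cohort generator

`generate_cohort()` draws from

\[ y_{ij} = \mu_j + \beta^{age}_j z(\mathrm{age}_i) + \beta^{sex}_j
   \mathrm{sex}_i + \beta^{date}_j t_i + \delta_j\,\mathrm{case}_i +
   s\,[\mathrm{date}_i = d^*] + \varepsilon_{ij}, \qquad
   \varepsilon_{ij} \sim N(0, \sigma_j^2), \]

then applies missing-completely-at-random blanking and sets below-LOD flags.
Defaults, fixed once as the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| n_controls / n_cases | 2251 / 90 | the emulated cohort's final group sizes |
| n_proteins | 200 | desk-scale default; study-scale runs use ~2151 |
| age_range | 40-69 years, uniform | the cohort's recruitment window |
| sex_ratio | 0.48 male | the cohort's approximate split |
| beta_age | 0.1 NPX per SD of age | modest, detectable covariate signal |
| beta_sex | 0.1 NPX | likewise |
| beta_date | 3e-4 NPX/day | ~0.1 NPX drift across a one-year window |
| protein_mean / protein_sd | 0 / 1 | NPX is relative; unit residual scale |
| lod | mu − 2.326 sigma | ~1% censoring, well under the 25% filter |
| missing_rate | 0.01 | sporadic MCAR missingness |
| date_range | one year | uniform sampling dates |
| outlier_date_shift | +1 NPX on the latest date | one aberrant date for QC to find |
| effect_sizes | 0 | null by default; studies inject deltas of 0.1-0.6 NPX |

What the generator does **not** emulate: heavy-tailed NPX distributions
(noise is Gaussian, so real outlier frequencies are not matched), plate and
bridging-normalization structure beyond the single date shift, dilution
groups, informative missingness, and any phenotype-assignment process —
group labels are assigned, not derived. Passing tests therefore demonstrate
that the *procedures* are correct under the stated noise model, not that
the specific published protein list would re-emerge from real data (which
is access-controlled and out of reach of a desk-scale build). One
calibration note: with unit residual SD, effects of 0.1-0.3 NPX at 90 cases
are underpowered (the published p-values imply per-protein residual SDs
well below 1), so the study-scale driver recovers only the largest injected
effects — an honest statement of power at sigma = 1, not a defect of the
estimator, which the tests show is unbiased.

Determinism: one integer seed governs the generator; identical
configurations produce identical cohorts byte for byte. QC, adjustment and
testing are deterministic by construction, so pipeline outputs are
reproducible from (config, seed) alone — the manifest records both.

## Verification problem sizes

The suite's simulation-based checks use: null mean-difference symmetry on
200 proteins at n = 150/50; empirical FDR on 20 complete-null cohorts of
500 proteins at n = 500/50; effect recovery (delta = 0.45, sigma = 1) at
n = 2251/90 over 200 replicates, compared against the closed-form standard
error \( \sigma\sqrt{1/2251 + 1/90} \approx 0.108 \); detection power for
delta = 0.5 among 200 proteins at n = 500/50 over 5 seeds, compared against
the noncentral-t prediction (~0.92 at per-comparison alpha 0.05); and
label-permutation uniformity over 1000 permutations. These sizes were
chosen so each property is measured with useful precision at desk scale.

## Known limitations

* The two-step residualize-then-test estimator is slightly conservative
  when covariates correlate with the group label; the joint-model
  equivalence holds exactly only under covariate balance.
* Within-panel FDR and global FDR answer different questions; a protein's
  significance can differ between them by multiplicity alone.
* The date-outlier z-score assumes approximately comparable numbers of
  measurements per date; a date carrying very few samples has a noisier
  daily mean and is more easily flagged.
* No Olink-internal QC flags (incubation/detection controls) are modelled
  or consumed; the pipeline starts from delivered NPX + LOD.
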