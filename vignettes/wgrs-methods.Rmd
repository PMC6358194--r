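---
title: "Weighted genetic risk scores for surgical recurrence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted genetic risk scores for surgical recurrence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgrs)
```

## The problem

Dupuytren's disease is a common fibroproliferative disorder of the palmar
fascia with high recurrence after surgery. Four clinical features — onset
before age 50, bilateral disease, ectopic fibrotic lesions, and positive
family history — form the Dupuytren's *diathesis* and mark an aggressive
disease course. Because susceptibility is strongly heritable and polygenic,
a per-patient *weighted genetic risk score* (wGRS) built from
genome-wide-significant susceptibility variants is a candidate prognostic
marker for recurrence, over and above the clinical diathesis.

This package implements that analysis chain end to end: score computation,
sample exclusion, score categorization, multiple imputation of missing
clinical data, case-only logistic association models, and fixed-effect
meta-analysis across two cohorts — together with a synthetic cohort
generator so the chain can be exercised and validated without
access-controlled patient data.

## The score

For a panel of $N$ biallelic SNPs with per-allele disease odds ratios
$OR_i$, the weight of SNP $i$ is $W_i = \ln OR_i$ and a patient's score is

$$ wGRS \;=\; \frac{N}{n} \sum_{i \in \text{genotyped}} W_i X_i , $$

where $X_i \in \{0,1,2\}$ counts the patient's effect alleles and $n$ is the
number of panel SNPs actually genotyped for that patient. The $N/n$ factor
rescales partially genotyped patients onto the full-panel scale, which is
unbiased when genotypes are missing at random and the missing SNPs'
expected contribution matches the genotyped ones. Patients genotyped at
fewer than `min_genotyped` SNPs (default 2) carry too little information
for this rescaling to be defensible and are excluded up front
(`filter_low_genotyping()`), generalizing the exclusion of samples
genotyped at a single SNP.

Effect-allele identity is enforced strictly on input: a VCF record is used
only if both its id and its \{REF, ALT\} pair match the panel entry, and no
strand flipping is ever attempted — a silently flipped allele corrupts every
downstream score, so mismatches fail loudly.

The shipped panel (`default_panel()`) is **synthetic**: 26 entries with
odds ratios between 1.11 and 1.98, the range typical of
genome-wide-significant common variants for this disease. The published
26-SNP panel sits behind controlled-access repositories; users who hold it
substitute a TSV with the same columns via `read_weight_table()`.

## Categorization and distributional checks

Scores are analyzed two ways: as a continuous per-unit predictor, and in
four categories with the reference population's mean − 1 SD, mean, and
mean + 1 SD as thresholds (sample SD, $n-1$ denominator). Intervals are
left-closed above — $(-\infty, m-s)$, $[m-s, m)$, $[m, m+s)$,
$[m+s, \infty)$ — so a score exactly at a threshold falls in the upper
group; under normality the expected shares are 15.9/34.1/34.1/15.9%.
Because the recurrence analyses are case-only and the cohorts' score
distributions differ, thresholds default to the cases of the same cohort;
any reference vector can be supplied instead.

`score_distribution_report()` provides the distributional companions: a
mean-centered Levene test for variance equality (via
`car::leveneTest(center = mean)`), a two-tailed two-sample $t$ test —
pooled-variance when the Levene p-value is ≥ 0.05, Welch otherwise — and
normal Q-Q coordinates emitted as plot-ready pairs rather than a figure.

## Missing data: chained equations

Missing clinical variables and scores are handled by multiple imputation by
chained equations (`mice_impute()`), with defaults of m = 75 completed
datasets and 100 cycles and the variable chain recurrence, wGRS, family
history, early onset, ectopic disease, bilateral disease, sex. Ectopic
disease participates as a predictor but is only imputed when it actually has
missing values. Choices the method family leaves open were fixed as
follows:

* **Conditional models.** Binary variables: logistic regression fitted on
  observed rows, coefficients perturbed by one draw from their asymptotic
  normal, then a Bernoulli draw. Continuous wGRS: Bayesian normal linear
  regression (scaled inverse-$\chi^2$ draw of the residual variance,
  normal draw of the coefficients, residual noise on predictions). The
  wGRS is imputed on the score scale, not via genotypes.
* **Visit order.** Ascending missingness rate, ties broken by chain order.
* **Initialization.** Random draws from each variable's observed values,
  independently per chain.
* **Separation guard.** If a conditional logistic fit diverges (complete or
  quasi-complete separation), it is refitted with a small ridge penalty
  (1e-6) on the penalized likelihood; the fallback is logged.
* **Seeds.** One master seed spawns an independent substream per chain, so
  chains are exchangeable and reproducible.

Estimates across the m datasets are combined by Rubin's rules
(`pool_rubin()`): pooled point estimate = mean; total variance = mean
within-imputation variance + $(1 + 1/m)\times$ between-imputation variance;
inference on a $t$ distribution with Barnard–Rubin adjusted degrees of
freedom (reducing to the classical large-sample df when the complete-data
df is infinite).

## Association models

All regressions are fitted by Newton's method with step-halving on the
exact likelihood, to a gradient max-norm below 1e-8 (cap 50 iterations),
with the covariance taken as the inverse observed information at the
optimum. Odds ratios carry Wald 95% intervals ($z = 1.959964$) and
two-sided p-values; no multiple-testing correction is applied, matching the
p < 0.05 convention of the analysis this package operationalizes.
Separation is a hard error, not a silently enormous odds ratio — with four
binary clinical covariates it is a live possibility at small n, and an
explicit failure is more honest than an OR of $10^6$.

The table-level analyses are case-only:

* `per_unit_association()` — recurrence (or any diathesis feature) on the
  continuous wGRS, optionally diathesis-adjusted.
* `recurrence_by_category()` — recurrence on indicators for categories 2–4
  versus the lowest category, unadjusted and adjusted for the four
  diathesis features; on an imputed stack the categories are re-derived
  within each completed dataset (the imputed scores differ across
  datasets), fitted per dataset, and Rubin-pooled.
* `diathesis_count_analysis()` — recurrence on indicators for carrying
  1–4 diathesis features versus none. This model is saturated in the
  count, so each OR equals the contingency-table cell ratio; a count level
  that is absent or has no outcome variation (its cell OR is not finite)
  is flagged unavailable rather than crashing the run.
* `category_diathesis_association()` — multinomial (softmax) regression of
  the four-level category on one diathesis feature at a time (univariable,
  matching a per-feature analysis; reference = lowest category).

## Meta-analysis

Per-cohort log odds ratios are combined by the fixed-effect
inverse-variance method: weights $w_i = 1/se_i^2$, pooled estimate
$\sum w_i \hat\theta_i / \sum w_i$, pooled SE $(\sum w_i)^{-1/2}$. Pooling
happens on the log-OR scale; within-cohort Rubin pooling happens first,
then cohorts are meta-analyzed. Adjusted and unadjusted estimates are
pooled separately. Cochran's Q and $I^2$ are reported as descriptive
heterogeneity diagnostics only — the model is fixed-effect by design.
`se_from_ci()` lets users meta-analyze published OR/CI triples by the Wald
back-transform, warning when the interval is too asymmetric on the log
scale to have been Wald.

## The synthetic cohort generator

No public individual-level data exist for this design, so the generator
(`simulate_cohort()`, `simulate_two_cohorts()`) emulates the study
structure with an explicit generative model — an observational design has
no "true" generative model, so this one is the package's own choice,
stated here:

1. Genotypes: $X_i \sim \text{Binomial}(2, p_i)$, Hardy–Weinberg, no
   linkage disequilibrium or population stratification.
2. Disease: $\Pr(\text{case}) = \text{logistic}(\alpha_0 + \sum_i W_i X_i)$
   — the panel weights act as the generative per-allele log odds ratios.
   Cases and controls are ascertained from simulated batches until the
   configured quotas are met.
3. Diathesis (cases only): each feature
   $f \sim \text{Bernoulli}(\text{logistic}(a_f + \gamma_f \cdot wGRS))$.
4. Recurrence (cases only):
   $\text{logistic}(\alpha_r + \beta \cdot wGRS + \sum_f \delta_f f)$.
5. Missingness: MCAR at configurable rates on genotype cells and on the
   imputable phenotype fields (never ectopic disease by default, which is
   observed completely in the larger cohort). MCAR is the only mechanism
   under which parameter-recovery tests have exact targets; MAR-by-covariate
   is a documented extension hook, not implemented.

The shipped presets (`cohort_config("uk")`, `cohort_config("nl")`) encode
the study conditions: cohorts of 6126 and 1730 cases, a ~3:1 male:female
ratio, bilateral disease at 63% and 40%, ectopic disease near 10–12%, and
per-unit wGRS→recurrence odds ratios of 1.18 and 1.22. Where the public
record gives no number — family history (44%/38%), early onset (38%/34%),
recurrence prevalence (30%/25%), control counts (6000/1700), the diathesis
effects on recurrence ($\delta$: 1.5, 2.2, 1.6, 1.4 as ORs) and the wGRS
effect on each feature ($\gamma$: OR 1.2 per unit) — the presets use values
a clinical epidemiologist would call realistic for this disease; they are
fixed once here and not tuned. Intercepts are calibrated to these marginal
prevalences by root-finding (`calibrate_config()`) on a 50,000-sample
calibration population with a fixed internal seed, so calibration never
perturbs a user's seeded draws.

Two emulation caveats matter when interpreting green tests. First, because
case status loads on the raw weighted burden with unit slope, the
simulated case–control score separation (≈ 0.9 score units) and the case
mean (≈ 6.8) sit somewhat above the published 6.32 vs 5.44; matching those
means exactly would require attenuating the generative disease model, which
the package deliberately does not do. Second, the generator omits linkage
disequilibrium, ascertainment by referral, and any sex effect on the score,
so passing tests certify the statistical machinery, not those aspects of
real cohorts.

The wGRS of a 26-SNP panel with moderate frequencies is a sum of 26 bounded
independent terms and is close to normal (the package's tests check this in
the Lilliefors sense), which is what makes the mean ± SD categorization
meaningful.

## Numerical and interface choices

* Sample SD uses the $n-1$ denominator throughout.
* Sex is coded 0 = female, 1 = male; binary fields are 0/1/NA; missing
  sentinels are `NA` (tables), `./.` or `.` (VCF) — nothing else.
* The rescaling constant is the panel's own size $N$, not a hard-coded 26,
  so other panels work; 26 is simply the shipped default.
* Degenerate inputs fail with classed errors (`wgrs_format_error`,
  `wgrs_config_error`, `wgrs_numeric_error`, `wgrs_separation_error`) that
  the command-line wrapper maps to exit codes 3, 2, 4, 4.
* `run_pipeline()` plus the exported per-stage functions are the package's
  interface; a thin `Rscript` wrapper (`inst/scripts/wgrs_pipeline.R`)
  covers shell use. Every artifact is a TSV/CSV/JSON with a YAML provenance
  sidecar naming the stage and seed, and a fixed seed reproduces a run
  byte for byte.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the machinery at sizes chosen
to give stable Monte-Carlo assertions while staying quick on one CPU:
parameter recovery at 20,000 cases, Wald-coverage sweeps of 200 replicates
at n = 2,000, imputation validation at 10,000 cases with 20% MCAR and
m = 5 / 10 cycles, and the two-cohort demo pipeline at 500/300 cases with
m = 3 / 5 cycles. The acceptance script analyzes the full preset cohort
sizes (6126 and 1730 cases) with m = 5 / 10 cycles; the m = 75 / 100-cycle
default remains the production setting.

## Known limitations

* No imputed-dosage genotypes, PLINK formats, or BCF streaming.
* No linkage disequilibrium or stratification in the generator.
* No time-to-recurrence modelling: recurrence is a binary phenotype here.
* No random-effects meta-analysis or small-study diagnostics.
* Whether the original category thresholds used cases only or cases plus
  controls is not public; both are supported, cases-only is the default.
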