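---
title: "Weighted genetic predisposition scores: model, construction and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted genetic predisposition scores: model, construction and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsassoc)
```

## The problem

Individually, common BMI-associated SNPs have effects too small to detect in
cohorts of a few hundred people. A weighted genetic predisposition score
(GPS; also called a GRS or PRS) aggregates them: genotypes are coded 0/1/2
as copies of the BMI-raising *effect allele*, each count is multiplied by
the SNP's published per-allele effect $\beta_i$ (kg/m$^2$), and the products
are summed,

$$\mathrm{raw}_j = \sum_{i=1}^{m} \beta_i \, g_{ij}.$$

To make the score interpretable, it is rescaled to *risk-allele units*:
dividing by the raw maximum $2\sum_i \beta_i$ and multiplying by the number
of alleles $2m$ maps it onto $[0, 2m]$, so one point corresponds to about
one average-weight risk allele. For a 29-SNP panel whose weights sum to
4.12 this is the familiar "divide by 8.24, multiply by 58" rule;
`rescale_score()` applies the generalized form, so a reduced panel (for
example the 25-SNP sensitivity rerun) renormalizes automatically to a 0-50
scale.

## Score construction rules

* **Coding and orientation.** The panel is authoritative. VCF genotypes are
  recoded per SNP to effect-allele counts whatever the REF/ALT polarity;
  a panel/VCF allele-set mismatch is a hard error because silent strand
  guessing corrupts scores. A/T and C/G SNPs therefore must match exactly.
* **Imputation.** A missing genotype is replaced by the sample mean coded
  genotype of that SNP (equal to twice the effect-allele frequency), so an
  individual's score is not deflated by missing calls. Imputation means are
  computed on the full genotyped sample *before* the individual exclusion
  below, because imputation is part of score calculation while the
  exclusion is a separate sample restriction; `compute_gps()` exposes
  `impute_after_exclusion` to switch this, and at realistic missingness the
  two differ negligibly.
* **Exclusion.** Individuals with more than `max_missing = 3` missing panel
  genotypes are excluded from score analyses (score set to `NA`); exactly
  3 missing is kept.
* **Quartiles.** Cut points are the empirical 25/50/75 percentiles of the
  analysis sample - they are sample statistics, not constants of the
  method. Intervals are half-open with a value exactly at a cut point
  assigned to the upper quartile (a deterministic tie rule).

## Quality control

`qc_report()` mirrors the usual per-SNP QC table: genotype counts over
non-missing calls, call rate, effect-allele frequency
$(n_1 + 2n_2)/(2n)$, a Hardy-Weinberg equilibrium test, and a comparison
of the observed allele distribution against a reference (discovery-study)
frequency.

The HWE test is the 1-df Pearson chi-square of the observed counts against
$n\,((1-f)^2,\, 2f(1-f),\, f^2)$ at the sample frequency $f$, without
continuity correction. The exact conditional test (Wigginton, Cutler &
Abecasis 2005) is available via `method = "exact"`; for some published
tables the printed p-values are only consistent with the exact test, so
both are provided, with the chi-square as the default. Monomorphic SNPs
return $p = 1$ rather than an error so that small simulated panels do not
crash a pipeline. The reference comparison is a 1-df goodness-of-fit of the
observed allele counts against the reference proportions - reference
*counts* are typically unavailable, so a two-sample test is not attempted.
Multiplicity uses the Bonferroni threshold $\alpha/m$ with $m$ the number
of SNPs surviving the call-rate filter (0.05/29 = 0.0017 for the full
panel).

The call-rate filter keeps SNPs genotyped in at least 95% of individuals;
the boundary itself is kept.

## Association models

All models use an additive genetic model: the exposure (score in allele
units, or a single coded genotype) enters linearly.

* Continuous traits (BMI, waist, hip, waist-to-hip ratio) use ordinary
  least squares; obesity uses maximum-likelihood logistic regression.
  Standard errors, 95% CIs ($\pm 1.96\,\mathrm{SE}$) and p-values are Wald
  throughout - published symmetric CIs are consistent with Wald, and
  likelihood-ratio variants are deliberately not implemented.
* Default adjustment set: age, sex (female vs male), physical activity
  (an ordered four-level score entered as integer 0-3) and smoking
  (current vs not, by default; a three-level factor coding is available).
  Waist and hip models support a second adjustment set adding BMI, which
  tests whether their association with the score is mediated by BMI.
* Missing covariates are handled by listwise deletion, and the number of
  dropped rows is recorded on every result.
* Obesity analyses contrast normal-weight (BMI < 25) with obese
  (BMI >= 30) individuals; overweight individuals belong to neither group
  and are removed inside the pipeline before case-control fits, while the
  full sample is retained for continuous traits.
* The quartile analysis fits indicator-coded quartiles against quartile 1
  (reference OR fixed at 1), and the trend p-value comes from a second
  model with the quartile index entered as a single ordinal 0-3 term - a
  standard epidemiological convention.
* `explained_variance_decomposition()` reports $R^2$ (in percent) of the
  crude model (trait ~ score), of the full model (trait ~ score +
  covariates), and their difference as the covariate share.
* `direction_consistency()` counts per-SNP effect estimates whose sign
  matches the discovery direction (positive under effect-allele coding)
  and tests the count with the exact one-sided binomial tail
  $P(X \ge k \mid n, 1/2)$; an estimate of exactly zero is counted as
  inconsistent. The uncorrected normal approximation is available for
  comparison but the exact tail is primary: for 23 consistent of 29 it
  gives $621{,}616/2^{29} = 0.00116$.

## The synthetic cohort generator

No individual-level data accompany studies of this kind, so the package
carries a generator that emulates the statistical structure the analysis
assumes; every stage is tested end-to-end against it.

* **Genotypes.** Each SNP is drawn independently as binomial(2, eaf) at the
  bundled panel's observed cohort frequencies - Hardy-Weinberg by
  construction, no linkage disequilibrium. Missing calls are masked
  uniformly per cell at rate 0.05, emulating a 95% genotyping success
  rate; over 29 SNPs this excludes roughly 6% of individuals under the
  more-than-3-missing rule, about 46 of 787, matching the scale of
  exclusion such cohorts report.
* **Weights.** Published panels rarely print their weights. The bundled
  `synthetic_weights.tsv` is an explicitly synthetic stand-in: 29 positive
  values with a GWAS-like decreasing profile, constrained to sum to 4.12
  (so twice the sum is the canonical 8.24 divisor) and spread-calibrated
  so the rescaled score's SD under Hardy-Weinberg independence is 3.7
  allele units, the value reported for the real weighted panel. They are
  not the discovery-study betas and are intended for simulation only.
* **Covariates.** Age uniform on [30, 64]; sex female with probability
  409/787; smoking never/former/current at (0.55, 0.20, 0.25); activity
  uniform over its four levels. These distributions, and the covariate
  effect directions (age +, female -, activity -, smoking -), are
  conventions of the generator, not claims about any real cohort.
* **BMI variance budget (closed form).** With per-allele effect $b = 0.15$
  kg/m$^2$ and score variance $V_g = 3.7^2$, the genetic component
  contributes $b^2 V_g \approx 0.31$; covariate coefficients are a fixed
  shape rescaled so their variance equals $13.1\%$ of the total
  $\sigma^2 = 5.5^2$; residual noise takes the remainder. The total SD of
  5.5 kg/m$^2$ is itself a modelling default chosen to make the triple
  {per-allele 0.15, SD(score) 3.7, crude $R^2$ 1.0%} internally
  consistent ($0.15^2 \times 3.7^2 / 5.5^2 \approx 1.0\%$); it is
  configurable. A budget whose components exceed the total is a
  configuration error, not a silent renormalization.
* **Obesity.** Two modes. *Logistic*: case status drawn from
  $\mathrm{logit}\,P = \alpha + \ln(1.11)(\mathrm{GPS}-\overline{\mathrm{GPS}})
  + 0.25\,C$ with $C$ the BMI covariate term and $\alpha$ solved
  numerically for a prevalence of 0.33 (the obese share among non-overweight
  adults in comparable cohorts); here the per-allele OR of 1.11 is the
  *true conditional parameter*, which is what OR-recovery tests need.
  *Threshold*: obesity is simulated BMI $\ge$ 30, for end-to-end realism
  including the overweight-exclusion step.
* **Anthropometry.** Height is drawn per sex and weight back-derived as
  BMI $\times$ height$^2$, so the Quetelet identity is exact. Waist and
  hip are generated from BMI alone plus noise - deliberately, so that the
  score-waist association is mediated by BMI by construction and the
  BMI-adjusted attenuation can be demonstrated.

**What the generator does not emulate:** linkage disequilibrium between
SNPs, assortative mating, non-uniform (assay-driven) missingness,
measurement error in anthropometry, or real covariate-genotype
correlation. Passing recovery tests therefore shows the estimator chain is
correct under the stated model, not that any real cohort satisfies that
model.

One interaction worth knowing: uniform 5% cell missingness puts every
SNP's expected call rate exactly at the 0.95 filter boundary, so roughly
half of simulated SNPs fall below it in any one cohort. Real missingness
is concentrated in failing assays rather than spread uniformly. Pipeline
examples that exercise the call-rate filter therefore simulate at a 2%
rate; score-recovery analyses compute scores on the full panel directly.

## Numerical choices and degenerate inputs

* Quartile ties go up; fewer than four distinct scores is an error.
* Monomorphic SNPs: HWE $p = 1$; a degenerate reference frequency (0 or 1)
  is an error for the frequency comparison.
* Logistic separation (fitted probabilities of 0/1) and non-convergence
  raise explicit errors rather than returning unstable estimates.
* Collinear designs raise a singular-design error naming the aliased
  columns.
* All simulation stages are deterministic given a seed; identical
  configurations produce byte-identical cohort files.

## Problem sizes used in the tests

The recovery checks run 50 cohorts of $n = 740$ for point estimates
(per-allele BMI effect, obesity OR, $R^2$ shares) and 200 cohorts for CI
coverage; oracle equivalences use 1,000 random genotype-count triples and
1,000-replicate null simulations at $n = 500$. These sizes put Monte-Carlo
error comfortably inside the asserted tolerances while keeping the whole
suite fast on a single CPU.

## Known limitations

* Bi-allelic autosomal SNPs only; no liftover, phasing, LD pruning or
  reference-panel imputation.
* The exact binomial direction test is one-sided by design; two-sided
  conventions differ between software and are not reproduced.
* The per-SNP association threshold (0.0017) assumes 29 independent tests;
  correlated panels would need a different multiplicity correction.
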