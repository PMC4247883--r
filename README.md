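# gpsassoc

Weighted genetic predisposition scores (GPS/GRS) for BMI and obesity
studies, with the full analysis pipeline around them: SNP-panel quality
control, score construction, covariate-adjusted association models, and a
deterministic synthetic cohort generator so everything can be tested
without individual-level data.

The package is aimed at genetic-epidemiology analysts replicating
established BMI loci in new population samples of moderate size, where
single-SNP tests are underpowered and the combined score is the primary
exposure.

## The method

Genotypes are coded $g_{ij} \in \{0,1,2\}$ as copies of the BMI-raising
effect allele. The score of individual $j$ over an $m$-SNP panel with
published per-allele effects $\beta_i$ (kg/m²) is

```
raw_j = Σ_i β_i g_ij          (missing g imputed by the SNP's mean dosage = 2·EAF)
GPS_j = raw_j / (2 Σ β_i) × 2m   (risk-allele units, range 0..2m)
```

For a 29-SNP panel with Σβ = 4.12 the rescaling is the canonical "divide
by 8.24, multiply by 58"; reduced panels renormalize automatically.
Individuals with more than 3 missing panel genotypes are excluded from
score analyses. QC covers per-SNP genotype counts, effect-allele
frequency, a 1-df Pearson Hardy–Weinberg χ² (exact test optional), a
≥ 95 % call-rate filter, allele-frequency comparison against the
discovery population, and a Bonferroni threshold α/m (0.05/29 = 0.0017).
Associations use additive linear models for continuous traits and
logistic models for obesity (normal weight vs obese, overweight removed),
with quartile odds ratios, an ordinal trend test, explained-variance
decomposition, and an exact binomial test of per-SNP direction
consistency.

## Worked example

A fully synthetic cohort of 787 adults is generated at the bundled panel's
allele frequencies (with the package's clearly-labelled *synthetic*
weights, since the published record does not include the real ones), the
score is built, and the adjusted BMI association is fitted:

```r
library(gpsassoc)

panel  <- isor_panel(synthetic_weights = TRUE)
cohort <- simulate_cohort(simulation_config(n = 787, seed = 42))
scores <- compute_gps(cohort$genotypes, panel)

sum(!scores$excluded)   # 741 scored
sum(scores$excluded)    # 46 excluded (> 3 missing genotypes)

ok  <- !scores$excluded
adj <- c("age", "sex", "activity", "smoking")
fit_linear(cohort$phenotypes$bmi[ok], scores$gps[ok],
           cohort$phenotypes[ok, ], adj)
#> linear model: outcome ~ exposure  (n = 741)
#>   beta 0.165 (SE 0.056) [0.055 - 0.275], p = 0.0034
#>   explained variance: crude 1.37%, full 12.43%
#>   adjusted for: age, sex, activity, smoking
```

The per-allele estimate of 0.165 kg/m² is this cohort's draw around the
generator's true effect of 0.15 kg/m²; the crude explained variance of
1.37 % sits around the configured ≈ 1 % genetic share, and the full-model
R² around the ≈ 14 % genetic-plus-covariate budget. The QC table gives the
usual per-SNP view:

```r
head(qc_report(cohort$genotypes_complete, panel)[,
     c("snp_id", "locus", "n0", "n1", "n2", "eaf", "hwe_p")], 3)
#>      snp_id  locus  n0  n1  n2       eaf     hwe_p
#> 1 rs9939609    FTO 302 367 118 0.3831004 0.7066534
#> 2 rs2867125 TMEM18  18 213 556 0.8418043 0.6499691
#> 3  rs571312   MC4R 460 278  49 0.2388818 0.4226071
```

`run_pipeline(run_config(...))` chains the whole analysis (QC → score →
Tables-style association, quartile and variance reports → sensitivity
rerun without user-chosen SNPs) and writes the report bundle;
`inst/scripts/gps-pipeline.R` exposes `run`, `simulate`, `qc` and `score`
subcommands on the shell.

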