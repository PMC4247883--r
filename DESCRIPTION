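Package: gpsassoc
Title: Weighted Genetic Predisposition Scores and Obesity-Trait Association Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Construction and analysis of weighted genetic predisposition
    scores (GPS) for body-mass-index and obesity studies. Provides SNP-panel
    quality control (genotype counts, effect-allele frequencies,
    Hardy-Weinberg equilibrium tests, call-rate filtering, allele-frequency
    comparison against a reference population), score construction with
    mean-dosage imputation of missing genotypes and rescaling to risk-allele
    units, covariate-adjusted linear and logistic association models for
    anthropometric traits and obesity risk, quartile odds-ratio and trend
    analysis, explained-variance decomposition, a direction-consistency
    binomial test, and a fully deterministic synthetic cohort generator so
    that every stage of the pipeline can be tested end-to-end without
    access to individual-level study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
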