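Package: gxecross
Title: Crossover Gene-Environment Interaction Analysis for
    Diathesis-Stress and Differential Susceptibility Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Confirmatory analysis of a gene-environment (GxE) interaction
    between a biallelic SNP (dominant carrier coding) and a continuous
    environmental exposure on a quantitative outcome. Provides genotype
    coding and Hardy-Weinberg equilibrium testing, cohort descriptives
    (Pearson correlations, pooled two-sample t-tests from raw data or from
    printed summary statistics), hierarchical moderated regression with
    per-step delta R-squared and simple slopes, Johnson-Neyman region-of-
    significance and crossover analysis with bootstrap or delta-method
    confidence intervals, the four re-parameterized crossover regression
    models (strong/weak diathesis-stress versus strong/weak differential
    susceptibility) with nested F tests and AIC/BIC model selection, and a
    synthetic-cohort generator with Hardy-Weinberg genotypes, correlated
    covariates and configurable interaction form so the whole pipeline is
    testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
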