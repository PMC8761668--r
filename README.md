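# gxecross

Confirmatory analysis of crossover gene–environment (G×E) interactions:
does a biallelic SNP moderate the effect of a continuous environmental
exposure on a quantitative trait, and if so, is the moderation of the
*diathesis-stress* form (risk-allele carriers fare worse only under
adversity; the genotype groups' regression lines cross at the most
adverse observed environment) or the *differential-susceptibility* form
(plasticity-allele carriers are worse under adversity but better in
benign environments; the lines cross at an interior value)?

The package grew out of a candidate-gene study of ZNF804A rs1344706
(dominant T-carrier coding) × alcohol-problem severity (MAST total) on
impulsivity (BIS total) in n = 452 men hospitalized for alcohol
dependence. It is aimed at researchers running the same confirmatory
workflow on their own cohort — or, since the original subject-level
data were not deposited, on synthetic cohorts with the published
statistical structure.

## What it computes

For outcome Y (z-scored), environment X (z-scored), carrier group
D ∈ {0, 1} and covariates, the four re-parameterized crossover models

    Y = B0 + B1·(X − C) + B4·edu + ε    (D = 0)
    Y = B0 + B2·(X − C) + B4·edu + ε    (D = 1)

* Model A — strong differential susceptibility (B1 = 0, C free)
* Model B — weak differential susceptibility (B1 free, C free)
* Model C — strong diathesis-stress (B1 = 0, C fixed at max X)
* Model D — weak diathesis-stress (B1 free, C fixed at max X)

are fitted by exact least squares (free-C models via the linear
expansion Y ~ X + D + X·D + covariates, with a profile-over-C numerical
cross-check), compared by nested F-tests and Gaussian AIC/BIC (k counts
the residual SD, and C only when free), and classified with an
auditable decision trail. Around this core the package provides
genotype coding and the Hardy–Weinberg χ² test, Pearson correlation
matrices, pooled two-sample t-tests from raw data *or* from printed
summary statistics, hierarchical moderated regression with per-step
ΔR² and standardized β, simple slopes, the crossover point
C = −b_D/b_XD with bootstrap or delta-method CIs, Johnson–Neyman
significance bounds, a seeded synthetic-cohort generator, and a
one-call pipeline with JSON/text reports. See the methods vignette
(`vignettes/crossover-gxe-methods.Rmd`) for the statistical details.

## Worked example

Hardy–Weinberg QC straight from published genotype counts:

```r
library(gxecross)
hwe_chi_square(c(108, 235, 109))
#> Hardy-Weinberg equilibrium chi-square test
#>             GG  GT    TT
#> observed 108.0 235 109.0
#> expected 112.5 226 113.5
#> allele freq: G = 0.4989, T = 0.5011
#> chi2 = 0.7170, df = 1, p = 0.3971
```

The observed counts sit within 0.72 χ² units of their Hardy–Weinberg
expectations (p = 0.40): no evidence of genotyping artefact.

Model fitting and selection on a synthetic cohort with a well-separated
interior crossover (non-carrier slope −0.2, carrier slope 0.4, true
crossover at X = 0):

```r
truth <- synthetic_truth(model = "B", B0 = 0.04, B1 = -0.2, B2 = 0.4,
                         C = 0, sigma = 0.42)
dat <- generate_cohort(truth, seed = 42)
select_model(fit_all_reparam(dat))
#> ...
#> decision trail:
#>   - F(C vs D) = 101.698 (1, 448), p = 0.0000 -> fixed-C regime favors D
#>   - F(A vs B) = 10.865 (1, 447), p = 0.0011 -> free-C regime favors B
#>   - F(D vs B) = 115.408 (1, 447), p = 0.0000 -> freeing C improves fit
#>     significantly; select B
#>   - interaction test (B1 = B2 in Model B): p = 0.0000 < 0.05 ->
#>     weak differential susceptibility
#> selected: Model B (weak differential susceptibility)

ros_analysis(dat, n_boot = 2000, seed = 42)
#> Region-of-significance / crossover analysis
#> crossover C = 0.0844, 95% CI (bootstrap) [-0.0823, 0.2542]
#> JN bounds (alpha = 0.050): lower = -0.0793, upper = 0.2541 (outside)
#> simple slopes:
#>  group   slope      se      t   p_value
#>      0 -0.1427 0.04329 -3.296 1.058e-03
#>      1  0.4152 0.02268 18.311 2.728e-56
```

The selection recovers the generating form: both groups respond to the
environment (weak), freeing the crossover beats pinning it at the
maximum (differential susceptibility), the estimated crossover 0.08
covers the true 0, and the carrier/non-carrier difference is
significant outside the narrow Johnson–Neyman band around it. At the
much smaller published effect sizes (slope difference 0.08) single
replicates often fail the interaction gate — see the vignette's power
discussion.

## Analysis workflow

The `analysis/` scripts replay the study end to end on a synthetic
cohort, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort.tsv + generating truth
Rscript analysis/02_descriptives.R        # HWE, correlations, group tests
Rscript analysis/03_moderated_regression.R# hierarchical fit, RoS, figure
Rscript analysis/04_reparam_models.R      # models A-D side by side
Rscript analysis/05_model_selection.R     # nested F, AIC/BIC, verdict
```

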