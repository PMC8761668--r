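---
title: "Methods: crossover G×E regression, region of significance, and model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover G×E regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxecross)
```

## The scientific question

`gxecross` implements a confirmatory analysis of a gene–environment
(G×E) interaction: does a biallelic SNP (here rs1344706, dominant
T-carrier coding) moderate the association between a continuous adverse
environment (alcohol-problem severity, MAST total) and a quantitative
outcome (impulsivity, BIS total)? Two competing theories make different
predictions about the *form* of such moderation:

* **Diathesis-stress**: risk-allele carriers fare worse only under
  adversity. The two genotype groups' regression lines cross at (or
  beyond) the most adverse observed environment, so carriers are never
  better off.
* **Differential susceptibility**: "plasticity"-allele carriers are
  worse under adversity but *better* in benign environments. The lines
  cross at an interior environment value.

Each form has a strong variant (the non-carrier group does not respond
to the environment at all, B1 = 0) and a weak variant (both groups
respond, carriers more steeply).

## The crossover re-parameterization

All four hypotheses are versions of one regression re-parameterized
around the crossover point C:

$$
Y = \begin{cases}
B_0 + B_1 (X - C) + B_4 \cdot \text{edu} + \varepsilon & D = 0\\
B_0 + B_2 (X - C) + B_4 \cdot \text{edu} + \varepsilon & D = 1
\end{cases}
$$

with Y the z-standardized outcome, X the z-standardized environment,
D the 0/1 carrier code, and education in raw years (age can be added as
a second covariate, coefficient B3). The four models are

| model | form | B1 | C |
|---|---|---|---|
| A | strong differential susceptibility | fixed 0 | free |
| B | weak differential susceptibility | free | free |
| C | strong diathesis-stress | fixed 0 | fixed |
| D | weak diathesis-stress | free | fixed |

Fixed-C models pin C at the observed maximum of X (`fix_point =
"sample_max"`, i.e. the most adverse observed environment; a numeric
override is accepted).

### Fitting

Fixed-C models are ordinary least squares on the transformed predictors
$(X-C)(1-D)$ and $(X-C)D$. Free-C models are fitted through the exact
linear expansion $Y \sim X + D + XD + \text{edu}$ (Model A omits the X
column): writing the expansion coefficients as $a$, the crossover is
$C = -a_D / a_{XD}$, $B_1 = a_X$, $B_2 = a_X + a_{XD}$,
$B_0 = a_0 + B_1 C$. This is not an approximation — the expansion spans
exactly the same function space — so the free-C fit is closed-form and
immune to the convergence and local-optimum ambiguities of generic
nonlinear least squares. A profile search over C
(`profile_crossover()`, coarse grid over the observed X range widened
by 1, then Brent optimization in the bracketing cell) is kept as an
internal numerical cross-check; it agrees with the closed form to
numerical precision whenever the crossover is identified, i.e. whenever
the slope difference $B_2 - B_1$ is well away from zero. Near-parallel
lines leave C unidentified (the SSE profile is flat and the closed-form
ratio explodes); the fitter refuses numerically zero interaction
coefficients rather than returning an arbitrary crossover.

Standard errors of the derived parameters use first-order (delta)
propagation of the expansion's coefficient covariance; for the crossover
a percentile bootstrap (shared with the region-of-significance module)
is available as an alternative.

### Likelihood, k, and information criteria

Model comparison uses the Gaussian maximum-likelihood log-likelihood
$\ell = -\tfrac{n}{2}(\ln(2\pi\,\text{SSE}/n) + 1)$, AIC $= 2k - 2\ell$,
BIC $= k \ln n - 2\ell$. The parameter count k includes the residual SD
and counts C only when it is estimated, giving k = 5, 6, 4, 5 for
models A–D with one covariate. This is the unique counting convention
whose BIC − AIC spacing, $k(\ln n - 2)$, reproduces the conventional
published spacings at n = 452, and it is verified as an identity on
every fit in the test suite.

### Selection procedure

`select_model()` fixes the comparison order:

1. strong vs weak within each crossover regime by nested F
   (C vs D, A vs B; $\alpha$ = 0.05 by default);
2. the two regime winners across regimes: nested F where nested
   (C⊂A, C⊂B, D⊂B), with a nonsignificant F favoring the more
   parsimonious fixed-C model; the one non-nested pairing (D vs A) by
   lower AIC, ties by lower BIC — both criteria are always printed so
   disagreements are visible;
3. an interaction gate: the hypothesis $B_1 = B_2$ is tested in Model B
   (it is that fit's product coefficient). When it is not rejected the
   classification is "no interaction", although the best-fitting model
   is still reported.

Nested F uses $F = ((\text{SSE}_r - \text{SSE}_f)/\Delta k) /
(\text{SSE}_f / \text{df}_f)$ with $\text{df}_f$ the full model's
residual df. Every applied rule is recorded in an ordered decision
trail, so the verdict is auditable and reproducible.

## Hierarchical regression and the region of significance

The traditional moderation analysis enters education, then the main
effects of X and D, then the product XD, reporting per-step ΔR² and,
per coefficient, B (SE), the standardized β, t, p and 95% CI. β is
computed as $B \cdot \text{sd(predictor)}/\text{sd}(Y)$; for the product
term the SD of the realized product column is used. Scaling convention:
Y and X are z-standardized, D stays binary, covariates stay in raw
years — the convention under which B and β coincide for X and the
crossover C = 1.57 of the emulated study lies on the standardized MAST
scale.

A significant product term is interpreted through the crossover point
$C = -b_D/b_{XD}$ (where the group difference $b_D + b_{XD}X$ vanishes)
and the Johnson–Neyman bounds, the real roots of

$$(b_{XD}^2 - t_c^2 v_{22})X^2 + 2(b_D b_{XD} - t_c^2 v_{12})X +
(b_D^2 - t_c^2 v_{11}) = 0,$$

where $v$ is the covariance block of $(b_D, b_{XD})$ and $t_c$ the
two-sided critical value at the residual df. The group difference is
significant where the quadratic is positive — outside the bounds in the
usual case, inside them when the leading coefficient is negative, and
nowhere when no real roots exist (the quadratic is negative at the
crossover by construction). Bounds outside the observed X range are
flagged: there the verdict rests on extrapolation. The crossover CI
defaults to a percentile bootstrap over case resamples (2000 draws,
explicit seed; resamples with a numerically zero interaction are redrawn
with a logged count, and more than 10% of them is an error); a
delta-method interval is available and the two agree as noise vanishes.

## The synthetic cohort generator

The subject-level data behind the motivating study were not deposited,
so `generate_cohort()` stands in for them and makes every stage
testable:

* genotypes are two independent Bernoulli alleles at the configured
  T-allele frequency (0.5011 in the study preset) — Hardy–Weinberg by
  construction;
* age, education and MAST come from a trivariate Gaussian with the
  published means, SDs and pairwise correlations; years are rounded,
  and MAST is truncated at zero and rounded (it is a nonnegative
  questionnaire total);
* the standardized outcome follows the configured crossover model plus
  Gaussian noise, and is mapped to the BIS scale through the published
  moments.

The study preset (defaults of `synthetic_truth()`) uses the weak
diathesis-stress form with B0 = 0.04, B1 = 0.28, B2 = 0.36, B4 = 0.04,
C at the sample maximum of X, and residual SD 0.84, calibrated once by
bisection (20 replicates per probe) so the fitted Model-D R² is about
0.15. All randomness flows from one explicit seed.

### What the generator does and does not emulate

Passing tests on these cohorts demonstrate that the estimators recover
the generating structure at the study's size and effect scale — not
that real questionnaire data behave Gaussianly. Known divergences:

* **Truncation attenuates the environment SD** by about 4% at the
  study's mean/SD ratio; means and correlations converge to their
  targets within 2% (0.02 absolute for correlations) at large n.
* **The Gaussian right tail overshoots a bounded questionnaire's
  maximum**: the sample maximum of standardized MAST is ~2.8–3.5 at
  n = 452 versus 1.57 in the real study. Since the preset pins the
  crossover at that maximum, the implied carrier/non-carrier *mean*
  difference, $(B_2-B_1)\cdot(0 - C)$, is larger in the synthetic
  cohorts (~0.2 SD) than the published group comparisons suggest
  (~0.1 SD, within their noise).
* **Power at the published effect size is modest.** With
  $B_2 - B_1 = 0.08$ and a standard error of the product coefficient
  near 0.10 at n = 452, the normal approximation puts the two-sided
  interaction test's power well below one half and sign recovery near
  $\Phi(0.8) \approx 0.8$ (the test suite asserts the corresponding
  rate bands). Single synthetic replicates therefore legitimately end
  in "no interaction"; the simulation-based checks work with medians
  and rates over hundreds of replicates instead of any one cohort.
* Item-level responses are not simulated (the pipeline consumes totals
  only), and no population stratification or genotyping error is
  modeled.

## Numerical and design choices

* **Pooled-variance (Student) t** rather than Welch for the group
  comparisons: it reproduces the published age/MAST/BIS statistics from
  the printed summaries at two decimals, which Welch does not. Two-sided
  p-values throughout; no multiple-testing correction (matching the
  original analysis).
* **HWE test**: χ² goodness of fit against expectations from the
  observed allele frequency, df = 1, no continuity correction — the
  published statistic is recovered only without correction.
* **Covariate set**: education only by default; the fixed-C models'
  residual dfs (3,448), (4,447), (2,449), (3,448) at n = 452 confirm
  that configuration. Age can be added (`covariates = c("education",
  "age")`), which introduces B3; neither configuration is asserted as
  uniquely correct.
* **Complete-case filtering** happens once, up front, with a logged
  count, so all stages share one analysis set. Invalid genotype labels
  are errors naming the offending rows, never silent drops.
* **Degenerate inputs**: monomorphic samples make HWE undefined (error);
  constant variables make correlations undefined (error naming the
  column); rank-deficient designs name the collinear columns; zero
  pooled variance with unequal means is refused; SSE = 0 makes the
  information criteria undefined (warning, infinite log-likelihood
  sentinel).
* **Scale notes**: `generate_cohort()` returns the analysis-scale
  dataset on which the generating parameters live; re-reading the
  raw-scale table and re-standardizing its outcome within-sample
  rescales all coefficients by 1/sd of the model-scale outcome, exactly
  as published coefficients live on their own sample's z-scale.

## Problem sizes used in the test suite

The suite validates the simulation claims at: 200 replicate cohorts for
parameter recovery (medians of B1, B2), 300 for bootstrap-CI coverage of
an interior crossover (with the slope difference at 0.6, where the
crossover is well identified), 200 per regime for model-selection
discrimination, 2000 multinomial cohorts for the HWE type-I error, 100
preset cohorts for the cohort-structure bands, and 50 seeded datasets
for the closed-form/profile equivalence. These sizes give Monte-Carlo
error comfortably inside the asserted bands while keeping the default
test run quick.

## Limitations

The pipeline addresses one SNP, one environment, a male cohort and a
cross-sectional design; it does not fit latent-variable or Bayesian
formulations of the same hypotheses, ordinal outcomes, or
continuous-moderator Johnson–Neyman (the moderator here is the binary
carrier group). Conclusions about the *form* of a G×E interaction are
sensitive to where the crossover can land, hence to the observed
environment range; the region-of-significance output flags any bound
that falls outside it.
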