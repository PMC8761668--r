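#' Generating parameters for a synthetic cohort
#'
#' Bundles everything the generator needs: cohort size, T-allele
#' frequency, the covariate moments and correlations (age and education in
#' years, environment on the raw MAST scale), the crossover-model form and
#' its parameters on the standardized analysis scale, the residual SD, and
#' the seed. The defaults are the emulated study's conditions: n = 452,
#' allele frequency 0.5011, age 44.11 (9.25), education 10.78 (2.84), MAST
#' 9.15 (5.49), correlations r(age, edu) = -0.39, r(age, MAST) = 0.21,
#' r(edu, MAST) = -0.24, outcome mapped to BIS 119.56 (45.28), and a weak
#' diathesis-stress (Model D) interaction with B1 = 0.28, B2 = 0.36,
#' B4 = 0.04, B0 = 0.04, crossover at the sample maximum of X, residual
#' SD calibrated so the fitted Model-D R-squared is about 0.15.
#'
#' @param n cohort size.
#' @param allele_freq_T frequency of the T (carrier) allele.
#' @param age_mean,age_sd,edu_mean,edu_sd,env_mean,env_sd covariate and
#'   environment moments (raw scale).
#' @param r_age_edu,r_age_env,r_edu_env pairwise correlations.
#' @param out_mean,out_sd raw-scale outcome moments used to map the
#'   standardized outcome back to the questionnaire scale.
#' @param model generating crossover model (`"A"`, `"B"`, `"C"`, `"D"`).
#' @param B0,B1,B2,B4 generating parameters on the standardized scale
#'   (B4 multiplies raw education years); `B3` multiplies raw age and is
#'   NULL to omit age from the generating equation.
#' @param C crossover location: `"sample_max"` or a number on the
#'   standardized X scale.
#' @param sigma residual SD of the standardized outcome.
#' @param seed integer seed.
#' @return object of class `synthetic_truth` (a validated list).
#' @export
synthetic_truth <- function(n = 452, allele_freq_T = 0.5011,
                            age_mean = 44.11, age_sd = 9.25,
                            edu_mean = 10.78, edu_sd = 2.84,
                            env_mean = 9.15, env_sd = 5.49,
                            r_age_edu = -0.39, r_age_env = 0.21,
                            r_edu_env = -0.24,
                            out_mean = 119.56, out_sd = 45.28,
                            model = "D",
                            B0 = 0.04, B1 = 0.28, B2 = 0.36, B4 = 0.04,
                            B3 = NULL, C = "sample_max",
                            sigma = 0.84, seed = 1) {
  stopifnot(n >= 10, allele_freq_T > 0, allele_freq_T < 1,
            age_sd > 0, edu_sd > 0, env_sd > 0, out_sd > 0, sigma >= 0)
  model <- match.arg(model, c("A", "B", "C", "D"))
  info <- reparam_model_info(model)
  if (!info$free_B1 && B1 != 0)
    stop("strong models (A, C) require B1 = 0", call. = FALSE)
  R <- matrix(c(1, r_age_edu, r_age_env,
                r_age_edu, 1, r_edu_env,
                r_age_env, r_edu_env, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation targets are not positive semi-definite",
         call. = FALSE)
  structure(list(n = n, allele_freq_T = allele_freq_T,
                 age_mean = age_mean, age_sd = age_sd,
                 edu_mean = edu_mean, edu_sd = edu_sd,
                 env_mean = env_mean, env_sd = env_sd,
                 corr = R,
                 out_mean = out_mean, out_sd = out_sd,
                 model = model,
                 params = list(B0 = B0, B1 = B1, B2 = B2, B4 = B4,
                               B3 = B3, C = C),
                 sigma = sigma, seed = seed),
            class = "synthetic_truth")
}

#' Generate a synthetic cohort from a `synthetic_truth`
#'
#' Genotypes are drawn as two independent alleles at the configured
#' T-allele frequency (Hardy-Weinberg proportions by construction) and
#' labeled GG/GT/TT. Age, education and the environment score are drawn
#' from a trivariate Gaussian with the configured moments and
#' correlations; ages and education years are rounded to whole years and
#' the environment score is truncated at 0 and rounded to an integer (it
#' is a questionnaire total). X is the within-cohort z-score of the
#' environment; the standardized outcome is built from the configured
#' crossover-model equation plus Gaussian noise, and is mapped back to the
#' raw questionnaire scale through the configured outcome moments.
#'
#' The returned object is the analysis-scale dataset (the scale on which
#' the generating parameters live, so noiseless data refit exactly); the
#' raw-scale per-subject table is attached as `attr(, "raw")` and the
#' truth as `attr(, "truth")`. Note that reading the raw table back and
#' re-standardizing its outcome rescales all coefficients by
#' 1/sd(Y_model) - the usual consequence of within-sample standardization.
#'
#' @param truth `synthetic_truth`.
#' @param seed optional override of `truth$seed`.
#' @return `gxe_analysis` data.frame with attributes `raw` (a
#'   `gxe_cohort`) and `truth`.
#' @export
generate_cohort <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  n <- truth$n
  q <- truth$allele_freq_T
  n_t_alleles <- stats::rbinom(n, 2L, q)
  genotype <- c("GG", "GT", "TT")[n_t_alleles + 1L]
  d <- as.integer(n_t_alleles > 0L)
  if (length(unique(d)) < 2L)
    stop("degenerate draw: only one carrier group present; use larger n",
         call. = FALSE)
  sds <- c(truth$age_sd, truth$edu_sd, truth$env_sd)
  Sigma <- truth$corr * tcrossprod(sds)
  covs <- MASS::mvrnorm(n, c(truth$age_mean, truth$edu_mean,
                             truth$env_mean), Sigma)
  age <- round(covs[, 1])
  education <- pmax(0, round(covs[, 2]))
  mast <- pmax(0, round(covs[, 3]))
  if (stats::sd(mast) == 0)
    stop("degenerate draw: environment score has zero variance",
         call. = FALSE)
  x <- standardize(mast)
  p <- truth$params
  cval <- if (identical(p$C, "sample_max")) max(x) else as.numeric(p$C)
  slope <- p$B1 + (p$B2 - p$B1) * d
  eta <- p$B0 + slope * (x - cval) + p$B4 * education
  if (!is.null(p$B3)) eta <- eta + p$B3 * age
  y <- eta + stats::rnorm(n, 0, truth$sigma)
  bis <- truth$out_mean + truth$out_sd * standardize(y)
  raw <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    genotype = genotype, age = age,
                    education_years = education, mast = mast,
                    bis = round(bis, 2))
  class(raw) <- c("gxe_cohort", "data.frame")
  out <- data.frame(Y = y, X = x, D = d, education = education, age = age)
  class(out) <- c("gxe_analysis", "data.frame")
  attr(out, "raw") <- raw
  attr(out, "truth") <- truth
  attr(out, "crossover") <- cval
  out
}

#' Generate the emulated-study cohort
#'
#' [generate_cohort()] under the study preset (the defaults of
#' [synthetic_truth()]): n = 452, Hardy-Weinberg genotypes at T-allele
#' frequency 0.5011, the published covariate moments and correlations,
#' and a weak diathesis-stress interaction at the published effect sizes
#' with residual noise calibrated to a fitted R-squared of about 0.15.
#'
#' @param seed integer seed.
#' @return `gxe_analysis` data.frame (see [generate_cohort()]).
#' @export
emulate_study <- function(seed = 1) {
  generate_cohort(synthetic_truth(seed = seed))
}

#' Calibrate the generator's residual SD to a target R-squared
#'
#' Bisection over sigma so that the mean fitted Model-D R-squared across
#' `reps` generated cohorts hits `target_r2`. Used once to fix the study
#' preset's sigma; exposed so the calibration is reproducible.
#'
#' @param truth `synthetic_truth` whose sigma is to be calibrated.
#' @param target_r2 target fitted R-squared (default 0.15).
#' @param reps replicates per probe (default 20).
#' @param interval search interval for sigma.
#' @param tol bisection tolerance on sigma.
#' @param seed base seed; probe replicate r uses seed + r.
#' @return calibrated sigma (numeric).
#' @export
calibrate_sigma <- function(truth, target_r2 = 0.15, reps = 20,
                            interval = c(0.05, 5), tol = 1e-3,
                            seed = 1000) {
  mean_r2 <- function(sg) {
    tt <- truth; tt$sigma <- sg
    mean(vapply(seq_len(reps), function(r) {
      dat <- generate_cohort(tt, seed = seed + r)
      fit_reparam(dat, truth$model,
                  fix_point = if (identical(truth$params$C, "sample_max"))
                    "sample_max" else truth$params$C)$r2
    }, numeric(1)))
  }
  lo <- interval[1]; hi <- interval[2]
  if (mean_r2(lo) < target_r2 || mean_r2(hi) > target_r2)
    stop("target R2 not bracketed by the sigma interval", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mean_r2(mid) > target_r2) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
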