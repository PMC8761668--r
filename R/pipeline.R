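#' Run the full confirmatory G x E analysis pipeline
#'
#' Sequences every stage over one analysis set: genotype QC (counts,
#' frequencies, Hardy-Weinberg test), descriptives (correlation matrix,
#' per-group comparisons), hierarchical moderated regression,
#' region-of-significance analysis, the four re-parameterized crossover
#' models, and model selection. Deterministic given the same cohort,
#' configuration and seed. Complete-case filtering happens once, in
#' [read_cohort()]/[as_cohort()], so every stage sees the same n.
#'
#' @param cohort a `gxe_cohort` data.frame or a path to a cohort table.
#' @param covariates covariate set for the regression stages.
#' @param alpha significance level used by the RoS bounds and the model
#'   comparisons.
#' @param ci_method,n_boot crossover-CI settings (see [crossover_ci()]).
#' @param fix_point crossover location for the diathesis-stress models.
#' @param seed seed for the bootstrap.
#' @return object of class `study_report` with sections `hwe`,
#'   `frequencies`, `correlations`, `group_tests`, `hierarchical`, `ros`,
#'   `reparam`, `selection` and a `provenance` block.
#' @export
run_pipeline <- function(cohort, covariates = "education", alpha = 0.05,
                         ci_method = "bootstrap", n_boot = 2000,
                         fix_point = "sample_max", seed = 1) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- stage("genotypes", genotype_counts(cohort$genotype))
  hwe <- stage("genotypes", hwe_chi_square(counts))
  freqs <- stage("genotypes", genotype_frequencies(counts))
  corr_df <- data.frame(genotype = code_dominant(cohort$genotype),
                        age = cohort$age,
                        education = cohort$education_years,
                        mast = cohort$mast, bis = cohort$bis)
  correlations <- stage("descriptives", correlation_matrix(corr_df))
  group_tests <- stage("descriptives", group_comparison(cohort))
  data <- stage("analysis_frame", analysis_frame(cohort))
  hier <- stage("moderated_regression", hierarchical_fit(data))
  ros <- stage("ros_analysis",
               ros_analysis(data, covariates = covariates, alpha = alpha,
                            ci_method = ci_method, n_boot = n_boot,
                            seed = seed))
  fits <- stage("reparam_gxe",
                fit_all_reparam(data, fix_point = fix_point,
                                covariates = covariates))
  selection <- stage("model_selection", select_model(fits, alpha = alpha))
  structure(
    list(hwe = hwe, frequencies = freqs, correlations = correlations,
         group_tests = group_tests, hierarchical = hier, ros = ros,
         reparam = fits, selection = selection,
         provenance = list(
           n = nrow(cohort), covariates = covariates, alpha = alpha,
           ci_method = ci_method, n_boot = n_boot,
           fix_point = fix_point, seed = seed,
           r_version = as.character(getRversion()))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("==== G x E study report (n = ", x$provenance$n, ") ====\n",
      sep = "")
  print(x$hwe); cat("\n")
  print(x$correlations); cat("\n")
  cat("group comparisons (pooled t):\n")
  print(format(x$group_tests, digits = 3), row.names = FALSE); cat("\n")
  print(x$hierarchical); cat("\n")
  print(x$ros); cat("\n")
  for (m in c("A", "B", "C", "D")) { print(x$reparam[[m]]); cat("\n") }
  print(x$selection)
  invisible(x)
}

report_to_list <- function(x) {
  rp <- lapply(x$reparam, function(f)
    list(model = f$model_label, description = f$description,
         params = as.list(f$params), se = as.list(f$se),
         sigma = f$sigma, sse = f$sse, r2 = f$r2,
         F = f$fstat$F, df1 = f$fstat$df1, df2 = f$fstat$df2,
         F_p = f$fstat$p_value,
         loglik = f$loglik, aic = f$aic, bic = f$bic, k = f$k))
  list(
    hwe = list(chi2 = x$hwe$chi2, df = x$hwe$df, p_value = x$hwe$p_value,
               observed = as.list(x$hwe$observed),
               expected = as.list(x$hwe$expected_counts)),
    frequencies = list(percent = as.list(x$frequencies$percent),
                       allele_freq = as.list(x$frequencies$allele_freq)),
    correlations = list(variables = x$correlations$variables,
                        r = x$correlations$r, p = x$correlations$p,
                        n = x$correlations$n),
    group_tests = x$group_tests,
    hierarchical = lapply(x$hierarchical$steps, function(s)
      list(step = s$step, terms_added = s$terms_added,
           coefficients = s$coefficients, r2 = s$r2,
           delta_r2 = s$delta_r2)),
    ros = list(crossover = x$ros$crossover,
               crossover_ci = x$ros$crossover_ci,
               jn = x$ros$jn, slopes = x$ros$slopes,
               x_range = x$ros$x_range),
    reparam = rp,
    selection = list(selected_model = x$selection$selected_model,
                     classification = x$selection$classification,
                     interaction_p = x$selection$interaction_p,
                     f_tests = x$selection$f_tests,
                     ic_table = x$selection$ic_table,
                     trail = x$selection$trail),
    provenance = x$provenance)
}

#' Write a study report to disk
#'
#' Writes a machine-readable JSON report and a human-readable text
#' rendering.
#'
#' @param report `study_report`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
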