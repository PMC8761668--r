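#' Pearson correlation matrix with two-sided p-values
#'
#' Complete-case Pearson correlations over the listed variables, with
#' p-values from the usual t transform t = r*sqrt((n-2)/(1-r^2)).
#'
#' @param data data.frame containing the variables.
#' @param variables character vector of column names (>= 2).
#' @return object of class `cor_matrix`: list with `r`, `p`, `n`,
#'   `variables`.
#' @export
correlation_matrix <- function(data, variables = names(data)) {
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols) > 0L)
    stop("variable(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  mat <- as.matrix(as.data.frame(lapply(data[variables], as.numeric)))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  if (n < 3L) stop("need at least 3 complete records", call. = FALSE)
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(mat)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, variables = variables),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 2, star_level = 0.001, ...) {
  cat(sprintf("Pearson correlations (complete cases, n = %d)\n", x$n))
  fmt <- format(round(x$r, digits))
  star <- ifelse(!is.na(x$p) & x$p < star_level, "*", " ")
  out <- matrix(paste0(fmt, star), nrow = nrow(x$r),
                dimnames = dimnames(x$r))
  out[upper.tri(out)] <- ""
  print(out, quote = FALSE)
  cat(sprintf("* p < %.3f (two-sided)\n", star_level))
  invisible(x)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's pooled-variance t computed from per-group n, mean and SD only,
#' so published group summaries can be re-analysed without raw data:
#' sp^2 = ((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2),
#' t = (m1-m2)/(sp*sqrt(1/n1+1/n2)), df = n1+n2-2, two-sided p.
#'
#' @param n1,mean1,sd1 first group's size, mean and SD.
#' @param n2,mean2,sd2 second group's size, mean and SD.
#' @return object of class `pooled_t`: list with `t`, `df`, `p_value`,
#'   `mean_difference`, `pooled_sd`.
#' @examples
#' pooled_t_from_summary(108, 43.64, 9.18, 344, 44.25, 9.27)
#' @export
pooled_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0",
                               call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  diff <- mean1 - mean2
  if (sp2 == 0) {
    if (diff != 0)
      stop("degenerate: zero pooled variance with unequal means",
           call. = FALSE)
    t <- 0
  } else {
    t <- diff / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  }
  structure(
    list(t = t, df = df,
         p_value = 2 * stats::pt(abs(t), df = df, lower.tail = FALSE),
         mean_difference = diff, pooled_sd = sqrt(sp2)),
    class = "pooled_t")
}

#' Pooled-variance two-sample t-test from raw values
#'
#' Raw-data twin of [pooled_t_from_summary()]: computes each group's
#' n/mean/SD and applies the identical pooled formula, so the two routes
#' agree to machine precision by construction.
#'
#' @param values numeric vector.
#' @param group 0/1 (or two-level) group labels, same length as `values`.
#' @return object of class `pooled_t` (group 0 minus group 1 difference).
#' @export
pooled_t_from_raw <- function(values, group) {
  stopifnot(length(values) == length(group))
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- group[keep]
  levels <- sort(unique(group))
  if (length(levels) != 2L)
    stop("group must have exactly two levels", call. = FALSE)
  g1 <- values[group == levels[1]]
  g2 <- values[group == levels[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least 2 members", call. = FALSE)
  pooled_t_from_summary(length(g1), mean(g1), stats::sd(g1),
                        length(g2), mean(g2), stats::sd(g2))
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf(
    "pooled two-sample t: t = %.4f, df = %d, p = %.4f (mean diff %.4f)\n",
    x$t, x$df, x$p_value, x$mean_difference))
  invisible(x)
}

#' Per-group summaries and pooled t-tests across cohort variables
#'
#' For each named variable, summarises the two carrier groups (n, mean, SD)
#' and runs the pooled two-sample t-test, reproducing the usual
#' "group comparison" table of a candidate-gene study.
#'
#' @param cohort cohort data.frame with a `genotype` column.
#' @param variables character vector of numeric columns to compare.
#' @return data.frame with one row per variable: group means/SDs, t, df, p.
#' @export
group_comparison <- function(cohort,
                             variables = c("age", "education_years",
                                           "mast", "bis")) {
  d <- code_dominant(cohort$genotype)
  rows <- lapply(variables, function(v) {
    x <- as.numeric(cohort[[v]])
    tt <- pooled_t_from_raw(x, d)
    data.frame(variable = v,
               n_GG = sum(d == 0), mean_GG = mean(x[d == 0]),
               sd_GG = stats::sd(x[d == 0]),
               n_T = sum(d == 1), mean_T = mean(x[d == 1]),
               sd_T = stats::sd(x[d == 1]),
               t = tt$t, df = tt$df, p_value = tt$p_value)
  })
  do.call(rbind, rows)
}
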