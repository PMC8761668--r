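#' Read a cohort table
#'
#' Reads the per-subject input table (TSV or CSV inferred from the file
#' extension, header required) with columns `subject_id`, `genotype`,
#' `age`, `education_years`, `mast`, `bis` (renameable through
#' `column_map`). Genotype labels are validated via [code_dominant()];
#' incomplete rows are dropped once, up front, with a message, so every
#' downstream stage sees the same analysis set.
#'
#' @param path file path ending in `.tsv`/`.txt` (tab) or `.csv` (comma).
#' @param column_map optional named character vector mapping the canonical
#'   names to the file's column names, e.g. `c(mast = "MAST_total")`.
#' @return data.frame of class `gxe_cohort` with the canonical columns.
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("subject_id", "genotype", "age", "education_years",
                 "mast", "bis")
  wanted <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) wanted[names(column_map)] <- column_map
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- raw[, wanted]
  names(out) <- canonical
  for (v in c("age", "education_years", "mast", "bis")) {
    num <- suppressWarnings(as.numeric(out[[v]]))
    bad <- which(is.na(num) & !is.na(out[[v]]) & out[[v]] != "")
    if (length(bad) > 0L)
      stop("unparseable numeric in column '", v, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    out[[v]] <- num
  }
  as_cohort(out)
}

#' Validate a cohort data.frame
#'
#' @param df data.frame with the canonical cohort columns.
#' @return the validated `gxe_cohort` data.frame (complete cases only; a
#'   message reports how many rows were dropped).
#' @export
as_cohort <- function(df) {
  canonical <- c("subject_id", "genotype", "age", "education_years",
                 "mast", "bis")
  missing_cols <- setdiff(canonical, names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[, canonical]
  complete <- stats::complete.cases(df)
  if (any(!complete))
    message(sum(!complete), " incomplete row(s) dropped; ",
            sum(complete), " remain")
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete rows", call. = FALSE)
  code_dominant(df$genotype)  # validates labels, names offending rows
  rownames(df) <- NULL
  class(df) <- c("gxe_cohort", "data.frame")
  df
}

#' Write a cohort table
#'
#' @param cohort cohort data.frame.
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(cohort, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Z-standardize a numeric vector
#'
#' Centers and scales to sample mean 0, SD 1 (n-1 denominator).
#'
#' @param values numeric vector, length >= 2, nonzero variance.
#' @return numeric vector of z-scores.
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) stop("zero variance: cannot standardize",
                               call. = FALSE)
  (values - mean(values)) / s
}

#' Build the analysis-scale dataset from a raw cohort
#'
#' Converts the raw cohort into the frame every model-fitting function
#' consumes: `Y` (z-standardized outcome, BIS), `X` (z-standardized
#' environment, MAST), `D` (0/1 T-carrier code), and the raw-scale
#' covariates `education` (years) and `age` (years). Standardizing Y and X
#' while leaving D binary and covariates raw is the scaling on which all
#' reported coefficients live; it can be switched off for data that is
#' already on the analysis scale.
#'
#' @param cohort `gxe_cohort` data.frame (or any data.frame with the
#'   canonical columns).
#' @param standardize_yx standardize outcome and environment? Default TRUE.
#' @return data.frame of class `gxe_analysis` with columns
#'   `Y`, `X`, `D`, `education`, `age` and attribute `moments` holding the
#'   raw means/SDs used.
#' @export
analysis_frame <- function(cohort, standardize_yx = TRUE) {
  d <- code_dominant(cohort$genotype)
  if (length(unique(d)) < 2L)
    stop("both genotype groups must be present", call. = FALSE)
  y_raw <- as.numeric(cohort$bis)
  x_raw <- as.numeric(cohort$mast)
  out <- data.frame(
    Y = if (standardize_yx) standardize(y_raw) else y_raw,
    X = if (standardize_yx) standardize(x_raw) else x_raw,
    D = d,
    education = as.numeric(cohort$education_years),
    age = as.numeric(cohort$age))
  attr(out, "moments") <- c(bis_mean = mean(y_raw), bis_sd = stats::sd(y_raw),
                            mast_mean = mean(x_raw), mast_sd = stats::sd(x_raw))
  class(out) <- c("gxe_analysis", "data.frame")
  out
}
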