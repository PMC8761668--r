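#' Dominant (T-carrier) coding of rs-style biallelic genotypes
#'
#' Collapses heterozygotes and T/T homozygotes into a single carrier group
#' coded 1; G/G homozygotes are coded 0. Parsing is case-insensitive and the
#' heterozygote is accepted in either letter order ("GT" or "TG"). Anything
#' else is an error, never silently dropped: silent row loss is exactly the
#' kind of data-integrity bias this guard exists to prevent.
#'
#' @param genotype_labels character vector of genotype strings
#'   (`"GG"`, `"GT"`/`"TG"`, `"TT"`, any case).
#' @return integer vector of 0/1 carrier codes, same length as the input.
#' @examples
#' code_dominant(c("GG", "GT", "TT", "tg"))
#' @export
code_dominant <- function(genotype_labels) {
  labels <- toupper(trimws(as.character(genotype_labels)))
  labels[labels == "TG"] <- "GT"
  code <- c(GG = 0L, GT = 1L, TT = 1L)[labels]
  bad <- which(is.na(code))
  if (length(bad) > 0L) {
    stop("invalid genotype label(s) at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": ", paste(unique(genotype_labels[utils::head(bad, 5L)]),
                     collapse = ", "),
         call. = FALSE)
  }
  unname(code)
}

#' Tabulate genotype counts
#'
#' @param genotype_labels character vector of genotype strings; validated the
#'   same way as [code_dominant()].
#' @return named integer vector `c(GG=, GT=, TT=)`.
#' @export
genotype_counts <- function(genotype_labels) {
  labels <- toupper(trimws(as.character(genotype_labels)))
  labels[labels == "TG"] <- "GT"
  code_dominant(labels)  # validation only
  c(GG = sum(labels == "GG"),
    GT = sum(labels == "GT"),
    TT = sum(labels == "TT"))
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0))
    stop("counts must be three nonnegative numbers (GG, GT, TT)",
         call. = FALSE)
  if (sum(counts) <= 0) stop("total genotype count must be positive",
                             call. = FALSE)
  counts
}

#' Genotype percentages and allele frequencies
#'
#' @param counts genotype counts as `c(GG, GT, TT)` (order matters; names
#'   are ignored).
#' @return list with `percent` (named, sums to 100), `allele_freq` (named
#'   frequencies of G and T) and `n_total`.
#' @examples
#' genotype_frequencies(c(108, 235, 109))
#' @export
genotype_frequencies <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  pct <- 100 * counts / n
  freq_t <- (2 * counts[3] + counts[2]) / (2 * n)
  list(percent = stats::setNames(pct, c("GG", "GT", "TT")),
       allele_freq = c(G = 1 - freq_t, T = freq_t),
       n_total = n)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Goodness-of-fit test of the observed genotype counts against the
#' Hardy-Weinberg expectations n*p^2, 2n*p*q, n*q^2 computed from the
#' observed allele frequencies. One degree of freedom (three genotype
#' classes, one estimated allele frequency); no continuity correction.
#'
#' @param counts genotype counts as `c(GG, GT, TT)`.
#' @return object of class `hwe_test`: list with `chi2`, `df`, `p_value`,
#'   `observed`, `expected_counts`, `allele_freq`, `n_total`.
#' @examples
#' hwe_chi_square(c(108, 235, 109))
#' @export
hwe_chi_square <- function(counts) {
  counts <- check_counts(counts)
  n <- sum(counts)
  q <- (2 * counts[3] + counts[2]) / (2 * n)  # freq of T
  p <- 1 - q
  if (p == 0 || q == 0)
    stop("HWE undefined: monomorphic sample (one allele absent)",
         call. = FALSE)
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  structure(
    list(chi2 = chi2,
         df = 1L,
         p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
         observed = stats::setNames(counts, c("GG", "GT", "TT")),
         expected_counts = stats::setNames(expected, c("GG", "GT", "TT")),
         allele_freq = c(G = p, T = q),
         n_total = n),
    class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("Hardy-Weinberg equilibrium chi-square test\n")
  tab <- rbind(observed = x$observed, expected = round(x$expected_counts, 2))
  print(tab)
  cat(sprintf("allele freq: G = %.4f, T = %.4f\n",
              x$allele_freq["G"], x$allele_freq["T"]))
  cat(sprintf("chi2 = %.4f, df = %d, p = %.4f\n", x$chi2, x$df, x$p_value))
  invisible(x)
}
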