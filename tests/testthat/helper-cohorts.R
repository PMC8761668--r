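# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk.

# A tiny deterministic raw cohort with both genotype groups.
tiny_cohort <- function(n = 24, seed = 11) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    genotype = rep(c("GG", "GT", "TT"), length.out = n),
    age = round(rnorm(n, 44, 9)),
    education_years = pmax(0, round(rnorm(n, 11, 3))),
    mast = pmax(0, round(rnorm(n, 9, 5))),
    bis = round(rnorm(n, 120, 45), 1))
}

# Noiseless analysis-scale dataset built directly from a crossover-model
# equation; bypasses the generator so tests of the fitters do not depend
# on it.
noiseless_reparam_data <- function(n = 200, B0 = 0.1, B1 = 0, B2 = 0.26,
                                   B4 = 0.06, C = NULL, seed = 21) {
  set.seed(seed)
  x <- rnorm(n)
  d <- rep(c(0L, 1L), length.out = n)
  edu <- round(rnorm(n, 11, 3))
  if (is.null(C)) C <- max(x)
  y <- B0 + (B1 + (B2 - B1) * d) * (x - C) + B4 * edu
  out <- data.frame(Y = y, X = x, D = d, education = edu,
                    age = round(rnorm(n, 44, 9)))
  class(out) <- c("gxe_analysis", "data.frame")
  out
}

# Small random analysis-scale dataset with a genuine interaction.
random_analysis_data <- function(n = 120, seed = 1, sigma = 0.8,
                                 B1 = 0.1, B2 = 0.45) {
  set.seed(seed)
  x <- rnorm(n)
  d <- rbinom(n, 1, 0.5)
  if (length(unique(d)) < 2L) d[1:2] <- c(0L, 1L)
  edu <- round(rnorm(n, 11, 3))
  y <- 0.2 + (B1 + (B2 - B1) * d) * x - 0.3 * d + 0.04 * edu +
    rnorm(n, 0, sigma)
  out <- data.frame(Y = y, X = x, D = d, education = edu,
                    age = round(rnorm(n, 44, 9)))
  class(out) <- c("gxe_analysis", "data.frame")
  out
}
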