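test_that("noiseless diathesis-stress data is recovered exactly", {
  dat <- noiseless_reparam_data(B0 = 0.1, B1 = 0, B2 = 0.26, B4 = 0.06)
  fc <- suppressWarnings(fit_reparam(dat, "C"))
  expect_equal(unname(fc$params["B0"]), 0.1, tolerance = 1e-8)
  expect_equal(unname(fc$params["B1"]), 0)
  expect_equal(unname(fc$params["B2"]), 0.26, tolerance = 1e-8)
  expect_equal(unname(fc$params["B4"]), 0.06, tolerance = 1e-8)
  expect_equal(unname(fc$params["C"]), max(dat$X))
  expect_equal(fc$r2, 1, tolerance = 1e-10)

  datD <- noiseless_reparam_data(B0 = -0.2, B1 = 0.28, B2 = 0.36,
                                 B4 = 0.04, seed = 67)
  fd <- suppressWarnings(fit_reparam(datD, "D"))
  expect_equal(unname(fd$params[c("B0", "B1", "B2", "B4")]),
               c(-0.2, 0.28, 0.36, 0.04), tolerance = 1e-8)
})

test_that("free-C models recover an interior crossover from noiseless data", {
  datB <- noiseless_reparam_data(B0 = 0.3, B1 = -0.2, B2 = 0.4,
                                 B4 = 0.05, C = 0.7, seed = 71)
  fb <- suppressWarnings(fit_reparam(datB, "B"))
  expect_equal(unname(fb$params[c("B0", "B1", "B2", "C", "B4")]),
               c(0.3, -0.2, 0.4, 0.7, 0.05), tolerance = 1e-8)
  datA <- noiseless_reparam_data(B0 = 0.3, B1 = 0, B2 = 0.4,
                                 B4 = 0.05, C = -0.4, seed = 73)
  fa <- suppressWarnings(fit_reparam(datA, "A"))
  expect_equal(unname(fa$params[c("B0", "B2", "C", "B4")]),
               c(0.3, 0.4, -0.4, 0.05), tolerance = 1e-8)
})

test_that("closed-form expansion and profile search agree (spot check)", {
  for (s in 1:5) {
    dat <- random_analysis_data(n = 150, seed = 200 + s)
    fb <- fit_reparam(dat, "B", refine = TRUE)
    expect_equal(fb$profile$sse, fb$sse, tolerance = 1e-9)
    expect_equal(fb$profile$C, unname(fb$params["C"]), tolerance = 1e-6)
    fa <- fit_reparam(dat, "A", refine = TRUE)
    expect_equal(fa$profile$sse, fa$sse, tolerance = 1e-9)
  }
})

test_that("nesting inequalities hold on arbitrary data", {
  for (s in 1:10) {
    dat <- random_analysis_data(n = 100, seed = 300 + s,
                                B1 = runif(1, -0.3, 0.3),
                                B2 = runif(1, -0.3, 0.5))
    fits <- fit_all_reparam(dat)
    expect_gte(fits$A$sse, fits$B$sse - 1e-10)  # freeing B1
    expect_gte(fits$C$sse, fits$D$sse - 1e-10)  # freeing B1
    expect_gte(fits$D$sse, fits$B$sse - 1e-10)  # freeing C
    expect_gte(fits$C$sse, fits$A$sse - 1e-10)  # freeing C
    # same column space as the ordinary interaction OLS
    r2_ols <- summary(interaction_fit(dat))$r.squared
    expect_equal(fits$B$r2, r2_ols, tolerance = 1e-10)
  }
})

test_that("information criteria follow the Gaussian closed form and k convention", {
  # residuals all 1, n = 4, k = 2: loglik = -2 * (log(2*pi) + 1)
  ic <- information_criteria(sse = 4, n = 4, k = 2)
  expect_equal(ic$loglik, -2 * (log(2 * pi) + 1), tolerance = 1e-12)
  expect_equal(ic$bic - ic$aic, 2 * (log(4) - 2), tolerance = 1e-12)
  # k-counting at the study size: 5 * (log(452) - 2)
  ic452 <- information_criteria(sse = 300, n = 452, k = 5)
  expect_equal(ic452$bic - ic452$aic, 5 * (log(452) - 2), tolerance = 1e-12)
  expect_equal(5 * (log(452) - 2), 20.57, tolerance = 0.005)
  expect_warning(ic0 <- information_criteria(0, 10, 2), "SSE")
  expect_true(is.infinite(ic0$loglik) && is.na(ic0$aic))
})

test_that("fit bookkeeping: k, dfs, sigma and the AIC/BIC identity", {
  dat <- generate_cohort(synthetic_truth(seed = 79))
  fits <- fit_all_reparam(dat)
  expect_equal(unname(vapply(fits, function(f) f$k, numeric(1))),
               c(5, 6, 4, 5))
  dfs <- lapply(fits, function(f) c(f$fstat$df1, f$fstat$df2))
  expect_equal(dfs$A, c(3, 448)); expect_equal(dfs$B, c(4, 447))
  expect_equal(dfs$C, c(2, 449)); expect_equal(dfs$D, c(3, 448))
  for (f in fits) {
    expect_equal(f$bic - f$aic, f$k * (log(f$n) - 2), tolerance = 1e-10)
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik, tolerance = 1e-10)
    expect_equal(f$df_residual, f$n - (f$k - 1))
    expect_equal(f$sigma, sqrt(f$sse / f$df_residual), tolerance = 1e-12)
    expect_true(f$r2 >= 0 && f$r2 <= 1)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  dat <- random_analysis_data(n = 80, seed = 83)
  dat1 <- dat; dat1$D <- 0L
  expect_error(fit_reparam(dat1, "D"), "both genotype groups")
  # numeric fix_point override is honored
  f <- fit_reparam(dat, "D", fix_point = 2.5)
  expect_equal(unname(f$params["C"]), 2.5)
  expect_error(fit_reparam(dat, "D", fix_point = Inf), "finite")
  # no interaction at all: crossover unidentified in free-C models
  set.seed(89)
  n <- 100; x <- rnorm(n); d <- rep(0:1, n / 2)
  dat2 <- data.frame(Y = 0.5 * x, X = x, D = d,
                     education = rnorm(n, 11, 3), age = rnorm(n, 44, 9))
  class(dat2) <- c("gxe_analysis", "data.frame")
  expect_error(fit_reparam(dat2, "B"), "unidentified")
})
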