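test_that("standardize produces exact z-scores and rejects constants", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  z <- standardize(rnorm(50, 100, 20))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # published-scale example: score 17.77 under moments mean 9.15, SD 5.49
  expect_equal((17.77 - 9.15) / 5.49, 1.5701, tolerance = 1e-4)
  expect_error(standardize(rep(2, 5)), "zero variance")
  expect_error(standardize(1), "at least 2")
})

test_that("hierarchical fit matches a normal-equations oracle step by step", {
  dat <- random_analysis_data(n = 80, seed = 13)
  hf <- hierarchical_fit(dat)
  # brute-force OLS oracle via explicit normal equations
  df <- data.frame(Y = dat$Y, X = dat$X, D = dat$D, XD = dat$X * dat$D,
                   education = dat$education)
  oracle_r2 <- function(terms) {
    M <- cbind(1, as.matrix(df[terms]))
    b <- solve(crossprod(M), crossprod(M, df$Y))
    res <- df$Y - M %*% b
    1 - sum(res^2) / sum((df$Y - mean(df$Y))^2)
  }
  r2s <- c(oracle_r2("education"),
           oracle_r2(c("education", "X", "D")),
           oracle_r2(c("education", "X", "D", "XD")))
  for (k in 1:3) {
    expect_equal(hf$steps[[k]]$r2, r2s[k], tolerance = 1e-10)
    expect_equal(hf$steps[[k]]$delta_r2,
                 r2s[k] - c(0, r2s)[k], tolerance = 1e-10)
    expect_gte(hf$steps[[k]]$delta_r2, -1e-12)
  }
})

test_that("orthonormal predictors contribute their squared marginal correlation", {
  set.seed(17)
  n <- 60
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n))))[, 2:3] * sqrt(n - 1)
  y <- rnorm(n)
  dat <- data.frame(Y = y, X = Q[, 1], D = rep(0:1, length.out = n),
                    education = Q[, 2], age = rnorm(n))
  class(dat) <- c("gxe_analysis", "data.frame")
  hf <- hierarchical_fit(dat, steps = list("X", "education"))
  expect_equal(hf$steps[[1]]$delta_r2, cor(y, Q[, 1])^2, tolerance = 1e-10)
  expect_equal(hf$steps[[2]]$delta_r2, cor(y, Q[, 2])^2, tolerance = 1e-10)
})

test_that("entry order leaves the full model unchanged; degenerate input errors", {
  dat <- random_analysis_data(n = 100, seed = 19)
  h1 <- hierarchical_fit(dat)
  h2 <- hierarchical_fit(dat, steps = list("XD", c("D", "X"), "education"))
  expect_equal(tail(h1$steps, 1)[[1]]$r2, tail(h2$steps, 1)[[1]]$r2,
               tolerance = 1e-12)
  expect_equal(sort(coef(h1$full_model)), sort(coef(h2$full_model)),
               tolerance = 1e-10)
  # perfect collinearity is reported, not silently dropped
  dat2 <- dat; dat2$education <- dat2$X
  expect_error(hierarchical_fit(dat2, steps = list(c("X", "education"))),
               "collinear")
  expect_error(hierarchical_fit(dat, steps = list("X", "X")),
               "new predictor")
  # noiseless single-predictor model explains everything
  dat3 <- dat; dat3$Y <- dat3$X
  h3 <- suppressWarnings(hierarchical_fit(dat3, steps = list("X")))
  expect_equal(h3$steps[[1]]$r2, 1, tolerance = 1e-12)
})

test_that("simple slopes obey their algebraic identities and recover truth", {
  dat <- random_analysis_data(n = 150, seed = 23)
  fit <- interaction_fit(dat)
  ss <- simple_slopes(fit)
  b <- coef(fit)
  expect_equal(ss$slope[1], unname(b["X"]), tolerance = 1e-12)
  expect_equal(ss$slope[2] - ss$slope[1], unname(b["XD"]),
               tolerance = 1e-12)
  # no interaction built in -> equal slopes
  set.seed(29)
  n <- 300; x <- rnorm(n); d <- rep(0:1, n / 2)
  dat0 <- data.frame(Y = 0.4 * x + 0.2 * d, X = x, D = d,
                     education = rnorm(n, 11, 3), age = rnorm(n, 44, 9))
  class(dat0) <- c("gxe_analysis", "data.frame")
  ss0 <- suppressWarnings(simple_slopes(interaction_fit(dat0)))
  expect_equal(ss0$slope[1], ss0$slope[2], tolerance = 1e-9)
  # large-n recovery of generating slopes 0.30 / 0.50
  set.seed(31)
  n <- 10000; x <- rnorm(n); d <- rbinom(n, 1, 0.5)
  datL <- data.frame(Y = (0.3 + 0.2 * d) * x + rnorm(n, 0, 0.1), X = x,
                     D = d, education = rnorm(n, 11, 3),
                     age = rnorm(n, 44, 9))
  class(datL) <- c("gxe_analysis", "data.frame")
  ssL <- simple_slopes(interaction_fit(datL))
  expect_equal(ssL$slope, c(0.3, 0.5), tolerance = 0.02)
  expect_error(simple_slopes(lm(Y ~ X, data = datL)), "interaction")
})

test_that("the fitted interaction sign tracks the generating slope difference", {
  # At the study preset the slope separation (0.36 - 0.28 = 0.08) is less
  # than one standard error of the product coefficient, so sign recovery
  # is power-limited: it must beat chance clearly but cannot be near-
  # certain. With a well-separated difference it must be near-certain.
  hits_study <- vapply(1:300, function(s) {
    d <- generate_cohort(synthetic_truth(seed = 4000 + s))
    sign(coef(interaction_fit(d))["XD"]) == sign(0.36 - 0.28)
  }, logical(1))
  expect_gte(mean(hits_study), 0.65)
  truth_sep <- synthetic_truth(model = "B", B0 = 0.04, B1 = -0.2,
                               B2 = 0.4, C = 0)
  hits_sep <- vapply(1:300, function(s) {
    d <- generate_cohort(truth_sep, seed = 4500 + s)
    sign(coef(interaction_fit(d))["XD"]) == sign(0.4 - (-0.2))
  }, logical(1))
  expect_gte(mean(hits_sep), 0.95)
})
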