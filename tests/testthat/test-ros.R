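test_that("crossover point follows the -b_D/b_XD algebra", {
  # noiseless construction crossing exactly at X = 1:
  # group difference = 0.2*(X - 1) vanishes at 1
  set.seed(41)
  n <- 200; x <- rnorm(n); d <- rep(0:1, n / 2)
  dat <- data.frame(Y = 0.3 * x + 0.2 * d * (x - 1),
                    X = x, D = d, education = rnorm(n, 11, 3),
                    age = rnorm(n, 44, 9))
  class(dat) <- c("gxe_analysis", "data.frame")
  fit <- interaction_fit(dat)
  expect_equal(crossover_point(fit), 1, tolerance = 1e-9)
  # b_D = 0 construction: lines cross at the origin of X
  dat0 <- dat; dat0$Y <- 0.3 * x + 0.2 * d * x
  fit0 <- interaction_fit(dat0)
  expect_equal(crossover_point(fit0), 0, tolerance = 1e-9)
  # algebra check on the fitted coefficients themselves
  b <- coef(fit)
  expect_equal(crossover_point(fit), unname(-b["D"] / b["XD"]),
               tolerance = 1e-12)
  # parallel lines: no crossover
  datp <- dat; datp$Y <- 0.3 * x + 0.5 * d
  expect_error(crossover_point(interaction_fit(datp)), "parallel")
})

test_that("crossover CI is deterministic, near-degenerate on noiseless data, and methods converge", {
  set.seed(43)
  n <- 300; x <- rnorm(n); d <- rep(0:1, n / 2)
  mk <- function(sigma) {
    dd <- data.frame(Y = 0.3 * x + 0.4 * d * (x - 0.5) +
                       rnorm(n, 0, sigma),
                     X = x, D = d, education = rnorm(n, 11, 3),
                     age = rnorm(n, 44, 9))
    class(dd) <- c("gxe_analysis", "data.frame")
    interaction_fit(dd)
  }
  fit <- mk(0.5)
  ci1 <- crossover_ci(fit, "bootstrap", n_boot = 500, seed = 99)
  ci2 <- crossover_ci(fit, "bootstrap", n_boot = 500, seed = 99)
  expect_identical(ci1, ci2)
  # delta and bootstrap intervals approach each other as noise vanishes
  gap <- vapply(c(0.5, 0.05, 0.005), function(sg) {
    f <- mk(sg)
    b <- crossover_ci(f, "bootstrap", n_boot = 500, seed = 7)
    dl <- crossover_ci(f, "delta", seed = 7)
    max(abs(b$lower - dl$lower), abs(b$upper - dl$upper))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  # noiseless: interval collapses onto the true crossover
  f0 <- mk(0)
  ci0 <- crossover_ci(f0, "bootstrap", n_boot = 200, seed = 1)
  expect_equal(ci0$lower, 0.5, tolerance = 1e-6)
  expect_equal(ci0$upper, 0.5, tolerance = 1e-6)
})

test_that("JN bounds sit exactly where the t-ratio crosses its critical value", {
  dat <- random_analysis_data(n = 250, seed = 47, B1 = 0.05, B2 = 0.5)
  fit <- interaction_fit(dat)
  jn <- jn_region(fit, alpha = 0.05)
  b <- coef(fit); v <- vcov(fit)[c("D", "XD"), c("D", "XD")]
  t_at <- function(x) {
    est <- b["D"] + b["XD"] * x
    se <- sqrt(v[1, 1] + 2 * x * v[1, 2] + x^2 * v[2, 2])
    unname(abs(est / se))
  }
  for (bound in c(jn$lower, jn$upper))
    expect_equal(t_at(bound), jn$t_crit, tolerance = 1e-8)
  # crossover lies between the bounds when both exist
  cc <- crossover_point(fit)
  expect_true(jn$lower < cc && cc < jn$upper)
  # dense-grid oracle: sign changes of |t| - t_crit within 1e-3 of bounds
  xr <- range(dat$X)
  grid <- seq(xr[1] - 3, xr[2] + 3, by = 1e-4)
  sig <- vapply(grid, t_at, numeric(1)) > jn$t_crit
  flips <- grid[which(diff(sig) != 0)]
  expect_equal(length(flips), 2)
  expect_lt(abs(flips[1] - jn$lower), 1e-3)
  expect_lt(abs(flips[2] - jn$upper), 1e-3)
})

test_that("JN region handles relabeling and saturated group effects", {
  dat <- random_analysis_data(n = 250, seed = 53, B1 = 0.05, B2 = 0.5)
  jn <- jn_region(interaction_fit(dat))
  # relabeling D flips the sign of the difference but not the region
  dat2 <- dat; dat2$D <- 1L - dat2$D
  jn2 <- jn_region(interaction_fit(dat2))
  expect_equal(jn$lower, jn2$lower, tolerance = 1e-9)
  expect_equal(jn$upper, jn2$upper, tolerance = 1e-9)
  # enormous group effect with tiny noise: significant across the
  # whole observed range (bounds fall far outside it)
  set.seed(59)
  n <- 400; x <- rnorm(n); d <- rep(0:1, n / 2)
  dat3 <- data.frame(Y = 5 * d + 0.02 * d * x + 0.3 * x +
                       rnorm(n, 0, 0.05),
                     X = x, D = d, education = rnorm(n, 11, 3),
                     age = rnorm(n, 44, 9))
  class(dat3) <- c("gxe_analysis", "data.frame")
  fit3 <- interaction_fit(dat3)
  jn3 <- jn_region(fit3)
  b <- coef(fit3); v <- vcov(fit3)[c("D", "XD"), c("D", "XD")]
  grid <- seq(min(x), max(x), length.out = 2000)
  tvals <- abs(b["D"] + b["XD"] * grid) /
    sqrt(v[1, 1] + 2 * grid * v[1, 2] + grid^2 * v[2, 2])
  expect_true(all(tvals > jn3$t_crit))
  inside <- !is.na(jn3$lower) &&
    (jn3$lower > min(x) & jn3$lower < max(x) |
     jn3$upper > min(x) & jn3$upper < max(x))
  expect_false(isTRUE(inside) && jn3$significant == "outside")
})

test_that("ros_analysis assembles a coherent result", {
  dat <- generate_cohort(synthetic_truth(seed = 61))
  res <- ros_analysis(dat, n_boot = 300, seed = 5)
  expect_s3_class(res, "ros_result")
  expect_true(res$crossover_ci$lower <= res$crossover &&
              res$crossover <= res$crossover_ci$upper)
  expect_equal(res$slopes$slope[2] - res$slopes$slope[1],
               unname(coef(res$fit)["XD"]), tolerance = 1e-12)
  expect_length(res$x_range, 2)
})
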