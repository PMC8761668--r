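#' Crossover point of the two genotype groups' regression lines
#'
#' The environment value at which the predicted group difference
#' b_D + b_XD * X vanishes: C = -b_D / b_XD. At this X the two groups'
#' regression lines intersect.
#'
#' @param fit `lm` with coefficients `D` and `XD` (see
#'   [interaction_fit()]).
#' @return the crossover point on the analysis (standardized-X) scale.
#' @export
crossover_point <- function(fit) {
  b <- stats::coef(fit)
  if (!all(c("D", "XD") %in% names(b)))
    stop("fit must contain D and XD terms", call. = FALSE)
  if (abs(b["XD"]) < .Machine$double.eps)
    stop("lines parallel; no crossover (interaction coefficient is 0)",
         call. = FALSE)
  unname(-b["D"] / b["XD"])
}

boot_crossover_draws <- function(fit, n_boot, seed, tol = 1e-10,
                                 max_degenerate_frac = 0.1) {
  mm <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  jd <- match("D", colnames(mm)); jxd <- match("XD", colnames(mm))
  n <- nrow(mm)
  set.seed(seed)
  draws <- numeric(n_boot)
  got <- 0L; tried <- 0L; degenerate <- 0L
  while (got < n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- .lm.fit(mm[idx, , drop = FALSE], y[idx])$coefficients
    tried <- tried + 1L
    if (!is.finite(cf[jxd]) || abs(cf[jxd]) < tol) {
      degenerate <- degenerate + 1L
      if (degenerate > max_degenerate_frac * max(tried, n_boot))
        stop("more than ", 100 * max_degenerate_frac,
             "% of bootstrap resamples have a numerically zero ",
             "interaction coefficient", call. = FALSE)
      next
    }
    got <- got + 1L
    draws[got] <- -cf[jd] / cf[jxd]
  }
  if (degenerate > 0L)
    message(degenerate, " degenerate bootstrap resample(s) redrawn")
  draws
}

#' Confidence interval for the crossover point
#'
#' Percentile bootstrap (case resampling, default 2000 resamples under a
#' fixed seed) or first-order delta-method propagation of the
#' (b_D, b_XD) covariance. Resamples whose interaction coefficient is
#' numerically zero are redrawn with a logged count; more than 10%
#' degenerate resamples is an error.
#'
#' @param fit `lm` with `D` and `XD` terms.
#' @param method `"bootstrap"` (default) or `"delta"`.
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed for the resampling.
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper`, `method`, `level`, and for the
#'   delta method also `se`.
#' @export
crossover_ci <- function(fit, method = c("bootstrap", "delta"),
                         n_boot = 2000, seed = 1, level = 0.95) {
  method <- match.arg(method)
  cc <- crossover_point(fit)
  if (method == "bootstrap") {
    draws <- boot_crossover_draws(fit, n_boot, seed)
    qs <- stats::quantile(draws, c((1 - level) / 2, (1 + level) / 2),
                          names = FALSE)
    list(lower = qs[1], upper = qs[2], method = "bootstrap",
         level = level, n_boot = n_boot)
  } else {
    b <- stats::coef(fit); v <- stats::vcov(fit)
    # d(-bD/bXD)/d(bD, bXD) = (-1/bXD, bD/bXD^2)
    g <- c(-1 / b["XD"], b["D"] / b["XD"]^2)
    se <- sqrt(drop(t(g) %*% v[c("D", "XD"), c("D", "XD")] %*% g))
    z <- stats::qnorm((1 + level) / 2)
    list(lower = cc - z * se, upper = cc + z * se, method = "delta",
         level = level, se = se)
  }
}

#' Johnson-Neyman region of significance for a binary moderator
#'
#' Finds the environment values X at which the genotype-group difference
#' in predicted outcome, b_D + b_XD * X, is exactly borderline
#' significant: |t(X)| = t_crit at the model's residual df. The bounds are
#' the real roots of the quadratic
#' (b_XD^2 - t^2 v22) X^2 + 2 (b_D b_XD - t^2 v12) X + (b_D^2 - t^2 v11),
#' where v is the covariance block of (b_D, b_XD). The difference is
#' significant where the quadratic is positive: outside the bounds in the
#' usual case, inside them when the leading coefficient is negative, and
#' nowhere when there are no real roots (the quadratic is negative at the
#' crossover by construction).
#'
#' @param fit `lm` with `D` and `XD` terms.
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `lower`, `upper` (NA when absent), `significant`
#'   (`"outside"`, `"inside"`, `"nowhere"`, or `"everywhere"`), `t_crit`,
#'   `alpha`.
#' @export
jn_region <- function(fit, alpha = 0.05) {
  b <- stats::coef(fit)
  if (!all(c("D", "XD") %in% names(b)))
    stop("fit must contain D and XD terms", call. = FALSE)
  v <- stats::vcov(fit)[c("D", "XD"), c("D", "XD")]
  tc <- stats::qt(1 - alpha / 2, df = stats::df.residual(fit))
  a <- b["XD"]^2 - tc^2 * v[2, 2]
  bq <- 2 * (b["D"] * b["XD"] - tc^2 * v[1, 2])
  cq <- b["D"]^2 - tc^2 * v[1, 1]
  disc <- bq^2 - 4 * a * cq
  if (disc < 0 || a == 0) {
    # constant-sign quadratic: evaluate at the crossover (or 0)
    x0 <- if (abs(b["XD"]) > .Machine$double.eps) -b["D"] / b["XD"] else 0
    sig <- unname(a * x0^2 + bq * x0 + cq) > 0
    return(list(lower = NA_real_, upper = NA_real_,
                significant = if (sig) "everywhere" else "nowhere",
                t_crit = tc, alpha = alpha))
  }
  roots <- sort((-bq + c(-1, 1) * sqrt(disc)) / (2 * a))
  list(lower = unname(roots[1]), upper = unname(roots[2]),
       significant = if (a > 0) "outside" else "inside",
       t_crit = tc, alpha = alpha)
}

#' Region-of-significance analysis of the fitted interaction
#'
#' Convenience wrapper running the full interaction model and collecting
#' the crossover point, its confidence interval, the Johnson-Neyman
#' bounds, and the per-group simple slopes. Bounds outside the observed
#' range of X are flagged: the group difference is then significant (or
#' not) only by extrapolation.
#'
#' @param data `gxe_analysis` data.frame.
#' @param covariates covariate set for the interaction model.
#' @param alpha significance level for the JN bounds.
#' @param ci_method,n_boot,seed,level passed to [crossover_ci()].
#' @return object of class `ros_result`.
#' @export
ros_analysis <- function(data, covariates = "education", alpha = 0.05,
                         ci_method = c("bootstrap", "delta"),
                         n_boot = 2000, seed = 1, level = 0.95) {
  ci_method <- match.arg(ci_method)
  fit <- interaction_fit(data, covariates)
  xr <- range(data$X)
  jn <- jn_region(fit, alpha)
  structure(
    list(crossover = crossover_point(fit),
         crossover_ci = crossover_ci(fit, ci_method, n_boot, seed, level),
         jn = jn,
         jn_outside_range = c(
           lower = !is.na(jn$lower) && (jn$lower < xr[1] || jn$lower > xr[2]),
           upper = !is.na(jn$upper) && (jn$upper < xr[1] || jn$upper > xr[2])),
         slopes = simple_slopes(fit),
         x_range = xr, alpha = alpha, fit = fit),
    class = "ros_result")
}

#' @export
print.ros_result <- function(x, ...) {
  cat("Region-of-significance / crossover analysis\n")
  cat(sprintf("crossover C = %.4f, %d%% CI (%s) [%.4f, %.4f]\n",
              x$crossover, round(100 * x$crossover_ci$level),
              x$crossover_ci$method,
              x$crossover_ci$lower, x$crossover_ci$upper))
  cat(sprintf("JN bounds (alpha = %.3f): lower = %s, upper = %s (%s)\n",
              x$alpha,
              formatC(x$jn$lower, digits = 4, format = "f"),
              formatC(x$jn$upper, digits = 4, format = "f"),
              x$jn$significant))
  if (any(x$jn_outside_range))
    cat("note: JN bound(s) fall outside the observed X range [",
        sprintf("%.3f, %.3f", x$x_range[1], x$x_range[2]), "]\n")
  cat("simple slopes:\n")
  print(format(x$slopes, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Plot the two genotype groups' regression lines with the crossover CI
#'
#' @param x `ros_result`.
#' @param ... passed to `plot()`.
#' @export
plot.ros_result <- function(x, ...) {
  b <- stats::coef(x$fit)
  mf <- stats::model.frame(x$fit)
  covs <- setdiff(names(b), c("(Intercept)", "X", "D", "XD"))
  base <- b["(Intercept)"] +
    sum(vapply(covs, function(v) b[v] * mean(mf[[v]]), numeric(1)))
  xs <- seq(x$x_range[1], x$x_range[2], length.out = 100)
  y0 <- base + b["X"] * xs
  y1 <- base + b["D"] + (b["X"] + b["XD"]) * xs
  plot(range(xs), range(c(y0, y1)), type = "n",
       xlab = "environment (standardized X)",
       ylab = "predicted outcome (standardized Y)", ...)
  ci <- x$crossover_ci
  graphics::rect(ci$lower, graphics::par("usr")[3],
                 ci$upper, graphics::par("usr")[4],
                 col = "grey90", border = NA)
  graphics::lines(xs, y0, lty = 1)
  graphics::lines(xs, y1, lty = 2)
  graphics::abline(v = x$crossover, col = "grey40", lty = 3)
  graphics::legend("topleft", lty = 1:2,
                   legend = c("non-carrier (D=0)", "carrier (D=1)"),
                   bty = "n")
  invisible(x)
}
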