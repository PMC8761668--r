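#' Gaussian information criteria from a residual sum of squares
#'
#' Maximum-likelihood Gaussian log-likelihood
#' loglik = -n/2 * (log(2*pi*SSE/n) + 1), with AIC = 2k - 2*loglik and
#' BIC = k*log(n) - 2*loglik. `k` counts every free parameter including
#' the residual SD sigma (and, for the crossover models, the crossover C
#' only when it is estimated): this is the unique counting convention
#' under which BIC - AIC = k*(log(n) - 2) reproduces the usual published
#' spacings.
#'
#' @param sse residual sum of squares.
#' @param n number of observations.
#' @param k free-parameter count (regression parameters + sigma + C when
#'   free).
#' @return list with `loglik`, `aic`, `bic`, `k`, `n`.
#' @export
information_criteria <- function(sse, n, k) {
  if (n <= k) stop("need n > k", call. = FALSE)
  if (sse <= 0) {
    warning("SSE is zero: log-likelihood unbounded, criteria undefined")
    return(list(loglik = Inf, aic = NA_real_, bic = NA_real_, k = k, n = n))
  }
  ll <- -n / 2 * (log(2 * pi * sse / n) + 1)
  list(loglik = ll, aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
       k = k, n = n)
}

reparam_model_info <- function(model) {
  switch(model,
    A = list(label = "strong differential susceptibility",
             free_B1 = FALSE, free_C = TRUE),
    B = list(label = "weak differential susceptibility",
             free_B1 = TRUE, free_C = TRUE),
    C = list(label = "strong diathesis-stress",
             free_B1 = FALSE, free_C = FALSE),
    D = list(label = "weak diathesis-stress",
             free_B1 = TRUE, free_C = FALSE),
    stop("model must be one of A, B, C, D", call. = FALSE))
}

#' Fit a re-parameterized crossover G x E regression model
#'
#' Fits one of the four crossover models for the outcome Y given
#' environment X, carrier group D and covariates:
#'
#' \preformatted{ Y = B0 + B1*(X - C)   + covariates + e   (group D = 0)
#'  Y = B0 + B2*(X - C)   + covariates + e   (group D = 1)}
#'
#' * Model A - strong differential susceptibility: B1 = 0, C estimated.
#' * Model B - weak differential susceptibility: B1 free, C estimated.
#' * Model C - strong diathesis-stress: B1 = 0, C fixed at `fix_point`.
#' * Model D - weak diathesis-stress: B1 free, C fixed at `fix_point`.
#'
#' Fixed-C models are plain least-squares fits on the transformed
#' predictors (X-C)(1-D) and (X-C)D. Free-C models are fitted through the
#' exact linear expansion Y ~ X + D + X:D + covariates (Model A drops the
#' X column), from which C = -coef(D)/coef(X:D), B1 = coef(X),
#' B2 = coef(X) + coef(X:D); this is exact, not an approximation, because
#' the expansion spans the same function space. Standard errors of the
#' derived parameters come from first-order (delta-method) propagation of
#' the linear fit's coefficient covariance. `refine = TRUE` additionally
#' runs a profile least-squares search over C (coarse grid then local
#' optimization) as an internal cross-check; the two routes agree to
#' numerical precision whenever the crossover is identified.
#'
#' The covariate coefficients follow the conventional naming: `B4` for
#' education, `B3` for age (present only when age is configured).
#'
#' @param data `gxe_analysis` data.frame (columns Y, X, D, education, age).
#' @param model `"A"`, `"B"`, `"C"` or `"D"`.
#' @param fix_point crossover location for the diathesis-stress models:
#'   `"sample_max"` (default; the observed maximum of X, the most adverse
#'   observed environment) or a number.
#' @param covariates character vector among `{"education", "age"}`.
#' @param refine run the profile-over-C cross-check for free-C models?
#' @return object of class `reparam_fit`.
#' @export
fit_reparam <- function(data, model = c("A", "B", "C", "D"),
                        fix_point = "sample_max",
                        covariates = "education", refine = FALSE) {
  model <- match.arg(model)
  info <- reparam_model_info(model)
  df <- model_terms_frame(data)
  if (length(unique(df$D)) < 2L)
    stop("both genotype groups must be present", call. = FALSE)
  if (!all(covariates %in% c("education", "age")))
    stop("covariates must be among education, age", call. = FALSE)
  n <- nrow(df)
  cov_b <- c(education = "B4", age = "B3")[covariates]

  if (!info$free_C) {
    cval <- if (identical(fix_point, "sample_max")) max(df$X)
            else as.numeric(fix_point)
    if (!is.finite(cval)) stop("fix_point must be finite", call. = FALSE)
    df$XC0 <- (df$X - cval) * (1 - df$D)
    df$XC1 <- (df$X - cval) * df$D
    terms <- c(if (info$free_B1) "XC0", "XC1", covariates)
    fit <- stats::lm(stats::reformulate(terms, response = "Y"), data = df)
    if (fit$qr$rank < length(terms) + 1L)
      stop("singular design", call. = FALSE)
    cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
    params <- c(B0 = unname(cf["(Intercept)"]),
                B1 = if (info$free_B1) unname(cf["XC0"]) else 0,
                B2 = unname(cf["XC1"]),
                stats::setNames(unname(cf[covariates]), cov_b),
                C = cval)
    ses <- c(B0 = unname(se["(Intercept)"]),
             B1 = if (info$free_B1) unname(se["XC0"]) else NA_real_,
             B2 = unname(se["XC1"]),
             stats::setNames(unname(se[covariates]), cov_b),
             C = NA_real_)
  } else {
    terms <- c(if (info$free_B1) "X", "D", "XD", covariates)
    fit <- stats::lm(stats::reformulate(terms, response = "Y"), data = df)
    if (fit$qr$rank < length(terms) + 1L)
      stop("singular design", call. = FALSE)
    cf <- stats::coef(fit)
    if (abs(cf["XD"]) < 1e-12)
      stop("crossover unidentified: interaction coefficient numerically 0",
           call. = FALSE)
    V <- stats::vcov(fit)
    cval <- unname(-cf["D"] / cf["XD"])
    # delta-method SE of C over (aD, aXD)
    gC <- c(-1 / cf["XD"], cf["D"] / cf["XD"]^2)
    seC <- sqrt(drop(t(gC) %*% V[c("D", "XD"), c("D", "XD")] %*% gC))
    se <- sqrt(diag(V))
    if (info$free_B1) {
      b1 <- unname(cf["X"]); b2 <- unname(cf["X"] + cf["XD"])
      se1 <- unname(se["X"])
      se2 <- sqrt(V["X", "X"] + V["XD", "XD"] + 2 * V["X", "XD"])
      # B0 = a0 - aX*aD/aXD; gradient over (a0, aX, aD, aXD)
      b0 <- unname(cf["(Intercept)"] + cf["X"] * cval)
      g0 <- c(1, -cf["D"] / cf["XD"], -cf["X"] / cf["XD"],
              cf["X"] * cf["D"] / cf["XD"]^2)
      idx <- c("(Intercept)", "X", "D", "XD")
      se0 <- sqrt(drop(t(g0) %*% V[idx, idx] %*% g0))
    } else {
      b1 <- 0; se1 <- NA_real_
      b2 <- unname(cf["XD"]); se2 <- unname(se["XD"])
      b0 <- unname(cf["(Intercept)"]); se0 <- unname(se["(Intercept)"])
    }
    params <- c(B0 = b0, B1 = b1, B2 = b2,
                stats::setNames(unname(cf[covariates]), cov_b),
                C = cval)
    ses <- c(B0 = se0, B1 = se1, B2 = se2,
             stats::setNames(unname(se[covariates]), cov_b),
             C = unname(seC))
  }

  sse <- sum(stats::residuals(fit)^2)
  tss <- sum((df$Y - mean(df$Y))^2)
  r2 <- 1 - sse / tss
  p <- length(stats::coef(fit))      # linear-expansion coefficients
  k <- p + 1L                        # + sigma; C-free adds its own column
  df1 <- p - 1L; df2 <- n - p
  fval <- (r2 / df1) / ((1 - r2) / df2)
  ic <- information_criteria(sse, n, k)
  out <- structure(
    list(model_label = model, description = info$label,
         params = params, se = ses,
         fixed = c(B1 = !info$free_B1, C = !info$free_C),
         sigma = sqrt(sse / df2),
         sse = sse, r2 = r2,
         fstat = list(F = fval, df1 = df1, df2 = df2,
                      p_value = stats::pf(fval, df1, df2,
                                          lower.tail = FALSE)),
         loglik = ic$loglik, aic = ic$aic, bic = ic$bic, k = k,
         n = n, df_residual = df2, covariates = covariates,
         fit = fit),
    class = "reparam_fit")
  if (refine && info$free_C) {
    out$profile <- profile_crossover(data, model, covariates)
  }
  out
}

#' Profile least-squares search for the crossover of a free-C model
#'
#' Minimizes SSE(C) of Model A or B directly over the crossover location:
#' for each candidate C the remaining parameters are profiled out by a
#' linear fit on the (X-C) predictors; the search runs a coarse grid over
#' the observed X range widened by 1 (extended if the minimum lands on an
#' edge) followed by local optimization in the bracketing cell. Serves as
#' an independent numerical route to the closed-form linear-expansion
#' estimate.
#'
#' @param data `gxe_analysis` data.frame.
#' @param model `"A"` or `"B"`.
#' @param covariates covariate set.
#' @param grid_n coarse-grid size (default 201).
#' @return list with `C`, `sse`.
#' @export
profile_crossover <- function(data, model = c("B", "A"),
                              covariates = "education", grid_n = 201) {
  model <- match.arg(model)
  df <- model_terms_frame(data)
  y <- df$Y
  covmat <- as.matrix(df[, covariates, drop = FALSE])
  x <- df$X; d <- df$D
  sse_at <- function(cc) {
    xc <- x - cc
    mm <- if (model == "B") cbind(1, xc * (1 - d), xc * d, covmat)
          else cbind(1, xc * d, covmat)
    sum(.lm.fit(mm, y)$residuals^2)
  }
  lo <- min(x) - 1; hi <- max(x) + 1
  repeat {
    grid <- seq(lo, hi, length.out = grid_n)
    vals <- vapply(grid, sse_at, numeric(1))
    i <- which.min(vals)
    if (i > 1L && i < length(grid)) break
    if (i == 1L) lo <- lo - (hi - lo) else hi <- hi + (hi - lo)
  }
  opt <- stats::optimize(sse_at, c(grid[i - 1L], grid[i + 1L]),
                         tol = 1e-10)
  list(C = opt$minimum, sse = opt$objective)
}

#' @export
print.reparam_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Re-parameterized crossover model %s (%s)\n",
              x$model_label, x$description))
  tab <- data.frame(estimate = round(x$params, digits),
                    se = round(x$se, digits))
  tab$se[is.na(x$se)] <- NA
  print(tab)
  cat(sprintf("sigma = %.4f, SSE = %.4f, R2 = %.4f\n",
              x$sigma, x$sse, x$r2))
  cat(sprintf("F(%d, %d) = %.2f, p = %.4g\n",
              x$fstat$df1, x$fstat$df2, x$fstat$F, x$fstat$p_value))
  cat(sprintf("k = %d, loglik = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$k, x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Fit all four crossover models
#'
#' @inheritParams fit_reparam
#' @return named list of `reparam_fit` objects (`A`, `B`, `C`, `D`).
#' @export
fit_all_reparam <- function(data, fix_point = "sample_max",
                            covariates = "education", refine = FALSE) {
  fits <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(m)
    fit_reparam(data, m, fix_point = fix_point, covariates = covariates,
                refine = refine))
  fits
}
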