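model_terms_frame <- function(data) {
  df <- data.frame(Y = data$Y, X = data$X, D = data$D, XD = data$X * data$D,
                   education = data$education, age = data$age)
  df
}

#' Hierarchical (stepwise-entry) moderated regression
#'
#' Ordinary least squares with predictors entered in blocks, reporting per
#' step the increment in explained variance (delta R-squared) and, for each
#' predictor in that step's model, the unstandardized coefficient B with
#' standard error, the standardized coefficient beta, t, two-sided p and
#' 95% CI. beta is computed as B * sd(predictor)/sd(Y) on the analysis
#' scale; for the product term the SD of the realized product column is
#' used. The default entry order is covariate, then main effects (X, D),
#' then the X*D product.
#'
#' @param data `gxe_analysis` data.frame (see [analysis_frame()]).
#' @param steps list of character vectors over
#'   `{"education", "age", "X", "D", "XD"}`; each step must add at least
#'   one new predictor.
#' @param conf_level confidence level for the CIs (default 0.95).
#' @return object of class `hier_fit`: per-step records plus the full
#'   model (`$full_model`, an `lm`).
#' @export
hierarchical_fit <- function(data,
                             steps = list("education", c("X", "D"), "XD"),
                             conf_level = 0.95) {
  df <- model_terms_frame(data)
  allowed <- setdiff(names(df), "Y")
  seen <- character(0)
  sd_y <- stats::sd(df$Y)
  out_steps <- vector("list", length(steps))
  r2_prev <- 0
  for (k in seq_along(steps)) {
    add <- steps[[k]]
    if (!all(add %in% allowed))
      stop("unknown predictor(s): ",
           paste(setdiff(add, allowed), collapse = ", "), call. = FALSE)
    if (any(add %in% seen) || length(add) == 0L)
      stop("step ", k, " must add at least one new predictor",
           call. = FALSE)
    seen <- c(seen, add)
    fml <- stats::reformulate(seen, response = "Y")
    fit <- stats::lm(fml, data = df)
    qr_rank <- fit$qr$rank
    if (qr_rank < length(seen) + 1L) {
      aliased <- names(which(is.na(stats::coef(fit))))
      stop("rank-deficient design at step ", k, "; collinear column(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    sm <- summary(fit)
    coefs <- sm$coefficients
    ci <- stats::confint(fit, level = conf_level)
    pred <- setdiff(rownames(coefs), "(Intercept)")
    tab <- data.frame(
      term = pred,
      B = coefs[pred, 1],
      SE = coefs[pred, 2],
      beta = coefs[pred, 1] *
        vapply(pred, function(v) stats::sd(df[[v]]), numeric(1)) / sd_y,
      t = coefs[pred, 3],
      p_value = coefs[pred, 4],
      ci_lower = ci[pred, 1],
      ci_upper = ci[pred, 2],
      row.names = NULL)
    r2 <- sm$r.squared
    out_steps[[k]] <- list(step = k, terms_added = add,
                           coefficients = tab,
                           r2 = r2, delta_r2 = r2 - r2_prev,
                           model = fit)
    r2_prev <- r2
  }
  structure(list(steps = out_steps,
                 full_model = out_steps[[length(out_steps)]]$model,
                 conf_level = conf_level),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, digits = 3, ...) {
  cat("Hierarchical moderated regression\n")
  for (s in x$steps) {
    cat(sprintf("Step %d (+ %s): R2 = %.4f, dR2 = %.4f\n",
                s$step, paste(s$terms_added, collapse = ", "),
                s$r2, s$delta_r2))
    tab <- s$coefficients[s$coefficients$term %in% s$terms_added, ]
    print(format(tab, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Fit the full interaction model by ordinary least squares
#'
#' Y ~ X + D + X:D (+ covariates), the "traditional" moderated-regression
#' parameterization whose product coefficient tests the GxE interaction.
#'
#' @param data `gxe_analysis` data.frame.
#' @param covariates character vector among `{"education", "age"}`
#'   (default education only).
#' @return `lm` fit with predictor columns `X`, `D`, `XD` and covariates.
#' @export
interaction_fit <- function(data, covariates = "education") {
  df <- model_terms_frame(data)
  if (length(unique(df$D)) < 2L)
    stop("both genotype groups must be present", call. = FALSE)
  fml <- stats::reformulate(c("X", "D", "XD", covariates), response = "Y")
  stats::lm(fml, data = df)
}

#' Per-group simple slopes of the environment on the outcome
#'
#' From the full interaction model: slope(D=0) = b_X and
#' slope(D=1) = b_X + b_XD, with standard errors from the coefficient
#' covariance matrix (variance sum plus twice the covariance for the
#' carrier group), t at residual df, two-sided p.
#'
#' @param fit an `lm` containing coefficients `X` and `XD` (see
#'   [interaction_fit()]) or a `hier_fit` whose full model does.
#' @return data.frame with rows for `D = 0` and `D = 1`: slope, SE, t,
#'   p_value.
#' @export
simple_slopes <- function(fit) {
  if (inherits(fit, "hier_fit")) fit <- fit$full_model
  b <- stats::coef(fit)
  if (!all(c("X", "XD") %in% names(b)))
    stop("fit must contain X and XD (interaction) terms", call. = FALSE)
  v <- stats::vcov(fit)
  slope <- c(b["X"], b["X"] + b["XD"])
  se <- sqrt(c(v["X", "X"],
               v["X", "X"] + v["XD", "XD"] + 2 * v["X", "XD"]))
  t <- slope / se
  df <- stats::df.residual(fit)
  data.frame(group = c(0L, 1L), slope = unname(slope), se = unname(se),
             t = unname(t),
             p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}
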