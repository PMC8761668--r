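reparam_nesting <- list(C = c("A", "B", "D"), D = "B", A = "B")

#' Nested F-test between two crossover model fits
#'
#' F = ((SSE_r - SSE_f)/df1) / (SSE_f/df2) with df1 the number of freed
#' regression parameters (the difference in k, since both fits count
#' sigma once) and df2 the full model's residual df. Valid nesting pairs
#' (restricted within full): C in A, C in B, C in D, D in B, A in B.
#' Models A and D free different parameters and are not nested; comparing
#' them is an error directing the caller to AIC/BIC.
#'
#' @param restricted,full `reparam_fit` objects on the same dataset.
#' @return list with `F`, `df1`, `df2`, `p_value`, `restricted`, `full`.
#' @export
nested_f <- function(restricted, full) {
  stopifnot(inherits(restricted, "reparam_fit"),
            inherits(full, "reparam_fit"))
  r <- restricted$model_label; f <- full$model_label
  if (!f %in% reparam_nesting[[r]])
    stop("model ", r, " is not nested in model ", f,
         "; compare non-nested models by AIC/BIC", call. = FALSE)
  if (restricted$n != full$n)
    stop("fits must be on the same dataset", call. = FALSE)
  df1 <- full$k - restricted$k
  df2 <- full$fstat$df2
  num <- max(restricted$sse - full$sse, 0)  # clamp rounding-level negatives
  fval <- (num / df1) / (full$sse / df2)
  list(F = fval, df1 = df1, df2 = df2,
       p_value = stats::pf(fval, df1, df2, lower.tail = FALSE),
       restricted = r, full = f)
}

#' Select among the four crossover models
#'
#' Formalizes the confirmatory comparison sequence: (1) within each
#' crossover regime the strong and weak variants are compared by nested F
#' (C vs D for the fixed-C pair, A vs B for the free-C pair) - a
#' significant F at `alpha` favors the weak (B1 free) variant; (2) the two
#' regime winners are compared across regimes: by nested F where they are
#' nested (a nonsignificant F favors the more parsimonious fixed-C model),
#' and by lower AIC with lower BIC as tie-break for the one non-nested
#' pairing (D vs A); (3) as a gate on the whole exercise, the interaction
#' itself is tested in the most general model (B1 = B2 hypothesis in
#' Model B) - when it is not rejected the classification is
#' "no interaction" even though a best-fitting model is still reported.
#' Every applied rule is recorded in an ordered decision trail.
#'
#' @param fits named list of the four `reparam_fit` objects (see
#'   [fit_all_reparam()]).
#' @param alpha significance level for the nested F-tests.
#' @return object of class `model_comparison`.
#' @export
select_model <- function(fits, alpha = 0.05) {
  if (!all(c("A", "B", "C", "D") %in% names(fits)))
    stop("fits must contain models A, B, C and D", call. = FALSE)
  for (m in c("A", "B", "C", "D"))
    if (!inherits(fits[[m]], "reparam_fit"))
      stop("fits$", m, " is not a reparam_fit", call. = FALSE)
  trail <- character(0)
  f_records <- list()
  note_f <- function(ft) {
    f_records[[length(f_records) + 1L]] <<- ft
    sprintf("F(%s vs %s) = %.3f (%d, %d), p = %.4f",
            ft$restricted, ft$full, ft$F, ft$df1, ft$df2, ft$p_value)
  }

  # (1) strong vs weak within each regime
  f_cd <- nested_f(fits$C, fits$D)
  fixed_winner <- if (f_cd$p_value < alpha) "D" else "C"
  trail <- c(trail, paste0(note_f(f_cd), " -> fixed-C regime favors ",
                           fixed_winner))
  f_ab <- nested_f(fits$A, fits$B)
  free_winner <- if (f_ab$p_value < alpha) "B" else "A"
  trail <- c(trail, paste0(note_f(f_ab), " -> free-C regime favors ",
                           free_winner))

  # (2) fixed-C winner vs free-C winner
  if (free_winner %in% reparam_nesting[[fixed_winner]]) {
    f_x <- nested_f(fits[[fixed_winner]], fits[[free_winner]])
    selected <- if (f_x$p_value < alpha) free_winner else fixed_winner
    trail <- c(trail, paste0(
      note_f(f_x), " -> ",
      if (f_x$p_value < alpha) "freeing C improves fit significantly"
      else "parsimony: fixed-C model retained",
      "; select ", selected))
  } else {
    # D vs A: non-nested, resolved by information criteria
    aics <- c(vapply(c(fixed_winner, free_winner),
                     function(m) fits[[m]]$aic, numeric(1)))
    bics <- c(vapply(c(fixed_winner, free_winner),
                     function(m) fits[[m]]$bic, numeric(1)))
    selected <- if (aics[1] < aics[2]) fixed_winner
                else if (aics[2] < aics[1]) free_winner
                else if (bics[1] <= bics[2]) fixed_winner else free_winner
    trail <- c(trail, sprintf(
      "%s vs %s non-nested: AIC %.2f vs %.2f, BIC %.2f vs %.2f -> select %s",
      fixed_winner, free_winner, aics[1], aics[2], bics[1], bics[2],
      selected))
  }

  # (3) interaction gate: B1 = B2 in the most general model (Model B's
  # linear expansion carries B2 - B1 as its XD coefficient)
  sm <- summary(fits$B$fit)$coefficients
  p_int <- sm["XD", 4]
  labels <- c(A = "strong differential susceptibility",
              B = "weak differential susceptibility",
              C = "strong diathesis-stress",
              D = "weak diathesis-stress")
  if (p_int < alpha) {
    classification <- unname(labels[selected])
    trail <- c(trail, sprintf(
      "interaction test (B1 = B2 in Model B): p = %.4f < %.2f -> %s",
      p_int, alpha, classification))
  } else {
    classification <- "no interaction"
    trail <- c(trail, sprintf(
      "interaction test (B1 = B2 in Model B): p = %.4f >= %.2f -> no interaction",
      p_int, alpha))
  }

  ic_table <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(m) {
    ft <- fits[[m]]
    data.frame(model = m, k = ft$k, sse = ft$sse, r2 = ft$r2,
               loglik = ft$loglik, aic = ft$aic, bic = ft$bic)
  }))
  f_table <- do.call(rbind, lapply(f_records, function(ft)
    data.frame(restricted = ft$restricted, full = ft$full, F = ft$F,
               df1 = ft$df1, df2 = ft$df2, p_value = ft$p_value)))
  structure(list(selected_model = selected,
                 classification = classification,
                 interaction_p = unname(p_int),
                 f_tests = f_table, ic_table = ic_table,
                 trail = trail, alpha = alpha),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Crossover model comparison\n")
  print(format(x$ic_table, digits = 4), row.names = FALSE)
  cat("nested F-tests:\n")
  print(format(x$f_tests, digits = 4), row.names = FALSE)
  cat("decision trail:\n")
  for (s in x$trail) cat("  - ", s, "\n", sep = "")
  cat(sprintf("selected: Model %s (%s)\n", x$selected_model,
              x$classification))
  invisible(x)
}
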