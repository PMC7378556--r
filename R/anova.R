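#' Factorial ANOVA with Tukey post hoc comparisons
#'
#' One- or two-way ANOVA (main effects, type-II sums of squares so
#' unbalanced designs are handled) on a numeric response, followed by Tukey
#' HSD pairwise comparisons for every factor whose ANOVA P value falls
#' below `alpha`.
#'
#' @param data `data.frame` holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of one or two factor column names.
#' @param alpha Significance threshold gating the post hoc test
#'   (default 0.05).
#' @return An object of class `anova_tukey`: `anova` (`data.frame` with
#'   factor, F, P), `tukey` (named list of pairwise tables for the
#'   significant factors) and `alpha`.
#' @export
anova_tukey <- function(data, response, factors, alpha = 0.05) {
  if (!response %in% names(data)) stop("response column not found")
  if (length(factors) < 1L || length(factors) > 2L)
    stop("one or two factors are supported")
  for (f in factors) {
    if (!f %in% names(data)) stop("factor column '", f, "' not found")
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L)
      stop("factor '", f, "' has fewer than 2 levels")
  }
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = "+")))
  fit <- stats::lm(fml, data = data)
  a2 <- car::Anova(fit, type = 2)
  keep <- rownames(a2) %in% factors
  tab <- data.frame(factor = rownames(a2)[keep],
                    F = a2[keep, "F value"],
                    P = a2[keep, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  aovfit <- stats::aov(fml, data = data)
  tukey <- list()
  for (i in seq_len(nrow(tab))) {
    if (is.finite(tab$P[i]) && tab$P[i] < alpha) {
      tk <- stats::TukeyHSD(aovfit, which = tab$factor[i])[[tab$factor[i]]]
      tukey[[tab$factor[i]]] <-
        data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(anova = tab, tukey = tukey, alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("<anova_tukey> alpha =", x$alpha, "\n")
  print(x$anova, row.names = FALSE)
  for (nm in names(x$tukey)) {
    cat("Tukey HSD for", nm, ":\n")
    print(x$tukey[[nm]], row.names = FALSE)
  }
  invisible(x)
}
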