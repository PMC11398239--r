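# Inter-session paired comparison following a normality-gated decision rule:
# Shapiro-Wilk on each group, paired t-test when both pass, Wilcoxon
# signed-rank on the pairs otherwise. Two-sided throughout.

#' Paired comparison with a normality-gated test choice
#'
#' @param a,b numeric vectors of paired observations (e.g. one value per
#'   subject in sessions 1 and 2); equal lengths >= 3.
#' @param alpha significance level for both the normality gate and the test.
#' @return A `paired_comparison`: chosen `test`, `statistic`, `df` (t-test
#'   only), `p_value`, `alpha`, `shapiro_p` (per group), and a `significant`
#'   flag.
#' @export
compare_paired <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("groups must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (all(a == b)) {
    warning("all paired differences are zero; degenerate comparison")
    return(structure(list(test = "degenerate", statistic = NA_real_,
                          df = NA_real_, p_value = 1, alpha = alpha,
                          shapiro_p = c(NA_real_, NA_real_),
                          significant = FALSE, n = length(a)),
                     class = "paired_comparison"))
  }
  sw <- function(x) {
    if (length(unique(x)) < 3) return(0)  # constant group cannot be normal
    stats::shapiro.test(x)$p.value
  }
  shapiro_p <- c(a = sw(a), b = sw(b))
  if (all(shapiro_p > alpha)) {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(test = "paired t-test", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    res <- list(test = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
                df = NA_real_, p_value = wt$p.value)
  }
  structure(c(res, list(alpha = alpha, shapiro_p = shapiro_p,
                        significant = res$p_value < alpha, n = length(a))),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired comparison (n = ", x$n, "): ", x$test, "\n", sep = "")
  if (x$test == "paired t-test")
    cat(sprintf("  t(%g) = %.3f, p = %.4g\n", x$df, x$statistic, x$p_value))
  else if (x$test == "Wilcoxon signed-rank")
    cat(sprintf("  W = %g, p = %.4g\n", x$statistic, x$p_value))
  else cat("  degenerate (all differences zero), p = 1\n")
  cat("  normality p-values: ", paste(signif(x$shapiro_p, 3), collapse = ", "),
      "; alpha = ", x$alpha,
      if (x$significant) " -> significant" else " -> not significant",
      "\n", sep = "")
  invisible(x)
}
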