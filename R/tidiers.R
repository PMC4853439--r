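#' Tidy an association fit
#'
#' @param x A `mirvar_assoc` object from [test_association()].
#' @param ... Unused.
#' @return A one-row tibble in broom style: `estimate` (odds ratio),
#'   `conf.low`, `conf.high`, `statistic` (chi-square), `df`, `p.value`,
#'   `p.value.fisher`.
#' @export
tidy.mirvar_assoc <- function(x, ...) {
  tibble(
    estimate = x$odds_ratio$odds_ratio,
    conf.low = x$odds_ratio$ci_low,
    conf.high = x$odds_ratio$ci_high,
    statistic = x$chi2$chi2,
    df = x$chi2$df,
    p.value = x$chi2$p_value,
    p.value.fisher = x$fisher$p_value
  )
}

#' Glance at an association fit
#'
#' @inheritParams tidy.mirvar_assoc
#' @return A one-row tibble: counts, MAFs and method descriptors.
#' @export
glance.mirvar_assoc <- function(x, ...) {
  tibble(
    n_cases = x$table$a + x$table$b,
    n_controls = x$table$c + x$table$d,
    n_case_carriers = x$table$a,
    n_control_carriers = x$table$c,
    maf_cases = x$maf_cases$maf,
    maf_controls = x$maf_controls$maf,
    minor_allele = x$table$minor_allele,
    model = x$model,
    yates = x$yates,
    conf.level = 1 - x$alpha
  )
}

#' @export
print.mirvar_assoc <- function(x, ...) {
  cat("Case-control association (", x$model, " model)\n", sep = "")
  cat(sprintf("  2x2 table [carrier | non-carrier]: cases %d | %d, controls %d | %d\n",
              x$table$a, x$table$b, x$table$c, x$table$d))
  cat(sprintf("  chi-square = %.3f (df = %d), p = %.5g%s\n",
              x$chi2$chi2, x$chi2$df, x$chi2$p_value,
              if (x$yates) " [Yates-corrected]" else ""))
  cat(sprintf("  odds ratio = %.3f, %d%% CI [%.3f, %.3f]\n",
              x$odds_ratio$odds_ratio, round(100 * (1 - x$alpha)),
              x$odds_ratio$ci_low, x$odds_ratio$ci_high))
  cat(sprintf("  Fisher exact p = %.5g\n", x$fisher$p_value))
  cat(sprintf("  MAF cases = %s (%.4f), controls = %s (%.4f)\n",
              x$maf_cases$percent_label, x$maf_cases$maf,
              x$maf_controls$percent_label, x$maf_controls$maf))
  invisible(x)
}

#' Tidy a one-way-ANOVA-with-comparisons fit
#'
#' @param x A `mirvar_anova` object from [anova_sidak()].
#' @param ... Unused.
#' @return The per-comparison tibble (`group1`, `group2`, `statistic`,
#'   `df`, `p.value`, `p.adj`).
#' @export
tidy.mirvar_anova <- function(x, ...) {
  rename(x$comparisons, p.value = "p_value", p.adj = "p_adj")
}

#' Glance at a one-way-ANOVA fit
#'
#' @inheritParams tidy.mirvar_anova
#' @return The one-row omnibus tibble.
#' @export
glance.mirvar_anova <- function(x, ...) {
  rename(x$omnibus, statistic = "f_statistic", p.value = "p_value")
}

#' @export
print.mirvar_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$f_statistic,
              x$omnibus$p_value))
  cat("Sidak-adjusted comparisons:\n")
  print(as.data.frame(x$comparisons), row.names = FALSE)
  invisible(x)
}
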