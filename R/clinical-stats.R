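#' Unpaired two-sample t test
#'
#' Two-sided comparison of two groups of continuous measurements.  The
#' default `"student"` variant pools the variances (df = n1 + n2 - 2), the
#' stated convention for the two-group phenotype comparisons; `"welch"`
#' uses the Satterthwaite approximation.
#'
#' @param x,y Numeric vectors (each n >= 2); `NA` values are dropped.
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`,
#'   `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least 2 non-missing values",
          class = "mirvar_stats_error")
  }
  if (sd(x) == 0 && sd(y) == 0 && mean(x) != mean(y)) {
    abort("zero variance in both groups with unequal means: t is infinite",
          class = "mirvar_stats_error")
  }
  fit <- t.test(x, y, var.equal = variant == "student")
  tibble(
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value, method = paste0("unpaired t (", variant, ")"),
    mean_x = mean(x), mean_y = mean(y),
    n_x = length(x), n_y = length(y)
  )
}

#' Paired t test on within-pair differences
#'
#' @param d Numeric vector of paired differences (n >= 2, non-constant).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`,
#'   `mean_diff`, `n`.
#' @export
paired_t <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) < 2) {
    abort("need at least 2 paired differences", class = "mirvar_stats_error")
  }
  if (sd(d) == 0) {
    abort("all differences identical: zero variance", class = "mirvar_stats_error")
  }
  fit <- t.test(d)
  tibble(
    statistic = unname(fit$statistic), df = unname(fit$parameter),
    p_value = fit$p.value, method = "paired t",
    mean_diff = mean(d), n = length(d)
  )
}

#' One-way ANOVA with Sidak-adjusted planned comparisons
#'
#' Omnibus one-way F test across k groups, followed by the requested
#' pairwise comparisons computed with the pooled within-group mean square
#' (t with df = N - k), Sidak-adjusted over the m requested comparisons:
#' `p_adj = 1 - (1 - p)^m`.  The adjustment family is the explicitly
#' requested comparison list, not all pairs.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param comparisons List of length-2 character vectors naming group pairs
#'   to compare; default compares every group to the first (control-style).
#' @return A list of class `mirvar_anova` with elements `omnibus` (one-row
#'   tibble: `f_statistic`, `df1`, `df2`, `p_value`) and `comparisons`
#'   (tibble: `group1`, `group2`, `statistic`, `df`, `p_value`, `p_adj`).
#' @export
anova_sidak <- function(groups, comparisons = NULL) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 groups with >= 2 values each", class = "mirvar_stats_error")
  }
  dat <- tibble(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  if (all(vapply(groups, sd, numeric(1)) == 0) &&
      length(unique(vapply(groups, mean, numeric(1)))) > 1) {
    abort("zero within-group variance everywhere with unequal means",
          class = "mirvar_stats_error")
  }
  fit <- aov(value ~ group, data = dat)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df2 <- an["Residuals", "Df"]
  omnibus <- tibble(
    f_statistic = an["group", "F value"],
    df1 = an["group", "Df"], df2 = df2,
    p_value = an["group", "Pr(>F)"]
  )
  if (is.null(comparisons)) {
    comparisons <- lapply(names(groups)[-1], function(g) c(names(groups)[1], g))
  }
  m <- length(comparisons)
  comp <- purrr::map_dfr(comparisons, function(pr) {
    if (!all(pr %in% names(groups))) {
      abort(paste0("unknown group in comparison: ", paste(pr, collapse = " vs ")),
            class = "mirvar_config_error")
    }
    g1 <- groups[[pr[1]]]; g2 <- groups[[pr[2]]]
    tstat <- (mean(g1) - mean(g2)) /
      sqrt(mse * (1 / length(g1) + 1 / length(g2)))
    p <- 2 * pt(abs(tstat), df2, lower.tail = FALSE)
    tibble(group1 = pr[1], group2 = pr[2], statistic = tstat,
           df = df2, p_value = p, p_adj = sidak_adjust(p, m))
  })
  structure(list(omnibus = omnibus, comparisons = comp),
            class = "mirvar_anova")
}

#' Sidak multiple-comparison adjustment
#'
#' @param p Raw p-value(s).
#' @param m Number of comparisons in the family.
#' @return Adjusted p-value(s) `1 - (1 - p)^m`.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  1 - (1 - p)^m
}

#' Per-group mean and standard error of the mean
#'
#' Mean +/- SEM summaries (SEM = sd / sqrt(n)).  Missing values are dropped
#' per group and counted; SEM is reported missing for n = 1 (sd undefined).
#'
#' @param data A data frame in long form.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping variable.
#' @return A tibble: `group`, `n`, `n_missing`, `mean`, `sem`.
#' @export
group_summary <- function(data, value, group) {
  if (!all(c(value, group) %in% names(data))) {
    abort("value/group columns not found in data", class = "mirvar_io_error")
  }
  out <- data %>%
    group_by(group = .data[[group]]) %>%
    summarise(
      n = sum(!is.na(.data[[value]])),
      n_missing = sum(is.na(.data[[value]])),
      mean = mean(.data[[value]], na.rm = TRUE),
      sem = if (sum(!is.na(.data[[value]])) > 1)
        sd(.data[[value]], na.rm = TRUE) / sqrt(sum(!is.na(.data[[value]])))
      else NA_real_,
      .groups = "drop"
    )
  if (any(out$n == 0)) {
    abort("empty group after dropping missing values", class = "mirvar_stats_error")
  }
  out
}

#' Compare a phenotype between genotype strata
#'
#' Joins phenotype and genotype tables on `subject_id`, stratifies the
#' chosen ECG outcome by carrier status of the minor allele, and reports the
#' per-stratum mean +/- SEM together with an unpaired t test.
#'
#' @param phenotypes Phenotype tibble (from [read_phenotype_table()]).
#' @param genotypes Genotype tibble.
#' @param outcome Outcome column, e.g. `"pr_ms"`.
#' @param variant t-test variant (see [two_sample_t()]).
#' @return A list with elements `summary` (per-stratum [group_summary()])
#'   and `test` (one-row [two_sample_t()] tibble).
#' @export
phenotype_by_genotype <- function(phenotypes, genotypes, outcome = "pr_ms",
                                  variant = c("student", "welch")) {
  variant <- match.arg(variant)
  genotypes <- mutate(genotypes, genotype = normalize_genotype(.data$genotype))
  minor <- .minor_allele(genotypes$genotype)
  dat <- phenotypes %>%
    left_join(select(genotypes, "subject_id", "genotype"), by = "subject_id") %>%
    filter(!is.na(.data$genotype)) %>%
    mutate(stratum = ifelse(.carries(.data$genotype, minor),
                            "carrier", "noncarrier"))
  strata <- split(dat[[outcome]], dat$stratum)
  list(
    summary = group_summary(dat, outcome, "stratum"),
    test = two_sample_t(strata[["noncarrier"]], strata[["carrier"]],
                        variant = variant)
  )
}
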