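#' Spike-in-normalised miRNA expression from plasma Ct values
#'
#' Relative expression against an exogenous spike-in control added at fixed
#' amount per sample: `2^-(Ct_target - Ct_spike)`.  The value is 1 when
#' target and spike-in cross at the same cycle, and halves for every cycle
#' the target lags the spike-in.  Missing Cts propagate to missing results.
#'
#' @param ct_target,ct_spike Numeric vectors of cycle-threshold values
#'   (each in (0, 45]), recycled to a common length.
#' @return Numeric vector of relative expression values (`2^-dCt`).
#' @export
#' @examples
#' spike_in_expression(25, 20)  # 2^-5 = 0.03125
spike_in_expression <- function(ct_target, ct_spike) {
  .check_ct(ct_target); .check_ct(ct_spike)
  2^(-(ct_target - ct_spike))
}

.check_ct <- function(ct) {
  if (any(!is.na(ct) & (ct <= 0 | ct > 45))) {
    abort("Ct values must lie in (0, 45]", class = "mirvar_format_error")
  }
  invisible(ct)
}

#' Aggregate a qPCR replicate set with an outlier rule
#'
#' Replicates (1-3 Cts) are averaged; if the maximum pairwise spread
#' exceeds `spread_threshold` cycles, the single replicate farthest from
#' the median is dropped first.  Returns `NA` when all replicates are
#' missing.
#'
#' @param cts Numeric vector of 1-3 replicate Cts (`NA` allowed).
#' @param spread_threshold Maximum tolerated spread in cycles (default 1.0).
#' @return The aggregated Ct (mean after the outlier rule).
#' @export
aggregate_replicates <- function(cts, spread_threshold = 1.0) {
  cts <- cts[!is.na(cts)]
  if (length(cts) == 0) return(NA_real_)
  .check_ct(cts)
  if (length(cts) > 2 && (max(cts) - min(cts)) > spread_threshold) {
    drop <- which.max(abs(cts - stats::median(cts)))
    cts <- cts[-drop]
  }
  mean(cts)
}

#' Housekeeping-normalised expression from replicate Ct sets
#'
#' Delta-Ct quantification for tissue mRNA: replicate Cts of target and
#' housekeeping assay are aggregated (see [aggregate_replicates()]), then
#' `value = 2^-(Ct_target - Ct_housekeeping)`.
#'
#' @param ct_target,ct_housekeeping Numeric vectors of 1-3 replicate Cts.
#' @param spread_threshold Passed to [aggregate_replicates()].
#' @return A single relative-expression value (or `NA` if either side is
#'   entirely missing).
#' @export
#' @examples
#' housekeeping_expression(c(24, 24, 24), c(20, 20, 20))  # 2^-4
housekeeping_expression <- function(ct_target, ct_housekeeping,
                                    spread_threshold = 1.0) {
  t_ct <- aggregate_replicates(ct_target, spread_threshold)
  h_ct <- aggregate_replicates(ct_housekeeping, spread_threshold)
  if (is.na(t_ct) || is.na(h_ct)) return(NA_real_)
  2^(-(t_ct - h_ct))
}

#' Per-sample relative expression from a long Ct table
#'
#' Pairs each sample's `target` row with its normaliser row (`spike_in` for
#' plasma, `housekeeping` for tissue), aggregates replicates and computes
#' `2^-dCt` per sample.
#'
#' @param ct_table Ct tibble (see [read_ct_table()]).
#' @param normalizer `"spike_in"` or `"housekeeping"`.
#' @param spread_threshold Passed to [aggregate_replicates()].
#' @return A tibble: `sample_id`, `assay_id`, `ct_target`, `ct_normalizer`,
#'   `value`, `normalizer`.
#' @export
relative_expression <- function(ct_table,
                                normalizer = c("spike_in", "housekeeping"),
                                spread_threshold = 1.0) {
  normalizer <- match.arg(normalizer)
  agg <- ct_table %>%
    mutate(ct = purrr::pmap_dbl(
      list(.data$ct1, .data$ct2, .data$ct3),
      function(...) aggregate_replicates(c(...), spread_threshold)
    ))
  targets <- filter(agg, .data$role == "target")
  norms <- filter(agg, .data$role == normalizer) %>%
    select("sample_id", ct_normalizer = "ct")
  n_dropped <- sum(!targets$sample_id %in% norms$sample_id)
  if (n_dropped > 0) {
    warn(sprintf("%d sample(s) without a %s row: result missing",
                 n_dropped, normalizer))
  }
  targets %>%
    left_join(norms, by = "sample_id") %>%
    mutate(value = 2^(-(.data$ct - .data$ct_normalizer)),
           normalizer = normalizer) %>%
    select("sample_id", "assay_id", ct_target = "ct", "ct_normalizer",
           "value", "normalizer")
}

#' Dual-reporter fold changes relative to a control condition
#'
#' Per-well ratio of the reporter channel to the normaliser channel
#' (orientation configurable: some constructs carry the experimental
#' reporter on Renilla and normalise to Firefly, others the reverse),
#' averaged per condition, then expressed as fold change over a designated
#' control condition (e.g. empty vector or control miRNA).
#'
#' @param wells Tibble with columns `condition`, `reporter`, `normalizer`
#'   (positive luminescence readings, one row per well).
#' @param control Name of the control condition (fold change 1 by
#'   construction).
#' @return A tibble: `condition`, `n_wells`, `mean_ratio`, `fold_change`.
#' @export
reporter_fold_change <- function(wells, control) {
  if (!all(c("condition", "reporter", "normalizer") %in% names(wells))) {
    abort("wells needs columns condition, reporter, normalizer",
          class = "mirvar_io_error")
  }
  if (any(wells$reporter <= 0 | wells$normalizer <= 0)) {
    abort("non-positive luminescence reading", class = "mirvar_format_error")
  }
  if (!control %in% wells$condition) {
    abort(paste0("control condition '", control, "' not present"),
          class = "mirvar_config_error")
  }
  per_cond <- wells %>%
    mutate(ratio = .data$reporter / .data$normalizer) %>%
    group_by(condition = .data$condition) %>%
    summarise(n_wells = n(), mean_ratio = mean(.data$ratio), .groups = "drop")
  ctrl <- per_cond$mean_ratio[per_cond$condition == control]
  mutate(per_cond, fold_change = .data$mean_ratio / ctrl)
}

#' Group fold change of relative expression
#'
#' Ratio of group means of per-sample relative expression values, e.g.
#' carrier vs non-carrier plasma miRNA levels.
#'
#' @param expr Tibble from [relative_expression()] plus a grouping column.
#' @param group Grouping column name.
#' @param reference Reference group (denominator).
#' @return A tibble: `group`, `n`, `mean_value`, `fold_change`.
#' @export
expression_fold_change <- function(expr, group, reference) {
  per <- expr %>%
    filter(!is.na(.data$value)) %>%
    group_by(across(dplyr::all_of(group))) %>%
    summarise(n = n(), mean_value = mean(.data$value), .groups = "drop")
  if (!reference %in% per[[group]]) {
    abort(paste0("reference group '", reference, "' not present"),
          class = "mirvar_config_error")
  }
  mutate(per, fold_change = .data$mean_value /
           per$mean_value[per[[group]] == reference])
}
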