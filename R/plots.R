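#' Plot an association fit as an odds-ratio interval
#'
#' Point estimate with the Woolf confidence interval on a log-scaled axis,
#' with the null (OR = 1) marked.
#'
#' @param object A `mirvar_assoc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirvar_assoc <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = "variant")) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "carrier odds ratio (95% CI, log scale)", y = NULL,
      title = sprintf("OR = %.3f, chi-square p = %.4g",
                      td$estimate, td$p.value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot gained and lost seed sites along the UTR
#'
#' One segment per site, positioned on the UTR coordinate axis, coloured by
#' status and annotated with the variant position.
#'
#' @param delta A site-delta tibble from [diff_sites()].
#' @param variant Optional one-row variant tibble to mark.
#' @return A ggplot object.
#' @export
plot_site_delta <- function(delta, variant = NULL) {
  p <- ggplot2::ggplot(delta) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mirna_id, yend = .data$mirna_id,
                   colour = .data$status),
      linewidth = 3
    ) +
    ggplot2::scale_colour_manual(values = c(gained = "#1b7837",
                                            lost = "#762a83",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "UTR position (c.*, nt)", y = NULL, colour = "status") +
    ggplot2::theme_minimal()
  if (!is.null(variant)) {
    p <- p + ggplot2::geom_vline(xintercept = variant$position,
                                 linetype = "dotted")
  }
  p
}

#' Plot group means with SEM error bars
#'
#' Bar-and-error-bar rendering of a [group_summary()] (mean +/- SEM), the
#' standard presentation for grouped phenotype and expression summaries.
#'
#' @param gs A tibble from [group_summary()].
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(gs, ylab = "mean ± SEM") {
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
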