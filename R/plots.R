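#' Plot an ROC curve
#'
#' @param object A `meth_roc` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot: the empirical ROC with the chance diagonal and the
#'   AUC in the subtitle.
#' @method autoplot meth_roc
#' @export
autoplot.meth_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = paste0(
        attr(object, "sample_type") %||% "", " ",
        attr(object, "statistic") %||% "ROC"
      ),
      subtitle = sprintf("AUC = %.3f", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' Sensitivity and specificity against the positive-marker threshold, one
#' panel per sample type when the sweep covers both.
#'
#' @param object A `meth_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_sweep
#' @export
autoplot.meth_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(unclass(object)),
    cols = c("sensitivity", "specificity"),
    names_to = "metric", values_to = "value"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$threshold, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Positive-marker threshold", y = "Proportion", colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (length(unique(df$sample_type[!is.na(df$sample_type)])) > 1) {
    p <- p + ggplot2::facet_wrap(~sample_type)
  }
  p
}

#' Forest plot of the paired post-DRE vs first-void analysis
#'
#' Mean within-patient difference (DRE minus FV) with its 95% interval for
#' each marker and summary statistic, markers with p < 0.05 highlighted.
#'
#' @param object A `meth_paired` from [paired_marker_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_paired
#' @export
autoplot.meth_paired <- function(object, ...) {
  df <- as_tibble(unclass(object))
  df$label <- factor(df$label, levels = rev(df$label))
  df$flagged <- df$p_value < 0.05
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_difference, y = .data$label, colour = .data$flagged
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.25
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
      labels = c(`TRUE` = "p < 0.05", `FALSE` = "p >= 0.05"), name = NULL
    ) +
    ggplot2::labs(
      x = "Mean difference (DRE - FV)", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Box plot of sample scores by grading group
#'
#' @param scores Tibble from [score_samples()].
#' @param statistic `"n_positive"` or `"avg_methylation"`.
#' @return A ggplot faceted by sample type, one box per grading group.
#' @export
plot_score_groups <- function(scores,
                              statistic = c("n_positive", "avg_methylation")) {
  statistic <- rlang::arg_match(statistic)
  df <- dplyr::filter(scores, !is.na(.data$grading_group))
  df$group <- factor(df$grading_group)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group, y = .data[[statistic]], fill = .data$group
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~sample_type) +
    ggplot2::scale_fill_manual(values = c(
      "0" = "seagreen3", "1" = "steelblue", "2" = "firebrick"
    ), guide = "none") +
    ggplot2::labs(x = "Grading group", y = statistic) +
    ggplot2::theme_minimal()
}
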