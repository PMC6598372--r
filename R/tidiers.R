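#' Tidy an ROC curve
#'
#' @param x A `meth_roc` from [roc_points()].
#' @param ... Unused.
#' @return Tibble of operating points: `threshold`, `fpr`, `tpr`.
#' @method tidy meth_roc
#' @export
tidy.meth_roc <- function(x, ...) {
  tibble(threshold = x$threshold, fpr = x$fpr, tpr = x$tpr)
}

#' One-row summary of an ROC curve
#'
#' @param x A `meth_roc` from [roc_points()].
#' @param ... Unused.
#' @return One-row tibble: `sample_type`, `statistic`, `auc`, `n_cases`,
#'   `n_controls`.
#' @method glance meth_roc
#' @export
glance.meth_roc <- function(x, ...) {
  tibble(
    sample_type = attr(x, "sample_type"),
    statistic = attr(x, "statistic"),
    auc = attr(x, "auc"),
    n_cases = attr(x, "n_cases"),
    n_controls = attr(x, "n_controls")
  )
}

#' Tidy a grading-group comparison
#'
#' @param x A `meth_groups` from [group_summaries()].
#' @param ... Unused.
#' @return The per-group summary tibble with `statistic` and `sample_type`
#'   columns prepended.
#' @method tidy meth_groups
#' @export
tidy.meth_groups <- function(x, ...) {
  dplyr::mutate(x$summaries,
    statistic = x$statistic, sample_type = x$sample_type,
    .before = 1
  )
}

#' One-row summary of a grading-group comparison
#'
#' @param x A `meth_groups` from [group_summaries()].
#' @param ... Unused.
#' @return One-row tibble with the two Wilcoxon p-values
#'   (`p_controls_vs_cases` for group 0 vs 1+2, `p_group1_vs_group2`).
#' @method glance meth_groups
#' @export
glance.meth_groups <- function(x, ...) {
  p <- setNames(x$tests$p_value, x$tests$comparison)
  tibble(
    statistic = x$statistic,
    sample_type = x$sample_type,
    p_controls_vs_cases = unname(p["0 vs 1+2"]),
    p_group1_vs_group2 = unname(p["1 vs 2"])
  )
}

#' Tidy a threshold sweep
#'
#' @param x A `meth_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return The sweep as a plain tibble.
#' @method tidy meth_sweep
#' @export
tidy.meth_sweep <- function(x, ...) {
  as_tibble(unclass(x))
}
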