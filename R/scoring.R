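#' Score each sample: positive-marker count and average methylation
#'
#' Computes the two sample-level statistics the pipeline is built around:
#' `n_positive`, the number of panel markers with any detectable methylation
#' (the cumulative "n of 32" statistic), and `avg_methylation`, the sum of
#' all panel signals divided by the full panel size — zero markers included
#' in the denominator, so a sample with no amplification anywhere scores 0
#' on both.
#'
#' @param cohort A [meth_cohort()].
#' @return Tibble with one row per sample: `patient_id`, `sample_type`,
#'   `diagnosis`, `grading_group`, `n_positive`, `avg_methylation`.
#' @export
#' @examples
#' cfg <- default_generator_config(seed = 1)
#' score_samples(generate_cohort(cfg))
score_samples <- function(cohort) {
  stopifnot(inherits(cohort, "meth_cohort"))
  panel_size <- length(cohort$panel)
  scores <- dplyr::summarise(
    dplyr::group_by(cohort$signals, .data$patient_id, .data$sample_type),
    n_positive = sum(is_positive(.data$signal)),
    avg_methylation = sum(.data$signal) / panel_size,
    .groups = "drop"
  )
  dplyr::left_join(
    scores,
    dplyr::select(cohort$patients, "patient_id", "diagnosis", "grading_group"),
    by = "patient_id"
  ) |>
    dplyr::select(
      "patient_id", "sample_type", "diagnosis", "grading_group",
      "n_positive", "avg_methylation"
    )
}

#' Classify samples by a positive-marker threshold
#'
#' A sample is called positive — "recommend a biopsy" in the screening
#' setting — when its number of methylated markers reaches the threshold:
#' `n_positive >= threshold`. The call is monotone in the threshold; a
#' sample positive at threshold t is positive at every threshold below t.
#'
#' @param n_positive Integer vector of positive-marker counts.
#' @param threshold Integer threshold between 1 and `panel_size`.
#' @param panel_size Number of markers in the panel (default 32).
#' @return Logical vector: `TRUE` where the sample meets the threshold.
#' @export
#' @examples
#' classify(c(9, 10, 32), threshold = 10) # FALSE TRUE TRUE
classify <- function(n_positive, threshold, panel_size = 32) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
    threshold != as.integer(threshold) ||
    threshold < 1 || threshold > panel_size) {
    abort(sprintf(
      "`threshold` must be a single integer in 1..%d.", panel_size
    ))
  }
  if (any(n_positive < 0 | n_positive > panel_size, na.rm = TRUE)) {
    abort(sprintf("`n_positive` must lie in 0..%d.", panel_size))
  }
  n_positive >= threshold
}
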