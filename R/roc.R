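#' Reconstruct a score distribution from cumulative threshold counts
#'
#' Published threshold-sweep tables report, for each threshold t, the number
#' of samples scoring at or above t (cumulative/survival counts). Those
#' columns determine the full per-sample score distribution: the number of
#' samples with score exactly c is `S(c) - S(c + 1)` (with `S` the
#' at-or-above count, `S(K + 1) = 0` past the last threshold), and the
#' number scoring 0 is `n - S(1)`. This inverts a printed cumulative column
#' into a probability mass function over scores `0..K`, from which medians,
#' sweeps and ROC curves can be recomputed.
#'
#' @param cumulative Integer vector: `cumulative[t]` is the number of
#'   samples with score >= t, for thresholds t = 1..K. Must be
#'   non-increasing with `cumulative[1] <= n`.
#' @param n Total number of samples.
#' @return Tibble with columns `score` (0..K) and `count`, summing to `n`.
#' @seealso [pmf_to_cumulative()] (the inverse), [expand_counts()].
#' @export
#' @examples
#' reconstruct_pmf(c(5, 5, 2), n = 6) # scores 0..3: counts 1,0,3,2
reconstruct_pmf <- function(cumulative, n) {
  cumulative <- as.numeric(cumulative)
  if (length(cumulative) == 0L || anyNA(cumulative)) {
    abort("`cumulative` must be a non-empty vector without NA.")
  }
  if (any(diff(cumulative) > 0)) {
    abort("`cumulative` must be non-increasing in the threshold.")
  }
  if (cumulative[1] > n || any(cumulative < 0)) {
    abort("`cumulative` counts must lie in 0..n.")
  }
  counts <- c(n - cumulative[1], -diff(c(cumulative, 0)))
  tibble(score = seq_along(counts) - 1L, count = as.integer(counts))
}

#' Re-accumulate a score pmf into at-or-above counts
#'
#' Inverse of [reconstruct_pmf()]: returns, for each threshold t = 1..K,
#' the number of samples with score >= t.
#'
#' @param pmf Tibble with columns `score` and `count`.
#' @return Integer vector of length `max(score)`.
#' @export
pmf_to_cumulative <- function(pmf) {
  k <- max(pmf$score)
  vapply(seq_len(k), function(t) sum(pmf$count[pmf$score >= t]), numeric(1)) |>
    as.integer()
}

#' Expand a score pmf into per-sample values
#'
#' @param pmf Tibble with columns `score` and `count`.
#' @return Numeric vector with each score repeated `count` times.
#' @export
expand_counts <- function(pmf) {
  rep(pmf$score, pmf$count)
}

#' Mann-Whitney AUC with half-credit ties
#'
#' The area under the empirical ROC curve, computed as the Mann-Whitney
#' probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted half:
#' `AUC = (#\{case > control\} + 0.5 * #\{case = control\}) / (n1 * n2)`.
#' On integer scores ties are common, and the half-credit convention makes
#' the pairwise statistic equal the trapezoidal area under the empirical
#' ROC curve through all unique thresholds. Implemented via midranks, so it
#' is O(n log n); tests verify it against the literal pairwise double loop.
#'
#' @param case_scores,control_scores Numeric score vectors (higher = more
#'   disease-like).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_mann_whitney(c(3, 4, 5), c(1, 2, 3)) # 1 tie pair: 8.5/9
auc_mann_whitney <- function(case_scores, control_scores) {
  n1 <- length(case_scores)
  n2 <- length(control_scores)
  if (n1 == 0L || n2 == 0L) {
    abort("Both score vectors must be non-empty.")
  }
  if (anyNA(case_scores) || anyNA(control_scores)) {
    abort("Scores must not contain NA.")
  }
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Empirical ROC curve
#'
#' One operating point per unique observed score, classifying positive at
#' `score >= threshold`, thresholds descending from above the maximum (the
#' (0, 0) corner) down to the minimum score (the (1, 1) corner). The
#' trapezoidal area under the resulting step-with-ties curve equals
#' [auc_mann_whitney()] on the same data.
#'
#' @inheritParams auc_mann_whitney
#' @param statistic Optional name of the score statistic (annotation only).
#' @param sample_type Optional sample-type annotation.
#' @return Tibble of class `meth_roc` with columns `threshold`, `fpr`,
#'   `tpr`, and attributes `auc`, `n_cases`, `n_controls`, `statistic`,
#'   `sample_type`.
#' @export
#' @examples
#' roc <- roc_points(c(3, 4, 5), c(1, 2, 3))
#' attr(roc, "auc")
roc_points <- function(case_scores, control_scores,
                       statistic = NA_character_,
                       sample_type = NA_character_) {
  n1 <- length(case_scores)
  n2 <- length(control_scores)
  if (n1 == 0L || n2 == 0L) {
    abort("Both score vectors must be non-empty.")
  }
  cuts <- sort(unique(c(case_scores, control_scores)), decreasing = TRUE)
  thresholds <- c(Inf, cuts)
  tpr <- vapply(thresholds, function(t) mean(case_scores >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(control_scores >= t), numeric(1))
  out <- tibble(threshold = thresholds, fpr = fpr, tpr = tpr)
  auc <- trapezoid_area(out$fpr, out$tpr)
  structure(
    out,
    auc = auc, n_cases = n1, n_controls = n2,
    statistic = statistic, sample_type = sample_type,
    class = c("meth_roc", class(out))
  )
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
}

#' Bundled per-threshold performance counts from the reference urine cohort
#'
#' The cumulative classification counts reported for the original 85
#' post-DRE / 65 first-void urine DNA cohort (36 DRE cases vs 49 DRE
#' controls, 30 FV cases vs 35 FV controls), at every positive-marker
#' threshold from 1 to 32: `pos_cases` is the number of case samples with
#' at least `threshold` methylated markers, `neg_controls` the number of
#' control samples with fewer. These printed counts are inputs to the
#' package's desk-scale reproductions: [reconstruct_pmf()] inverts them
#' into per-sample score distributions.
#'
#' @return Tibble: `sample_type`, `threshold`, `pos_cases`, `n_cases`,
#'   `neg_controls`, `n_controls` (64 rows).
#' @export
study_threshold_counts <- function() {
  path <- system.file("extdata", "threshold_counts.csv", package = "methpanel")
  readr::read_csv(path,
    col_types = readr::cols(
      sample_type = "c", threshold = "i", pos_cases = "i",
      n_cases = "i", neg_controls = "i", n_controls = "i"
    ),
    progress = FALSE
  )
}

#' Bundled per-marker detection counts from the reference urine cohort
#'
#' Per-marker positives among cases and negatives among controls for the 13
#' newly assayed CpG-island markers, by sample type, as reported for the
#' reference cohort. Sensitivities are `pos_cases / n_cases` and
#' specificities `neg_controls / n_controls`; these rates also seed the
#' synthetic-cohort generator's class-conditional detection probabilities
#' ([default_generator_config()]).
#'
#' @return Tibble: `marker`, `sample_type`, `pos_cases`, `n_cases`,
#'   `neg_controls`, `n_controls` (26 rows).
#' @export
study_marker_rates <- function() {
  path <- system.file("extdata", "marker_rates.csv", package = "methpanel")
  readr::read_csv(path,
    col_types = readr::cols(
      marker = "c", sample_type = "c", pos_cases = "i", n_cases = "i",
      neg_controls = "i", n_controls = "i"
    ),
    progress = FALSE
  )
}

#' Reconstruct per-sample count distributions for the reference cohort
#'
#' Applies [reconstruct_pmf()] to the bundled cumulative counts
#' ([study_threshold_counts()]) for one sample type. For cases the printed
#' column is already the at-or-above count; for controls the printed column
#' counts negatives (below threshold), so it is flipped to `n - negatives`
#' first.
#'
#' @param sample_type `"DRE"` or `"FV"`.
#' @return List with elements `cases` and `controls`, each a pmf tibble
#'   (`score`, `count`) over scores 0..32.
#' @export
#' @examples
#' d <- reconstruct_study_distributions("DRE")
#' median(expand_counts(d$cases)) # 16
reconstruct_study_distributions <- function(sample_type = c("DRE", "FV")) {
  sample_type <- rlang::arg_match(sample_type)
  tab <- dplyr::filter(
    study_threshold_counts(), .data$sample_type == !!sample_type
  ) |>
    dplyr::arrange(.data$threshold)
  list(
    cases = reconstruct_pmf(tab$pos_cases, n = tab$n_cases[1]),
    controls = reconstruct_pmf(
      tab$n_controls[1] - tab$neg_controls, n = tab$n_controls[1]
    )
  )
}
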