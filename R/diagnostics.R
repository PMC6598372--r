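#' Wald confidence interval for a binomial proportion
#'
#' The normal-approximation (Wald) interval
#' `p +/- z * sqrt(p * (1 - p) / n)` around the observed proportion
#' `p = successes / n`. The interval is deliberately **not** truncated to
#' \[0, 1\]: near-perfect sensitivities yield upper bounds above 1 (e.g.
#' 28/30 gives (0.84, 1.02)) and near-zero rates yield negative lower
#' bounds, and the untruncated bounds are what diagnostic reports built on
#' this interval print. At p = 0 or p = 1 the interval has zero width.
#'
#' @param successes Integer vector of success counts.
#' @param n Integer vector of trials (recycled); must be positive.
#' @param z Normal quantile; fixed default 1.96 for a 95% interval.
#' @return Tibble with columns `estimate`, `low`, `high`.
#' @export
#' @examples
#' wald_ci(28, 30) # upper bound 1.02
wald_ci <- function(successes, n, z = 1.96) {
  if (any(!is.finite(n) | n <= 0)) {
    abort("`n` must be positive: interval undefined for n = 0.")
  }
  if (any(successes < 0 | successes > n)) {
    abort("`successes` must lie in 0..n.")
  }
  p <- successes / n
  half <- z * sqrt(p * (1 - p) / n)
  tibble(estimate = p, low = p - half, high = p + half)
}

#' Evaluate a binary classifier against biopsy outcome
#'
#' Folds per-sample calls into a 2x2 table and the four conditional
#' metrics. Sensitivity and specificity are conditioned on diagnosis
#' (TP/(TP+FN), TN/(TN+FP)) and carry Wald 95% intervals; PPV and NPV are
#' computed directly from the table at the cohort's own prevalence
#' (TP/(TP+FP), TN/(TN+FN)) and are `NA` when their denominator is empty,
#' rendered as `"na"` by [format_diagnostics()].
#'
#' @param case_calls Logical vector: classifier call for each case sample.
#' @param control_calls Logical vector: call for each control sample.
#' @param label Row label (marker name or threshold such as `"10of32"`).
#' @param sample_type Optional sample type annotation (`"DRE"`/`"FV"`).
#' @param z Normal quantile for the Wald intervals.
#' @return One-row tibble: `label`, `sample_type`, `tp`, `fn`, `fp`, `tn`,
#'   `n_cases`, `n_controls`, `sensitivity`, `sens_low`, `sens_high`,
#'   `specificity`, `spec_low`, `spec_high`, `ppv`, `npv`.
#' @export
#' @examples
#' evaluate_binary(rep(c(TRUE, FALSE), c(29, 7)), rep(c(FALSE, TRUE), c(37, 12)))
evaluate_binary <- function(case_calls, control_calls, label = NA_character_,
                            sample_type = NA_character_, z = 1.96) {
  case_calls <- as.logical(case_calls)
  control_calls <- as.logical(control_calls)
  if (length(case_calls) == 0L || length(control_calls) == 0L) {
    abort("Need at least one case and one control call.")
  }
  if (anyNA(case_calls) || anyNA(control_calls)) {
    abort("Calls must not contain NA.")
  }
  tp <- sum(case_calls)
  fn <- length(case_calls) - tp
  fp <- sum(control_calls)
  tn <- length(control_calls) - fp

  sens_ci <- wald_ci(tp, tp + fn, z = z)
  spec_ci <- wald_ci(tn, tn + fp, z = z)
  tibble(
    label = label, sample_type = sample_type,
    tp = tp, fn = fn, fp = fp, tn = tn,
    n_cases = tp + fn, n_controls = tn + fp,
    sensitivity = sens_ci$estimate,
    sens_low = sens_ci$low, sens_high = sens_ci$high,
    specificity = spec_ci$estimate,
    spec_low = spec_ci$low, spec_high = spec_ci$high,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Per-marker diagnostic table
#'
#' One diagnostic row per panel marker, calling a sample positive for that
#' marker when any methylation was detected ([is_positive()]), i.e. the
#' single-marker analogue of the panel threshold classifier.
#'
#' @param cohort A [meth_cohort()].
#' @param sample_type `"DRE"` or `"FV"`.
#' @param markers Markers to evaluate; defaults to the whole panel, in
#'   panel order.
#' @return Tibble with one [evaluate_binary()] row per marker.
#' @export
per_marker_table <- function(cohort, sample_type, markers = cohort$panel) {
  stopifnot(inherits(cohort, "meth_cohort"))
  check_sample_type(sample_type)
  stopifnot(length(sample_type) == 1L)
  dat <- marker_class_signals(cohort, sample_type)
  purrr::map_dfr(markers, function(m) {
    sub <- dplyr::filter(dat, .data$marker == m)
    evaluate_binary(
      is_positive(sub$signal[sub$diagnosis == "case"]),
      is_positive(sub$signal[sub$diagnosis == "control"]),
      label = m, sample_type = sample_type
    )
  })
}

marker_class_signals <- function(cohort, sample_type) {
  dat <- dplyr::filter(cohort$signals, .data$sample_type == !!sample_type)
  dat <- dplyr::left_join(
    dat,
    dplyr::select(cohort$patients, "patient_id", "diagnosis"),
    by = "patient_id"
  )
  if (!all(c("case", "control") %in% dat$diagnosis)) {
    abort(paste0(
      "Need both cases and controls with ", sample_type, " samples."
    ))
  }
  dat
}

#' Diagnostic threshold sweep over the whole panel
#'
#' Evaluates the positive-marker-count classifier at every threshold from 1
#' to the panel size, reproducing the cumulative "n of N" performance
#' table: row t classifies a sample positive when at least t markers are
#' methylated. Case-positive counts are non-increasing and control-negative
#' counts non-decreasing in t by construction.
#'
#' @param cohort A [meth_cohort()].
#' @param sample_type `"DRE"` or `"FV"`.
#' @param thresholds Integer thresholds to evaluate (default 1..panel size).
#' @return Tibble of class `meth_sweep`: one [evaluate_binary()] row per
#'   threshold, labelled `"<t>of<panel size>"`, with a `threshold` column.
#' @export
#' @examples
#' cohort <- generate_cohort(default_generator_config(seed = 1))
#' threshold_sweep(cohort, "DRE")
threshold_sweep <- function(cohort, sample_type,
                            thresholds = seq_along(cohort$panel)) {
  stopifnot(inherits(cohort, "meth_cohort"))
  scores <- dplyr::filter(
    score_samples(cohort), .data$sample_type == !!sample_type
  )
  sweep_from_scores(
    scores$n_positive[scores$diagnosis == "case"],
    scores$n_positive[scores$diagnosis == "control"],
    panel_size = length(cohort$panel),
    thresholds = thresholds, sample_type = sample_type
  )
}

#' Threshold sweep from per-sample positive-marker counts
#'
#' Lower-level form of [threshold_sweep()] operating on bare count vectors,
#' e.g. counts reconstructed from a published cumulative table via
#' [reconstruct_pmf()].
#'
#' @param case_counts,control_counts Integer vectors of per-sample
#'   positive-marker counts.
#' @param panel_size Panel size (defines the threshold range and labels).
#' @param thresholds Thresholds to evaluate.
#' @param sample_type Optional annotation.
#' @return Tibble of class `meth_sweep`.
#' @export
sweep_from_scores <- function(case_counts, control_counts, panel_size = 32,
                              thresholds = seq_len(panel_size),
                              sample_type = NA_character_) {
  if (length(case_counts) == 0L || length(control_counts) == 0L) {
    abort("Need scores for at least one case and one control.")
  }
  rows <- purrr::map_dfr(thresholds, function(t) {
    out <- evaluate_binary(
      classify(case_counts, t, panel_size),
      classify(control_counts, t, panel_size),
      label = sprintf("%dof%d", t, panel_size),
      sample_type = sample_type
    )
    out$threshold <- as.integer(t)
    out
  })
  new_meth_sweep(dplyr::relocate(rows, "threshold"))
}

new_meth_sweep <- function(x) {
  class(x) <- unique(c("meth_sweep", class(x)))
  x
}

#' Round half away from zero
#'
#' Fixed-precision rounding where exact halves round up (2.5 -> 2.55 at one
#' digit fewer), matching how diagnostic tables are conventionally printed;
#' R's own `round()` rounds halves to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Format a diagnostic table for reporting
#'
#' Rounds metrics half-up to `digits` decimals, renders confidence
#' intervals as `"(low, high)"`, counts as `"k/n"` fractions, and undefined
#' predictive values as `"na"`. Internal tables stay at full precision;
#' this is presentation only.
#'
#' @param tbl A tibble from [evaluate_binary()], [per_marker_table()] or
#'   [threshold_sweep()].
#' @param digits Decimal places (default 2, as such tables are printed).
#' @return Tibble of characters: `label`, `sample_type`, `cases`,
#'   `sensitivity`, `sens_ci`, `controls`, `specificity`, `spec_ci`,
#'   `ppv`, `npv`.
#' @export
format_diagnostics <- function(tbl, digits = 2) {
  num <- function(x) {
    ifelse(is.na(x), "na", formatC(round_half_up(x, digits),
      format = "f", digits = digits
    ))
  }
  tibble(
    label = tbl$label,
    sample_type = tbl$sample_type,
    cases = sprintf("%d/%d", tbl$tp, tbl$n_cases),
    sensitivity = num(tbl$sensitivity),
    sens_ci = sprintf("(%s, %s)", num(tbl$sens_low), num(tbl$sens_high)),
    controls = sprintf("%d/%d", tbl$tn, tbl$n_controls),
    specificity = num(tbl$specificity),
    spec_ci = sprintf("(%s, %s)", num(tbl$spec_low), num(tbl$spec_high)),
    ppv = num(tbl$ppv),
    npv = num(tbl$npv)
  )
}
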