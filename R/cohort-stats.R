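#' Wilcoxon rank-sum test (two-sided)
#'
#' Two-sample location comparison used for grading-group contrasts. Uses
#' the exact null distribution when both groups have at most 10
#' observations and the pooled data are tie-free, otherwise the normal
#' approximation with the usual tie correction. No continuity correction by
#' default (`correct = FALSE`), matching the default of the statistical
#' environment such comparisons are conventionally run in; set
#' `correct = TRUE` to apply it.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param correct Apply the continuity correction in the normal
#'   approximation? Default `FALSE`.
#' @return One-row tibble: `statistic` (the rank-sum W for `x`), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(101, 102, 103))
wilcoxon_rank_sum <- function(x, y, correct = FALSE) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both samples must be non-empty.")
  }
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= 10L && length(y) <= 10L && !ties
  fit <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = correct)
  )
  p <- fit$p.value
  # every pooled value tied: the null variance is 0 and there is no
  # evidence of a shift, so report p = 1 rather than NaN
  if (is.na(p)) p <- 1
  tibble(
    statistic = unname(fit$statistic),
    p_value = p,
    method = if (use_exact) "exact" else "normal"
  )
}

#' Paired t test on within-patient differences
#'
#' One-sample t test that the mean within-patient difference is zero, with
#' a 95% confidence interval on the mean difference. Degenerate inputs are
#' handled explicitly: identically zero differences give t = 0, p = 1;
#' constant nonzero differences are the infinite-t limit (p reported as 0,
#' degenerate interval at the mean).
#'
#' @param differences Numeric vector of paired differences (at least 2),
#'   oriented DRE minus FV throughout this package.
#' @param label Optional name of the marker or statistic being compared.
#' @return One-row tibble: `label`, `n_pairs`, `mean_difference`,
#'   `conf_low`, `conf_high`, `statistic` (t), `p_value`.
#' @export
#' @examples
#' paired_t(c(0.5, -0.2, 0.9, 1.1, 0.3))
paired_t <- function(differences, label = NA_character_) {
  if (length(differences) < 2L) {
    abort("Need at least 2 paired differences.")
  }
  if (anyNA(differences)) abort("Differences must not contain NA.")
  n <- length(differences)
  m <- mean(differences)
  s <- sd(differences)
  # constant to machine precision counts as zero-variance (t.test itself
  # refuses "essentially constant" data)
  if (s == 0 || s / sqrt(n) <= 10 * .Machine$double.eps * abs(m)) {
    s <- 0
  }
  if (s == 0) {
    return(tibble(
      label = label, n_pairs = n, mean_difference = m,
      conf_low = m, conf_high = m,
      statistic = if (m == 0) 0 else sign(m) * Inf,
      p_value = if (m == 0) 1 else 0
    ))
  }
  fit <- t.test(differences)
  tibble(
    label = label, n_pairs = n, mean_difference = m,
    conf_low = fit$conf.int[1], conf_high = fit$conf.int[2],
    statistic = unname(fit$statistic), p_value = fit$p.value
  )
}

#' Paired post-DRE vs first-void analysis
#'
#' For every patient with both a post-DRE and a first-void sample, computes
#' within-patient differences (DRE minus FV) for each marker's signal and
#' for the two sample-level statistics (`n_positive`, `avg_methylation`),
#' and runs [paired_t()] on each. A positive mean difference means the
#' marker is recovered better from post-DRE urine.
#'
#' @param cohort A [meth_cohort()].
#' @return Tibble of class `meth_paired`: one [paired_t()] row per marker
#'   plus rows labelled `n_positive` and `avg_methylation`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_generator_config(seed = 1))
#' paired_marker_analysis(cohort)
paired_marker_analysis <- function(cohort) {
  stopifnot(inherits(cohort, "meth_cohort"))
  types <- dplyr::summarise(
    dplyr::group_by(cohort$samples, .data$patient_id),
    both = all(c("DRE", "FV") %in% .data$sample_type), .groups = "drop"
  )
  paired_ids <- types$patient_id[types$both]
  if (length(paired_ids) < 2L) {
    abort("Need at least 2 patients with both DRE and FV samples.")
  }

  sig <- dplyr::filter(cohort$signals, .data$patient_id %in% paired_ids) |>
    tidyr::pivot_wider(
      id_cols = c("patient_id", "marker"),
      names_from = "sample_type", values_from = "signal"
    ) |>
    dplyr::mutate(diff = .data$DRE - .data$FV)

  marker_rows <- purrr::map_dfr(cohort$panel, function(m) {
    paired_t(sig$diff[sig$marker == m], label = m)
  })

  scores <- dplyr::filter(
    score_samples(cohort), .data$patient_id %in% paired_ids
  ) |>
    tidyr::pivot_wider(
      id_cols = "patient_id", names_from = "sample_type",
      values_from = c("n_positive", "avg_methylation")
    )
  stat_rows <- dplyr::bind_rows(
    paired_t(scores$n_positive_DRE - scores$n_positive_FV,
      label = "n_positive"
    ),
    paired_t(scores$avg_methylation_DRE - scores$avg_methylation_FV,
      label = "avg_methylation"
    )
  )
  out <- dplyr::bind_rows(marker_rows, stat_rows)
  class(out) <- c("meth_paired", class(out))
  out
}

#' Grading-group summaries and comparisons
#'
#' Summarises one sample-level statistic (positive-marker count or average
#' methylation) within each risk grading group — 0 (negative biopsy), 1
#' (low-risk CAPRA), 2 (elevated-risk CAPRA) and the combined group 1+2
#' (all positive biopsies) — with box-plot quantities (median, first and
#' third quartiles via linear interpolation, extremes), and runs Wilcoxon
#' rank-sum comparisons of 0 vs 1+2 and 1 vs 2. Cases without a grading
#' group (follow-up reclassifications) are excluded from the grouping.
#'
#' @param cohort A [meth_cohort()].
#' @param statistic `"n_positive"` or `"avg_methylation"`.
#' @param sample_type `"DRE"` or `"FV"`.
#' @param correct Continuity correction flag passed to
#'   [wilcoxon_rank_sum()].
#' @return Object of class `meth_groups`: list with `statistic`,
#'   `sample_type`, `summaries` (tibble: group, n, mean, sd, min, q1,
#'   median, q3, max) and `tests` (tibble: comparison, statistic, p_value).
#' @export
#' @examples
#' cohort <- generate_cohort(default_generator_config(seed = 1))
#' group_summaries(cohort, "n_positive", "DRE")
group_summaries <- function(cohort,
                            statistic = c("n_positive", "avg_methylation"),
                            sample_type = c("DRE", "FV"),
                            correct = FALSE) {
  stopifnot(inherits(cohort, "meth_cohort"))
  statistic <- rlang::arg_match(statistic)
  sample_type <- rlang::arg_match(sample_type)
  scores <- dplyr::filter(
    score_samples(cohort), .data$sample_type == !!sample_type
  )
  x <- scores[[statistic]]
  gg <- scores$grading_group

  groups <- list(
    "0" = x[!is.na(gg) & gg == 0L],
    "1" = x[!is.na(gg) & gg == 1L],
    "2" = x[!is.na(gg) & gg == 2L],
    "1+2" = x[!is.na(gg) & gg %in% c(1L, 2L)]
  )
  summaries <- purrr::imap_dfr(groups, function(v, label) {
    if (length(v) == 0L) {
      return(tibble(
        group = label, n = 0L, mean = NA_real_, sd = NA_real_,
        min = NA_real_, q1 = NA_real_, median = NA_real_,
        q3 = NA_real_, max = NA_real_
      ))
    }
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    tibble(
      group = label, n = length(v), mean = mean(v),
      sd = if (length(v) > 1) sd(v) else NA_real_,
      min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v)
    )
  })

  comparisons <- list(
    "0 vs 1+2" = list(groups[["0"]], groups[["1+2"]]),
    "1 vs 2" = list(groups[["1"]], groups[["2"]])
  )
  tests <- purrr::imap_dfr(comparisons, function(pair, label) {
    if (length(pair[[1]]) == 0L || length(pair[[2]]) == 0L) {
      warn(paste0("Empty group: skipping comparison ", label, "."))
      return(tibble(
        comparison = label, statistic = NA_real_, p_value = NA_real_,
        method = NA_character_
      ))
    }
    res <- wilcoxon_rank_sum(pair[[1]], pair[[2]], correct = correct)
    dplyr::bind_cols(tibble(comparison = label), res)
  })

  structure(
    list(
      statistic = statistic, sample_type = sample_type,
      summaries = summaries, tests = tests
    ),
    class = "meth_groups"
  )
}

#' @export
print.meth_groups <- function(x, ...) {
  cat(sprintf(
    "<meth_groups> %s, %s samples\n", x$statistic, x$sample_type
  ))
  print(x$summaries)
  print(x$tests)
  invisible(x)
}

#' Case PSA mean under the iterated outlier-exclusion rule
#'
#' Summary convention for case PSA: any value greater than twice the
#' highest remaining value is excluded, applied iteratively from the top
#' until the maximum no longer exceeds twice the runner-up. The mean and SD
#' are then taken over the retained values.
#'
#' @param psa Numeric vector of PSA values (ng/mL); `NA`s dropped.
#' @return List with `mean`, `sd`, `excluded` (values removed, largest
#'   first), `n_used`.
#' @export
#' @examples
#' psa_mean_with_outlier_rule(c(5, 6, 40)) # 40 excluded
psa_mean_with_outlier_rule <- function(psa) {
  psa <- psa[!is.na(psa)]
  if (length(psa) == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, excluded = numeric(0), n_used = 0L))
  }
  kept <- sort(psa, decreasing = TRUE)
  excluded <- numeric(0)
  while (length(kept) >= 2L && kept[1] > 2 * kept[2]) {
    excluded <- c(excluded, kept[1])
    kept <- kept[-1]
  }
  list(
    mean = mean(kept),
    sd = if (length(kept) > 1) sd(kept) else NA_real_,
    excluded = excluded,
    n_used = length(kept)
  )
}

#' Cohort demographics table
#'
#' Summarises patient characteristics by diagnosis the way screening-cohort
#' demographic tables are laid out: mean/SD/median/range for age and PSA
#' (case PSA under the outlier rule of [psa_mean_with_outlier_rule()]),
#' counts and percentages for sample availability and, when the patient
#' table carries them, race, Gleason score (dichotomised at <= 7 vs > 7,
#' boundary inclusive in the low stratum) and positive biopsy cores
#' (<= 3 vs > 3).
#'
#' @param cohort A [meth_cohort()].
#' @return Tibble with character columns `variable`, `statistic`, `cases`,
#'   `controls`.
#' @export
cohort_demographics <- function(cohort) {
  stopifnot(inherits(cohort, "meth_cohort"))
  pts <- cohort$patients
  cases <- pts[pts$diagnosis == "case", ]
  ctrls <- pts[pts$diagnosis == "control", ]
  fmt <- function(x, d = 1) formatC(x, format = "f", digits = d)
  pct <- function(k, n) sprintf("%d (%s%%)", k, fmt(100 * k / n))

  num_block <- function(var, x_case, x_ctrl, d = 1) {
    s <- function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) {
        return(c("0", NA, NA, NA))
      }
      c(
        as.character(length(x)),
        sprintf("%s (%s)", fmt(mean(x), d), fmt(sd(x), d)),
        fmt(median(x), d),
        sprintf("%s-%s", fmt(min(x), d), fmt(max(x), d))
      )
    }
    a <- s(x_case)
    b <- s(x_ctrl)
    tibble(
      variable = var,
      statistic = c("n", "mean (sd)", "median", "range"),
      cases = a, controls = b
    )
  }

  out <- dplyr::bind_rows(
    tibble(
      variable = "patients", statistic = "n",
      cases = as.character(nrow(cases)), controls = as.character(nrow(ctrls))
    ),
    num_block("age", cases$age, ctrls$age)
  )

  psa_case <- psa_mean_with_outlier_rule(cases$psa)
  psa_rows <- num_block("psa", cases$psa, ctrls$psa)
  psa_rows$cases[psa_rows$statistic == "mean (sd)"] <-
    sprintf("%s (%s)", fmt(psa_case$mean), fmt(psa_case$sd))
  psa_rows <- dplyr::bind_rows(psa_rows, tibble(
    variable = "psa", statistic = "outliers excluded (cases)",
    cases = as.character(length(psa_case$excluded)), controls = "0"
  ))
  out <- dplyr::bind_rows(out, psa_rows)

  avail <- dplyr::summarise(
    dplyr::group_by(cohort$samples, .data$patient_id),
    kind = if (all(c("DRE", "FV") %in% .data$sample_type)) {
      "DRE and FV"
    } else if ("DRE" %in% .data$sample_type) "DRE only" else "FV only",
    .groups = "drop"
  )
  avail <- dplyr::left_join(
    avail, dplyr::select(pts, "patient_id", "diagnosis"),
    by = "patient_id"
  )
  for (kind in c("DRE and FV", "DRE only", "FV only")) {
    k_case <- sum(avail$kind == kind & avail$diagnosis == "case")
    k_ctrl <- sum(avail$kind == kind & avail$diagnosis == "control")
    out <- dplyr::bind_rows(out, tibble(
      variable = "urine samples", statistic = kind,
      cases = pct(k_case, nrow(cases)), controls = pct(k_ctrl, nrow(ctrls))
    ))
  }

  if ("race" %in% names(pts)) {
    for (lev in sort(unique(pts$race[!is.na(pts$race)]))) {
      out <- dplyr::bind_rows(out, tibble(
        variable = "race", statistic = lev,
        cases = pct(sum(cases$race == lev, na.rm = TRUE), nrow(cases)),
        controls = pct(sum(ctrls$race == lev, na.rm = TRUE), nrow(ctrls))
      ))
    }
  }

  dichotomised <- function(var, cut) {
    if (!var %in% names(pts)) {
      return(NULL)
    }
    x <- cases[[var]]
    known <- x[!is.na(x)]
    tibble(
      variable = var,
      statistic = c(
        "n", "mean (sd)",
        sprintf("<= %s", cut), sprintf("> %s", cut), "missing"
      ),
      cases = c(
        as.character(length(known)),
        if (length(known)) {
          sprintf("%s (%s)", fmt(mean(known)), fmt(sd(known)))
        } else {
          NA_character_
        },
        pct(sum(known <= cut), nrow(cases)),
        pct(sum(known > cut), nrow(cases)),
        pct(sum(is.na(x)), nrow(cases))
      ),
      controls = "NA"
    )
  }
  out <- dplyr::bind_rows(
    out,
    dichotomised("gleason", 7),
    dichotomised("positive_cores", 3)
  )
  out
}
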