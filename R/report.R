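#' Run the full panel evaluation on a cohort
#'
#' One pass over a cohort producing every analysis table: the per-marker
#' diagnostic table, the full threshold sweep, ROC curves and AUCs for both
#' sample-level statistics, grading-group summaries with Wilcoxon
#' comparisons, the paired post-DRE vs first-void analysis (when at least
#' two patients have both samples), and the demographics table. Samples
#' failing the amplifiable-DNA control are dropped first.
#'
#' @param cohort A [meth_cohort()].
#' @param threshold Headline positive-marker threshold used in the report
#'   summary (default 10, i.e. "10 of 32" on the default panel).
#' @param sample_types Sample types to evaluate; types with missing classes
#'   are skipped with a warning.
#' @return Object of class `meth_report`: a list with elements `threshold`,
#'   `scores`, `per_marker`, `sweep`, `roc` (list of `meth_roc`), `auc`
#'   (tibble), `groups` (list of `meth_groups`), `paired`, `demographics`,
#'   `rejected`.
#' @export
#' @examples
#' report <- evaluate_cohort(generate_cohort(default_generator_config(seed = 1)))
#' report$auc
evaluate_cohort <- function(cohort, threshold = 10,
                            sample_types = c("DRE", "FV")) {
  stopifnot(inherits(cohort, "meth_cohort"))
  qc <- qc_filter(cohort)
  cohort <- qc$cohort
  panel_size <- length(cohort$panel)
  if (threshold < 1 || threshold > panel_size) {
    abort(sprintf("`threshold` must lie in 1..%d.", panel_size))
  }
  scores <- score_samples(cohort)

  usable <- function(stype) {
    sub <- scores[scores$sample_type == stype, ]
    ok <- all(c("case", "control") %in% sub$diagnosis)
    if (!ok) {
      warn(paste0(
        "Skipping ", stype, ": need both cases and controls."
      ))
    }
    ok
  }
  sample_types <- sample_types[vapply(sample_types, usable, logical(1))]
  if (length(sample_types) == 0L) {
    abort("No sample type has both cases and controls.")
  }

  per_marker <- purrr::map_dfr(sample_types, function(st) {
    per_marker_table(cohort, st)
  })
  sweep <- purrr::map_dfr(sample_types, function(st) {
    threshold_sweep(cohort, st)
  })
  sweep <- new_meth_sweep(sweep)

  roc <- list()
  for (st in sample_types) {
    sub <- scores[scores$sample_type == st, ]
    for (stat in c("n_positive", "avg_methylation")) {
      roc[[paste(st, stat, sep = ".")]] <- roc_points(
        sub[[stat]][sub$diagnosis == "case"],
        sub[[stat]][sub$diagnosis == "control"],
        statistic = stat, sample_type = st
      )
    }
  }
  auc <- purrr::map_dfr(roc, glance)

  groups <- list()
  for (st in sample_types) {
    for (stat in c("n_positive", "avg_methylation")) {
      groups[[paste(st, stat, sep = ".")]] <-
        group_summaries(cohort, stat, st)
    }
  }

  n_paired <- sum(table(cohort$samples$patient_id) == 2L)
  paired <- if (n_paired >= 2L) paired_marker_analysis(cohort) else NULL

  structure(
    list(
      threshold = threshold,
      scores = scores,
      per_marker = per_marker,
      sweep = sweep,
      roc = roc,
      auc = auc,
      groups = groups,
      paired = paired,
      demographics = cohort_demographics(cohort),
      rejected = qc$rejected
    ),
    class = "meth_report"
  )
}

#' @export
print.meth_report <- function(x, ...) {
  cat("<meth_report>\n")
  head_rows <- dplyr::filter(x$sweep, .data$threshold == x$threshold)
  cat(sprintf("Headline threshold %dof%d:\n", x$threshold,
    max(x$sweep$threshold)))
  print(format_diagnostics(head_rows))
  cat("AUCs:\n")
  print(x$auc)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every table of a [evaluate_cohort()] report as CSV plus a single
#' JSON summary (headline threshold metrics and AUCs) to a directory.
#'
#' @param report A `meth_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "meth_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(dir, name)
  readr::write_csv(report$scores, out("scores.csv"), progress = FALSE)
  readr::write_csv(
    format_diagnostics(report$per_marker), out("per_marker.csv"),
    progress = FALSE
  )
  readr::write_csv(report$per_marker, out("per_marker_full.csv"),
    progress = FALSE
  )
  readr::write_csv(
    format_diagnostics(report$sweep), out("threshold_sweep.csv"),
    progress = FALSE
  )
  readr::write_csv(report$sweep, out("threshold_sweep_full.csv"),
    progress = FALSE
  )
  roc_tbl <- purrr::imap_dfr(report$roc, function(r, nm) {
    dplyr::mutate(tidy(r),
      sample_type = attr(r, "sample_type"),
      statistic = attr(r, "statistic")
    )
  })
  readr::write_csv(roc_tbl, out("roc_points.csv"), progress = FALSE)
  if (!is.null(report$paired)) {
    readr::write_csv(report$paired, out("paired_analysis.csv"),
      progress = FALSE
    )
  }
  grp_tbl <- purrr::imap_dfr(report$groups, function(g, nm) {
    dplyr::mutate(g$summaries,
      statistic = g$statistic, sample_type = g$sample_type
    )
  })
  readr::write_csv(grp_tbl, out("group_summaries.csv"), progress = FALSE)
  grp_tests <- purrr::imap_dfr(report$groups, function(g, nm) {
    dplyr::mutate(g$tests,
      score_statistic = g$statistic, sample_type = g$sample_type
    )
  })
  readr::write_csv(grp_tests, out("group_tests.csv"), progress = FALSE)
  readr::write_csv(report$demographics, out("demographics.csv"),
    progress = FALSE
  )

  head_rows <- dplyr::filter(
    report$sweep, .data$threshold == report$threshold
  )
  summary <- list(
    threshold = report$threshold,
    headline = head_rows,
    auc = report$auc,
    n_samples = nrow(report$scores),
    n_rejected = nrow(report$rejected)
  )
  jsonlite::write_json(summary, out("summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(dir)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience runner (also used by the command-line script): generates a
#' cohort from a configuration, writes the signal table, patient metadata
#' and a provenance record of the exact configuration used.
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @param layout Signal file layout (`"long"` or `"wide"`).
#' @return The generated [meth_cohort()], invisibly.
#' @export
run_simulate <- function(config, dir, layout = "long") {
  cohort <- generate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(dir, "cohort.csv"), layout = layout)
  write_patients(cohort, file.path(dir, "patients.csv"))
  prov <- config
  class(prov) <- NULL
  prov$rates <- as.data.frame(prov$rates)
  jsonlite::write_json(
    prov, file.path(dir, "generator_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(cohort)
}

#' Evaluate a cohort from files and write the report bundle
#'
#' @param cohort_path Signal table path (see [read_cohort()]).
#' @param metadata_path Patient metadata CSV path.
#' @param dir Output directory for [write_report()].
#' @param layout,values Passed to [read_cohort()].
#' @param threshold Headline threshold.
#' @param panel Marker panel.
#' @return The `meth_report`, invisibly.
#' @export
run_evaluate <- function(cohort_path, metadata_path, dir,
                         layout = "long", values = "signal",
                         threshold = 10, panel = default_panel()) {
  cohort <- read_cohort(
    cohort_path,
    layout = layout, values = values,
    panel = panel, metadata = metadata_path
  )
  report <- evaluate_cohort(cohort, threshold = threshold)
  write_report(report, dir)
  invisible(report)
}
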