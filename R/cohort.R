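#' Build a validated methylation cohort
#'
#' A `meth_cohort` bundles the three tables the pipeline works on: the long
#' per-sample, per-marker signal table; the per-sample table (sample type
#' and the amplifiable-DNA control flag from the imprinted-gene assay); and
#' the per-patient table (biopsy diagnosis, risk grading group, PSA, age).
#' Construction validates the whole object: every sample must cover the
#' panel exactly once, every sample's patient must resolve, a patient may
#' contribute at most one sample of each type (post-DRE and first-void),
#' and a control patient must sit in grading group 0.
#'
#' @param signals Data frame with columns `patient_id`, `sample_type`
#'   (`"DRE"` or `"FV"`), `marker`, `signal` (non-negative methylation
#'   signal; 0 means no amplification).
#' @param patients Data frame with columns `patient_id`, `diagnosis`
#'   (`"case"` or `"control"`) and optionally `grading_group` (0 = negative
#'   biopsy, 1 = low-risk CAPRA score of 2 or less, 2 = CAPRA score of 3 or
#'   more; `NA` for cases reclassified on follow-up without a CAPRA score),
#'   `psa` (ng/mL), `age` (years), plus any further metadata columns
#'   (e.g. `race`, `gleason`, `positive_cores`).
#' @param panel Character vector of marker names; defaults to the bundled
#'   32-marker panel.
#' @param samples Optional data frame with columns `patient_id`,
#'   `sample_type`, `control_ok` (logical QC flag). When omitted it is
#'   derived from `signals` with `control_ok = TRUE`.
#' @return An object of class `meth_cohort`: a list with elements `panel`,
#'   `signals`, `samples`, `patients`.
#' @export
#' @examples
#' sig <- tidyr::expand_grid(
#'   patient_id = c("P1", "P2"), sample_type = "DRE",
#'   marker = default_panel()
#' )
#' sig$signal <- rep(c(3, 0), each = 32)
#' pts <- tibble::tibble(
#'   patient_id = c("P1", "P2"),
#'   diagnosis = c("case", "control"),
#'   grading_group = c(1, 0)
#' )
#' meth_cohort(sig, pts)
meth_cohort <- function(signals, patients, panel = default_panel(),
                        samples = NULL) {
  check_panel(panel)
  signals <- as_tibble(signals)
  patients <- as_tibble(patients)

  need <- c("patient_id", "sample_type", "marker", "signal")
  missing_cols <- setdiff(need, names(signals))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "`signals` is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  signals <- dplyr::mutate(
    signals,
    patient_id = as.character(.data$patient_id),
    sample_type = as.character(.data$sample_type),
    marker = as.character(.data$marker),
    signal = as.numeric(.data$signal)
  )
  check_sample_type(signals$sample_type)

  unknown <- setdiff(unique(signals$marker), panel)
  if (length(unknown) > 0L) {
    abort(paste0(
      "Marker(s) not in the panel: ", paste(unknown, collapse = ", ")
    ))
  }
  if (anyNA(signals$signal)) {
    abort("`signals$signal` contains missing values; encode no amplification as 0.")
  }
  if (any(signals$signal < 0)) {
    abort("Methylation signals must be non-negative.")
  }

  dup <- dplyr::count(
    signals, .data$patient_id, .data$sample_type, .data$marker
  )
  dup <- dplyr::filter(dup, .data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0(
      "Duplicated (patient_id, sample_type, marker) rows, e.g. ",
      dup$patient_id[1], "/", dup$sample_type[1], "/", dup$marker[1]
    ))
  }

  coverage <- dplyr::summarise(
    dplyr::group_by(signals, .data$patient_id, .data$sample_type),
    n_markers = dplyr::n(), .groups = "drop"
  )
  incomplete <- dplyr::filter(coverage, .data$n_markers != length(panel))
  if (nrow(incomplete) > 0L) {
    miss <- setdiff(panel, signals$marker[
      signals$patient_id == incomplete$patient_id[1] &
        signals$sample_type == incomplete$sample_type[1]
    ])
    abort(paste0(
      "Sample ", incomplete$patient_id[1], "/", incomplete$sample_type[1],
      " does not cover the panel exactly (missing: ",
      paste(head(miss, 5), collapse = ", "),
      if (length(miss) > 5) ", ..." else "", ")"
    ))
  }

  if (!all(c("patient_id", "diagnosis") %in% names(patients))) {
    abort("`patients` must have columns `patient_id` and `diagnosis`.")
  }
  patients <- dplyr::mutate(
    patients,
    patient_id = as.character(.data$patient_id),
    diagnosis = as.character(.data$diagnosis)
  )
  if (anyDuplicated(patients$patient_id)) {
    abort("`patients$patient_id` must be unique.")
  }
  bad_dx <- setdiff(unique(patients$diagnosis), c("case", "control"))
  if (length(bad_dx) > 0L) {
    abort(paste0(
      "`diagnosis` must be \"case\" or \"control\"; found: ",
      paste(bad_dx, collapse = ", ")
    ))
  }
  if (!"grading_group" %in% names(patients)) {
    patients$grading_group <- ifelse(patients$diagnosis == "control", 0L, NA_integer_)
  }
  patients$grading_group <- as.integer(patients$grading_group)
  bad_gg <- setdiff(unique(patients$grading_group), c(0L, 1L, 2L, NA))
  if (length(bad_gg) > 0L) {
    abort("`grading_group` must be 0, 1, 2 or NA.")
  }
  bad_ctrl <- patients$diagnosis == "control" &
    (is.na(patients$grading_group) | patients$grading_group != 0L)
  if (any(bad_ctrl)) {
    abort(paste0(
      "Control patients must have grading_group 0: ",
      paste(head(patients$patient_id[bad_ctrl], 5), collapse = ", ")
    ))
  }
  for (col in c("psa", "age")) {
    if (!col %in% names(patients)) patients[[col]] <- NA_real_
    patients[[col]] <- as.numeric(patients[[col]])
  }

  if (is.null(samples)) {
    samples <- dplyr::distinct(signals, .data$patient_id, .data$sample_type)
    samples$control_ok <- TRUE
  } else {
    samples <- as_tibble(samples)
    if (!all(c("patient_id", "sample_type", "control_ok") %in% names(samples))) {
      abort("`samples` must have columns patient_id, sample_type, control_ok.")
    }
    samples <- dplyr::mutate(
      samples,
      patient_id = as.character(.data$patient_id),
      sample_type = as.character(.data$sample_type),
      control_ok = as.logical(.data$control_ok)
    )
    key <- function(d) paste(d$patient_id, d$sample_type)
    sig_keys <- unique(key(signals))
    if (!setequal(key(samples), sig_keys) || anyDuplicated(key(samples))) {
      abort("`samples` must list each (patient_id, sample_type) in `signals` exactly once.")
    }
  }

  orphan <- setdiff(samples$patient_id, patients$patient_id)
  if (length(orphan) > 0L) {
    abort(paste0(
      "Sample patient_id(s) missing from `patients`: ",
      paste(head(orphan, 5), collapse = ", ")
    ))
  }

  structure(
    list(
      panel = panel,
      signals = dplyr::arrange(
        dplyr::mutate(signals,
          marker = factor(.data$marker, levels = panel)
        ),
        .data$patient_id, .data$sample_type, .data$marker
      ) |>
        dplyr::mutate(marker = as.character(.data$marker)),
      samples = dplyr::arrange(samples, .data$patient_id, .data$sample_type),
      patients = dplyr::arrange(patients, .data$patient_id)
    ),
    class = "meth_cohort"
  )
}

#' @export
print.meth_cohort <- function(x, ...) {
  n_case <- sum(x$patients$diagnosis == "case")
  n_ctrl <- sum(x$patients$diagnosis == "control")
  cat(sprintf(
    "<meth_cohort> %d markers, %d samples (%d DRE, %d FV), %d patients (%d cases / %d controls)\n",
    length(x$panel), nrow(x$samples),
    sum(x$samples$sample_type == "DRE"), sum(x$samples$sample_type == "FV"),
    nrow(x$patients), n_case, n_ctrl
  ))
  invisible(x)
}

#' Per-sample signal matrix in wide form
#'
#' @param cohort A [meth_cohort()].
#' @return Tibble with `patient_id`, `sample_type`, then one numeric column
#'   per panel marker, in panel order.
#' @export
signals_wide <- function(cohort) {
  stopifnot(inherits(cohort, "meth_cohort"))
  tidyr::pivot_wider(
    cohort$signals,
    id_cols = c("patient_id", "sample_type"),
    names_from = "marker", values_from = "signal"
  ) |>
    dplyr::select(dplyr::all_of(c("patient_id", "sample_type", cohort$panel)))
}

#' Read a cohort from tabular files
#'
#' Reads per-sample, per-marker measurements from a CSV/TSV file in long
#' format (`patient_id, sample_type, marker, value`) or wide format
#' (`patient_id, sample_type`, one column per panel marker), joins patient
#' metadata, and returns a validated [meth_cohort()]. Files may carry either
#' already-transformed methylation signals (`values = "signal"`, where the
#' literal 0 means no amplification and blank cells are an error) or raw Cq
#' values (`values = "cq"`, where a blank cell or the token `"Undetermined"`
#' means no amplification, matching common qPCR export conventions); Cq
#' values are passed through [transform_cq()].
#'
#' @param path Path to the sample file (`.csv` or `.tsv`, by extension).
#' @param layout `"long"` or `"wide"`.
#' @param values `"signal"` or `"cq"`.
#' @param panel Marker panel; wide files must have exactly these marker
#'   columns, long files may not mention markers outside it.
#' @param metadata Patient metadata: a path to a CSV with columns
#'   `patient_id, diagnosis, capra_group, psa, age, control_ok` (and
#'   optionally `followup_cancer`, `race`, `gleason`, `positive_cores`), or
#'   an equivalent data frame, or `NULL` to label every patient as a
#'   control with no metadata (useful for format round-trips).
#' @param apply_followup When `TRUE` (default) patients flagged
#'   `followup_cancer` in the metadata — negative biopsy later upgraded to a
#'   cancer diagnosis on clinical follow-up — are reclassified as cases
#'   before any analysis; their grading group becomes `NA` since no biopsy
#'   CAPRA score exists.
#' @param max_cycles Cycle ceiling for [transform_cq()] when `values = "cq"`.
#' @return A validated [meth_cohort()].
#' @export
read_cohort <- function(path, layout = c("long", "wide"),
                        values = c("signal", "cq"),
                        panel = default_panel(), metadata = NULL,
                        apply_followup = TRUE, max_cycles = 32) {
  layout <- rlang::arg_match(layout)
  values <- rlang::arg_match(values)
  check_panel(panel)
  raw <- read_delim_auto(path)

  if (layout == "long") {
    need <- c("patient_id", "sample_type", "marker", "value")
    if (!all(need %in% names(raw))) {
      abort(paste0(
        "Long layout needs columns ", paste(need, collapse = ", "),
        "; found ", paste(names(raw), collapse = ", ")
      ))
    }
    long <- dplyr::select(raw, dplyr::all_of(need))
  } else {
    id_cols <- c("patient_id", "sample_type")
    if (!all(id_cols %in% names(raw))) {
      abort("Wide layout needs columns patient_id and sample_type.")
    }
    marker_cols <- setdiff(names(raw), id_cols)
    if (!setequal(marker_cols, panel)) {
      abort(paste0(
        "Wide marker columns do not match the panel (missing: ",
        paste(head(setdiff(panel, marker_cols), 5), collapse = ", "),
        "; extra: ",
        paste(head(setdiff(marker_cols, panel), 5), collapse = ", "), ")"
      ))
    }
    long <- tidyr::pivot_longer(
      raw,
      cols = dplyr::all_of(panel),
      names_to = "marker", values_to = "value",
      values_transform = as.character
    )
  }

  long$value <- as.character(long$value)
  if (values == "cq") {
    blank <- is.na(long$value) | long$value %in% c("", "Undetermined")
    cq <- suppressWarnings(as.numeric(long$value))
    if (any(!blank & is.na(cq))) {
      abort(paste0(
        "Unparseable Cq value(s), e.g. \"",
        long$value[!blank & is.na(cq)][1], "\""
      ))
    }
    cq[blank] <- NA_real_
    long$signal <- transform_cq(cq, max_cycles = max_cycles)
  } else {
    sig <- suppressWarnings(as.numeric(long$value))
    if (any(is.na(sig))) {
      abort("Signal files may not contain blank or non-numeric cells; encode no amplification as 0.")
    }
    long$signal <- sig
  }
  long <- dplyr::select(long, -"value")

  pts <- read_patients(metadata, apply_followup = apply_followup)
  if (is.null(pts)) {
    pts <- tibble(
      patient_id = unique(as.character(long$patient_id)),
      diagnosis = "control", grading_group = 0L, control_ok = TRUE
    )
  }
  samples <- dplyr::distinct(long, .data$patient_id, .data$sample_type) |>
    dplyr::mutate(patient_id = as.character(.data$patient_id))
  if ("control_ok" %in% names(pts)) {
    samples <- dplyr::left_join(
      samples, dplyr::select(pts, "patient_id", "control_ok"),
      by = "patient_id"
    )
    samples$control_ok <- samples$control_ok %|% TRUE
  } else {
    samples$control_ok <- TRUE
  }
  pts$control_ok <- NULL

  meth_cohort(long, pts, panel = panel, samples = samples)
}

`%|%` <- function(x, y) ifelse(is.na(x), y, x)

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
      progress = FALSE
    )
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
      progress = FALSE
    )
  }
}

#' Read a patient metadata table
#'
#' @inheritParams read_cohort
#' @param x Path to a metadata CSV/TSV, a data frame, or `NULL`.
#' @return Tibble of patient metadata with the column `capra_group` renamed
#'   to `grading_group`, or `NULL` when `x` is `NULL`.
#' @export
read_patients <- function(x, apply_followup = TRUE) {
  if (is.null(x)) {
    return(NULL)
  }
  pts <- if (is.character(x)) read_delim_auto(x) else as_tibble(x)
  if ("capra_group" %in% names(pts) && !"grading_group" %in% names(pts)) {
    pts <- dplyr::rename(pts, grading_group = "capra_group")
  }
  for (col in intersect(c("grading_group"), names(pts))) {
    pts[[col]] <- as.integer(pts[[col]])
  }
  for (col in intersect(c("psa", "age", "gleason", "positive_cores"), names(pts))) {
    pts[[col]] <- as.numeric(pts[[col]])
  }
  for (col in intersect(c("control_ok", "followup_cancer"), names(pts))) {
    pts[[col]] <- as.logical(pts[[col]])
  }
  if (apply_followup && "followup_cancer" %in% names(pts)) {
    flip <- !is.na(pts$followup_cancer) & pts$followup_cancer &
      pts$diagnosis == "control"
    pts$diagnosis[flip] <- "case"
    if ("grading_group" %in% names(pts)) {
      pts$grading_group[flip] <- NA_integer_
    }
  }
  pts
}

#' Write a cohort's signal table to a file
#'
#' Writes the per-sample, per-marker methylation signals as CSV/TSV in long
#' or wide layout, such that `read_cohort()` on the result reproduces the
#' signals exactly (signals are plain decimal text, so values recorded at
#' fixed decimal precision round-trip bit-exactly).
#'
#' @inheritParams read_cohort
#' @param cohort A [meth_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, layout = c("long", "wide")) {
  stopifnot(inherits(cohort, "meth_cohort"))
  layout <- rlang::arg_match(layout)
  out <- if (layout == "long") {
    dplyr::rename(cohort$signals, value = "signal")
  } else {
    signals_wide(cohort)
  }
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a cohort's patient metadata to a CSV
#'
#' @param cohort A [meth_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(cohort, path) {
  stopifnot(inherits(cohort, "meth_cohort"))
  qc <- dplyr::summarise(
    dplyr::group_by(cohort$samples, .data$patient_id),
    control_ok = all(.data$control_ok), .groups = "drop"
  )
  out <- dplyr::left_join(cohort$patients, qc, by = "patient_id") |>
    dplyr::rename(capra_group = "grading_group")
  out$control_ok <- out$control_ok %|% TRUE
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Drop samples that failed the amplifiable-DNA control assay
#'
#' Each urine sample carries a QC flag from an imprinted-gene control assay
#' run alongside the markers to verify that amplifiable DNA was recovered.
#' Samples whose flag is `FALSE` are removed from the cohort before any
#' scoring; patients are kept even if all their samples are rejected, so the
#' metadata table is unchanged.
#'
#' @param cohort A [meth_cohort()].
#' @return A list with `cohort` (the filtered [meth_cohort()]) and
#'   `rejected` (tibble of removed samples: `patient_id`, `sample_type`).
#' @export
qc_filter <- function(cohort) {
  stopifnot(inherits(cohort, "meth_cohort"))
  bad <- dplyr::filter(cohort$samples, !.data$control_ok)
  if (nrow(bad) == 0L) {
    return(list(cohort = cohort, rejected = bad[, c("patient_id", "sample_type")]))
  }
  keep_key <- paste(cohort$samples$patient_id, cohort$samples$sample_type)[
    cohort$samples$control_ok
  ]
  sig <- dplyr::filter(
    cohort$signals,
    paste(.data$patient_id, .data$sample_type) %in% keep_key
  )
  if (length(keep_key) == 0L) {
    warn("All samples failed the amplifiable-DNA control; cohort is empty.")
  }
  filtered <- structure(
    list(
      panel = cohort$panel,
      signals = sig,
      samples = dplyr::filter(cohort$samples, .data$control_ok),
      patients = cohort$patients
    ),
    class = "meth_cohort"
  )
  list(cohort = filtered, rejected = bad[, c("patient_id", "sample_type")])
}
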