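# In-code fixtures: small cohorts built from signal matrices.

mini_panel <- function(k = 4) paste0("M", seq_len(k))

# mat: samples x markers signal matrix (colnames = panel). One sample per
# patient unless patient_ids repeats ids across sample types.
cohort_from_matrix <- function(mat, diagnosis,
                               sample_type = rep("DRE", nrow(mat)),
                               patient_ids = sprintf("P%02d", seq_len(nrow(mat))),
                               grading_group = NULL,
                               control_ok = rep(TRUE, nrow(mat)),
                               panel = colnames(mat), ...) {
  stopifnot(!is.null(colnames(mat)))
  signals <- tibble::tibble(
    patient_id = rep(patient_ids, each = ncol(mat)),
    sample_type = rep(sample_type, each = ncol(mat)),
    marker = rep(colnames(mat), times = nrow(mat)),
    signal = as.vector(t(mat))
  )
  upat <- !duplicated(patient_ids)
  patients <- tibble::tibble(
    patient_id = patient_ids[upat],
    diagnosis = diagnosis[upat],
    ...
  )
  if (!is.null(grading_group)) {
    patients$grading_group <- grading_group[upat]
  }
  samples <- tibble::tibble(
    patient_id = patient_ids, sample_type = sample_type,
    control_ok = control_ok
  )
  meth_cohort(signals, patients, panel = panel, samples = samples)
}

# paired cohort: every patient has a DRE and an FV sample
paired_cohort_from_matrices <- function(dre, fv, diagnosis, ...) {
  n <- nrow(dre)
  ids <- sprintf("P%02d", seq_len(n))
  cohort_from_matrix(
    rbind(dre, fv),
    diagnosis = c(diagnosis, diagnosis),
    sample_type = rep(c("DRE", "FV"), each = n),
    patient_ids = c(ids, ids),
    ...
  )
}
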