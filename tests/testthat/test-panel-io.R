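test_that("Cq transform maps no-amplification to 0 and subtracts from the ceiling", {
  expect_equal(transform_cq(NA_real_), 0)
  expect_equal(transform_cq(17), 15)
  expect_equal(transform_cq(32), 0)
  expect_equal(transform_cq(25), 7)
  expect_equal(transform_cq(c(NA, 17, 32, 25)), c(0, 15, 0, 7))
  # clamps past the ceiling rather than going negative
  expect_equal(transform_cq(40), 0)
  expect_equal(transform_cq(20, max_cycles = 35), 15)
})

test_that("Cq transform is strictly decreasing on (0, max_cycles] and clamps beyond", {
  cq <- seq(0.5, 32, by = 0.5)
  sig <- suppressWarnings(transform_cq(cq))
  expect_true(all(diff(sig) < 0))
  expect_true(all(suppressWarnings(transform_cq(seq(32, 45))) == 0))
})

test_that("Cq transform warns above the expected range and rejects invalid input", {
  expect_warning(transform_cq(16), "exceed 15")
  expect_silent(transform_cq(17))
  expect_error(transform_cq(-3), "finite and > 0")
  expect_error(transform_cq(Inf), "finite and > 0")
  expect_error(transform_cq("a"), "numeric")
  expect_error(transform_cq(20, max_cycles = 0), "positive")
})

test_that("cohorts round-trip through long and wide files exactly", {
  cohort <- generate_cohort(default_generator_config(seed = 11))
  for (layout in c("long", "wide")) {
    for (ext in c("csv", "tsv")) {
      path <- withr::local_tempfile(fileext = paste0(".", ext))
      write_cohort(cohort, path, layout = layout)
      back <- read_cohort(path, layout = layout, values = "signal")
      expect_identical(back$signals$signal, cohort$signals$signal)
      expect_identical(back$signals$marker, cohort$signals$marker)
    }
  }
})

test_that("Cq-layout files honour the blank/Undetermined no-amplification dialect", {
  panel <- mini_panel(3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,sample_type,marker,value",
    "P1,DRE,M1,Undetermined",
    "P1,DRE,M2,17",
    "P1,DRE,M3,"
  ), path)
  co <- read_cohort(path, layout = "long", values = "cq", panel = panel)
  expect_equal(co$signals$signal, c(0, 15, 0))
  # the same blanks are an error in a signal-layout file
  expect_error(
    read_cohort(path, layout = "long", values = "signal", panel = panel),
    "blank"
  )
})

test_that("file validation rejects marker mismatches and unknown sample types", {
  panel <- mini_panel(2)
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,sample_type,M1,MX", "P1,DRE,1,2"), wide)
  expect_error(
    read_cohort(wide, layout = "wide", values = "signal", panel = panel),
    "do not match the panel"
  )
  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,sample_type,marker,value",
    "P1,XX,M1,1", "P1,XX,M2,0"
  ), long)
  expect_error(
    read_cohort(long, layout = "long", values = "signal", panel = panel),
    "DRE"
  )
})

test_that("cohort construction enforces panel coverage, uniqueness and labels", {
  panel <- mini_panel(2)
  sig <- tibble::tibble(
    patient_id = c("P1", "P1"), sample_type = "DRE",
    marker = c("M1", "M2"), signal = c(1, 0)
  )
  pts <- tibble::tibble(patient_id = "P1", diagnosis = "case", grading_group = 1)
  expect_s3_class(meth_cohort(sig, pts, panel = panel), "meth_cohort")
  expect_error(
    meth_cohort(sig[c(1, 1, 2), ], pts, panel = panel),
    "Duplicated"
  )
  expect_error(
    meth_cohort(sig[1, ], pts, panel = panel),
    "does not cover the panel"
  )
  expect_error(
    meth_cohort(dplyr::mutate(sig, marker = c("M1", "MX")), pts, panel = panel),
    "not in the panel"
  )
  expect_error(
    meth_cohort(sig, dplyr::mutate(pts, diagnosis = "control"), panel = panel),
    "grading_group 0"
  )
  expect_error(
    meth_cohort(dplyr::mutate(sig, signal = c(-1, 0)), pts, panel = panel),
    "non-negative"
  )
})

test_that("follow-up reclassification flips flagged controls to cases at load", {
  panel <- mini_panel(2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,sample_type,marker,value",
    "P1,DRE,M1,1", "P1,DRE,M2,0",
    "P2,DRE,M1,0", "P2,DRE,M2,0"
  ), path)
  meta <- tibble::tibble(
    patient_id = c("P1", "P2"), diagnosis = c("control", "control"),
    capra_group = c(0L, 0L), followup_cancer = c(TRUE, FALSE)
  )
  co <- read_cohort(path, layout = "long", values = "signal", panel = panel,
    metadata = meta)
  expect_equal(co$patients$diagnosis, c("case", "control"))
  expect_true(is.na(co$patients$grading_group[1]))
  co_raw <- read_cohort(path, layout = "long", values = "signal",
    panel = panel, metadata = meta, apply_followup = FALSE)
  expect_equal(co_raw$patients$diagnosis, c("control", "control"))
})

test_that("QC filter removes samples failing the amplifiable-DNA control", {
  panel <- mini_panel(2)
  mat <- matrix(c(1, 0, 2, 3, 0, 0), 3, 2, byrow = TRUE,
    dimnames = list(NULL, panel))
  ok <- cohort_from_matrix(mat, diagnosis = rep("control", 3))
  res <- qc_filter(ok)
  expect_identical(res$cohort$signals, ok$signals)
  expect_equal(nrow(res$rejected), 0)

  one_bad <- cohort_from_matrix(mat, diagnosis = rep("control", 3),
    control_ok = c(TRUE, FALSE, TRUE))
  res <- qc_filter(one_bad)
  expect_equal(nrow(res$rejected), 1)
  expect_equal(res$rejected$patient_id, "P02")
  expect_equal(nrow(res$cohort$samples), 2)

  all_bad <- cohort_from_matrix(mat, diagnosis = rep("control", 3),
    control_ok = rep(FALSE, 3))
  expect_warning(res <- qc_filter(all_bad), "All samples failed")
  expect_equal(nrow(res$cohort$signals), 0)
  expect_equal(nrow(res$rejected), 3)
})
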