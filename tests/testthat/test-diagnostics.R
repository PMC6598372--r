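test_that("Wald intervals reproduce known printed values and stay untruncated", {
  ci <- wald_ci(28, 30)
  expect_equal(round_half_up(ci$low, 2), 0.84)
  expect_equal(round_half_up(ci$high, 2), 1.02)
  expect_gt(ci$high, 1) # deliberately not clamped

  ci <- wald_ci(29, 36)
  expect_equal(round_half_up(ci$low, 2), 0.68)
  expect_equal(round_half_up(ci$high, 2), 0.93)

  expect_equal(unlist(wald_ci(49, 49)[, c("low", "high")]),
    c(low = 1, high = 1))
  expect_equal(unlist(wald_ci(0, 36)[, c("low", "high")]),
    c(low = 0, high = 0))
  expect_error(wald_ci(0, 0), "n = 0")
  expect_error(wald_ci(5, 3), "0..n")
})

test_that("Wald interval is symmetric about p with width shrinking as 1/sqrt(n)", {
  for (k in c(3, 10, 17)) {
    ci <- wald_ci(k, 20)
    expect_equal(ci$estimate - ci$low, ci$high - ci$estimate)
  }
  w1 <- with(wald_ci(30, 100), high - low)
  w4 <- with(wald_ci(120, 400), high - low)
  expect_equal(w1 / w4, 2)
})

test_that("binary evaluation reproduces reported threshold rows", {
  # 29/36 cases positive, 37/49 controls negative
  dre <- evaluate_binary(
    rep(c(TRUE, FALSE), c(29, 7)),
    rep(c(TRUE, FALSE), c(12, 37))
  )
  expect_equal(round_half_up(dre$sensitivity, 2), 0.81)
  expect_equal(round_half_up(dre$specificity, 2), 0.76)
  expect_equal(dre$ppv, 29 / 41)
  expect_equal(round_half_up(dre$ppv, 2), 0.71)

  fv <- evaluate_binary(
    rep(c(TRUE, FALSE), c(28, 2)),
    rep(c(TRUE, FALSE), c(8, 27))
  )
  expect_equal(round_half_up(fv$sensitivity, 2), 0.93)
  expect_equal(fv$npv, 27 / 29)
  expect_equal(round_half_up(fv$npv, 2), 0.93)

  # no positives at all: PPV undefined, NPV is the negative fraction
  none <- evaluate_binary(rep(FALSE, 36), rep(FALSE, 49))
  expect_true(is.na(none$ppv))
  expect_equal(none$npv, 49 / 85)
  expect_equal(format_diagnostics(none)$ppv, "na")

  expect_error(evaluate_binary(logical(0), TRUE), "at least one")
})

test_that("binary evaluation agrees with a brute-force recount on random calls", {
  set.seed(7)
  for (i in 1:20) {
    cc <- sample(c(TRUE, FALSE), sample(2:40, 1), replace = TRUE)
    kk <- sample(c(TRUE, FALSE), sample(2:40, 1), replace = TRUE)
    row <- evaluate_binary(cc, kk)
    ref <- recount_2x2(cc, kk)
    expect_equal(
      c(row$tp, row$fn, row$fp, row$tn),
      unname(ref[c("tp", "fn", "fp", "tn")])
    )
    expect_equal(row$sensitivity, ref[["tp"]] / (ref[["tp"]] + ref[["fn"]]))
    expect_equal(row$specificity, ref[["tn"]] / (ref[["tn"]] + ref[["fp"]]))
    # rates recover integer counts before rounding
    expect_equal(row$sensitivity * row$n_cases, round(row$sensitivity * row$n_cases))
    expect_equal(row$specificity * row$n_controls, round(row$specificity * row$n_controls))
  }
})

test_that("the threshold sweep is monotone: sensitivity falls, specificity rises", {
  for (seed in c(3, 9)) {
    co <- generate_cohort(default_generator_config(seed = seed))
    for (st in c("DRE", "FV")) {
      sw <- threshold_sweep(co, st)
      expect_equal(nrow(sw), 32)
      expect_true(all(diff(sw$tp) <= 0)) # case positives non-increasing
      expect_true(all(diff(sw$tn) >= 0)) # control negatives non-decreasing
      expect_true(all(diff(sw$sensitivity) <= 1e-12))
      expect_true(all(diff(sw$specificity) >= -1e-12))
    }
  }
})

test_that("a single case with k positives yields a unit-step sensitivity curve", {
  sw <- sweep_from_scores(7, c(0, 3), panel_size = 10)
  expect_equal(sw$sensitivity, as.numeric(1:10 <= 7))
  expect_equal(sw$label[3], "3of10")
})

test_that("per-marker table calls each marker by bare positivity, in panel order", {
  panel <- mini_panel(3)
  # M1 separates perfectly; M2 never fires; M3 fires everywhere
  mat <- matrix(
    c(
      2, 0, 1,
      3, 0, 4,
      0, 0, 2,
      0, 0, 0.5
    ), 4, 3,
    byrow = TRUE, dimnames = list(NULL, panel)
  )
  co <- cohort_from_matrix(mat,
    diagnosis = c("case", "case", "control", "control"),
    grading_group = c(1, 1, 0, 0)
  )
  tab <- per_marker_table(co, "DRE")
  expect_equal(tab$label, panel)
  expect_equal(tab$sensitivity, c(1, 0, 1))
  expect_equal(tab$specificity, c(1, 1, 0))
  expect_equal(tab$ppv, c(1, NA, 0.5))
})

test_that("report formatting rounds half away from zero at two decimals", {
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(0.805, 2), 0.81)
  row <- evaluate_binary(rep(c(TRUE, FALSE), c(29, 7)),
    rep(c(TRUE, FALSE), c(12, 37)))
  fmt <- format_diagnostics(row)
  expect_equal(fmt$sens_ci, "(0.68, 0.93)")
  expect_equal(fmt$cases, "29/36")
})
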