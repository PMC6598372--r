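test_that("rank-sum test: identity gives p ~ 1, separation the minimal exact p", {
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1)
  sep <- wilcoxon_rank_sum(c(1, 2, 3), c(101, 102, 103))
  expect_equal(sep$method, "exact")
  expect_equal(sep$p_value, 0.1) # 2 / choose(6, 3)
  expect_error(wilcoxon_rank_sum(numeric(0), x), "non-empty")
})

test_that("rank-sum test is symmetric in its arguments", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(sample(3:15, 1))
    b <- rnorm(sample(3:15, 1))
    expect_equal(
      wilcoxon_rank_sum(a, b)$p_value,
      wilcoxon_rank_sum(b, a)$p_value
    )
  }
})

test_that("exact rank-sum p matches complete permutation enumeration at n = 6 vs 6", {
  set.seed(22)
  for (i in 1:8) {
    a <- round(rnorm(6), 6)
    b <- round(rnorm(6, mean = runif(1, -1, 1)), 6)
    got <- wilcoxon_rank_sum(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, perm_wilcoxon_p(a, b))
  }
})

test_that("paired t handles degenerate difference vectors explicitly", {
  zero <- paired_t(rep(0, 6))
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p_value, 1)
  const <- paired_t(c(1, 1, 1, 1))
  expect_equal(const$statistic, Inf)
  expect_equal(const$p_value, 0)
  expect_equal(const$mean_difference, 1)
  expect_error(paired_t(1), "at least 2")
})

test_that("paired t matches the textbook formula on a fixed vector", {
  d <- c(0.5, -0.2, 0.9, 1.1, 0.3)
  got <- paired_t(d)
  n <- length(d)
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t_ref <- m / (s / sqrt(n))
  expect_equal(got$statistic, t_ref)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_ref), n - 1))
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  expect_equal(got$conf_low, m - half)
  expect_equal(got$conf_high, m + half)
  expect_true(got$conf_low <= got$mean_difference &
    got$mean_difference <= got$conf_high)
  # sign flip negates t, keeps |t|
  expect_equal(paired_t(-d)$statistic, -t_ref)
})

test_that("paired analysis uses only dual-sample patients, oriented DRE minus FV", {
  panel <- mini_panel(3)
  set.seed(31)
  dre <- matrix(runif(30, 1, 10), 10, 3, dimnames = list(NULL, panel))
  co_same <- paired_cohort_from_matrices(dre, dre, rep("case", 10),
    grading_group = rep(1, 10))
  res <- paired_marker_analysis(co_same)
  expect_equal(nrow(res), 5) # 3 markers + n_positive + avg_methylation
  expect_true(all(res$mean_difference == 0))
  expect_true(all(res$n_pairs == 10))

  fv <- dre
  fv[, "M2"] <- pmax(dre[, "M2"] - 1, 0.01) # DRE recovers M2 better by ~1
  co_shift <- paired_cohort_from_matrices(dre, fv, rep("case", 10),
    grading_group = rep(1, 10))
  res <- paired_marker_analysis(co_shift)
  m2 <- res[res$label == "M2", ]
  expect_gt(m2$mean_difference, 0.9)
  expect_lt(m2$p_value, 0.01)
})

test_that("constructed DRE/FV shifts in a 58-pair cohort are recovered at p < 0.05", {
  set.seed(32)
  panel <- default_panel()
  shifted <- panel[c(3, 8, 14, 21, 30)]
  n <- 58
  base <- matrix(runif(n * 32, 0.5, 12), n, 32, dimnames = list(NULL, panel))
  noise <- matrix(rnorm(n * 32, 0, 0.3), n, 32)
  fv <- pmax(base + noise, 0)
  fv[, shifted] <- pmax(fv[, shifted] - 1.5, 0)
  co <- paired_cohort_from_matrices(base, fv,
    rep(c("case", "control"), c(26, 32)),
    grading_group = rep(c(1, 0), c(26, 32))
  )
  res <- paired_marker_analysis(co)
  markers_only <- res[res$label %in% panel, ]
  flagged <- markers_only$label[markers_only$p_value < 0.05]
  expect_true(all(shifted %in% flagged))
  # few false flags beyond the 5 real shifts at alpha = 0.05
  expect_lte(length(setdiff(flagged, shifted)), 4)
})

test_that("group summaries have ordered quartiles and sensible comparisons", {
  co <- generate_cohort(default_generator_config(seed = 41))
  for (stat in c("n_positive", "avg_methylation")) {
    gs <- group_summaries(co, stat, "DRE")
    s <- gs$summaries[gs$summaries$n > 0, ]
    expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
      s$median <= s$q3 & s$q3 <= s$max))
    expect_equal(
      s$n[s$group == "1+2"],
      sum(s$n[s$group %in% c("1", "2")])
    )
    expect_true(all(gs$tests$p_value >= 0 & gs$tests$p_value <= 1,
      na.rm = TRUE))
  }
})

test_that("an upward-shifted elevated-risk group separates from the low-risk group", {
  cfg <- default_generator_config(seed = 42, n_cases = 300, n_controls = 100,
    group2_shift = 1.5, fraction_paired = 0, fraction_dre_only = 1,
    fraction_fv_only = 0)
  gs <- group_summaries(generate_cohort(cfg), "n_positive", "DRE")
  s <- gs$summaries
  expect_gt(s$median[s$group == "2"], s$median[s$group == "1"])
  expect_lt(gs$tests$p_value[gs$tests$comparison == "1 vs 2"], 0.01)
})

test_that("identical samples give flat groups and p ~ 1 comparisons", {
  panel <- mini_panel(2)
  mat <- matrix(rep(c(2, 3), each = 12), 12, 2, dimnames = list(NULL, panel))
  co <- cohort_from_matrix(mat,
    diagnosis = rep(c("control", "case"), 6),
    grading_group = rep(c(0, 1, 0, 2), 3)
  )
  gs <- group_summaries(co, "avg_methylation", "DRE")
  expect_equal(unique(gs$summaries$median), 2.5)
  expect_true(all(gs$tests$p_value == 1))
})

test_that("the PSA outlier rule iterates removal of dominant maxima", {
  none <- psa_mean_with_outlier_rule(c(5, 6, 7))
  expect_equal(none$mean, 6)
  expect_equal(none$excluded, numeric(0))

  one <- psa_mean_with_outlier_rule(c(5, 6, 40))
  expect_equal(one$excluded, 40)
  expect_equal(one$mean, 5.5)

  two <- psa_mean_with_outlier_rule(c(3, 4, 30, 90))
  expect_equal(two$excluded, c(90, 30))
  expect_equal(two$mean, 3.5)

  # a maximum at exactly 2x the runner-up stays
  expect_equal(psa_mean_with_outlier_rule(c(5, 10))$excluded, numeric(0))
})

test_that("demographics summarise age exactly and dichotomise at inclusive boundaries", {
  panel <- mini_panel(2)
  mat <- matrix(1, 4, 2, dimnames = list(NULL, panel))
  co <- cohort_from_matrix(mat,
    diagnosis = c("case", "case", "control", "control"),
    grading_group = c(1, 2, 0, 0),
    age = c(60, 70, 62, 64),
    psa = c(5, 6, 4, 4.5),
    gleason = c(7, 8, NA, NA)
  )
  demo <- cohort_demographics(co)
  age_mean <- demo$cases[demo$variable == "age" & demo$statistic == "mean (sd)"]
  expect_equal(age_mean, sprintf("%.1f (%.1f)", 65, sd(c(60, 70))))
  gle7 <- demo$cases[demo$variable == "gleason" & demo$statistic == "<= 7"]
  expect_match(gle7, "^1 ") # boundary value 7 counts as low
  expect_equal(
    demo$cases[demo$variable == "patients"], "2"
  )
})
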