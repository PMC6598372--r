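#' Configuration for the synthetic-cohort generator
#'
#' Collects every knob of the generator into a validated object. The
#' generator emulates a two-arm urine screening cohort: each patient gets a
#' biopsy diagnosis, cases a CAPRA-based grading group, each patient one or
#' two urine samples (post-DRE and/or first-void), and each marker an
#' independent Bernoulli methylation call with a class- and sample-type-
#' conditional detection probability; positive calls get a signal magnitude
#' on the 0-15 transformed scale.
#'
#' @param rates Tibble with columns `marker`, `sample_type`, `p_case`,
#'   `p_control`: detection probability of each marker in cases and
#'   controls, per sample type. Must cover `panel` x \{DRE, FV\}.
#' @param panel Marker panel (defaults to the markers in `rates`).
#' @param n_cases,n_controls Number of case / control patients.
#' @param fraction_paired,fraction_dre_only,fraction_fv_only Probabilities
#'   that a patient contributes both sample types, only a post-DRE sample,
#'   or only a first-void sample; must sum to 1.
#' @param group2_fraction Proportion of cases in the elevated-risk grading
#'   group (CAPRA >= 3).
#' @param group2_shift Additive log-odds boost to every marker's detection
#'   probability for elevated-risk cases, encoding their higher cumulative
#'   methylation. 0 disables the group effect.
#' @param paired_agreement Probability that a paired patient's first-void
#'   call for a marker is copied from the post-DRE call rather than drawn
#'   independently, creating within-patient concordance.
#' @param burden_sd Standard deviation (log scale) of an optional
#'   per-patient lognormal "tumor burden" scalar multiplying all marker
#'   log-odds, inducing positive inter-marker correlation. 0 (default)
#'   keeps markers independent.
#' @param signal_min,signal_max Range of the uniform signal magnitude drawn
#'   for positive calls (half-open: signals are strictly positive).
#' @param signal_digits Decimal places signals are rounded to, so written
#'   cohorts round-trip exactly through decimal text.
#' @param psa_case,psa_control,age_case,age_control Length-2 numeric
#'   `c(mean, sd)` for the PSA (ng/mL) and age (years) normal draws.
#' @param seed Integer seed; the same configuration always generates the
#'   identical cohort.
#' @return Object of class `generator_config`.
#' @seealso [default_generator_config()] for defaults seeded from the
#'   bundled per-marker rates; [generate_cohort()].
#' @export
generator_config <- function(rates,
                             panel = unique(rates$marker),
                             n_cases = 42, n_controls = 52,
                             fraction_paired = 58 / 92,
                             fraction_dre_only = 27 / 92,
                             fraction_fv_only = 7 / 92,
                             group2_fraction = 18 / 33,
                             group2_shift = 1,
                             paired_agreement = 0.8,
                             burden_sd = 0,
                             signal_min = 0.5, signal_max = 15,
                             signal_digits = 3,
                             psa_case = c(7.1, 3.3),
                             psa_control = c(5.6, 2.7),
                             age_case = c(67.1, 7.1),
                             age_control = c(63.9, 7.6),
                             seed = 1L) {
  check_panel(panel)
  rates <- as_tibble(rates)
  need <- c("marker", "sample_type", "p_case", "p_control")
  if (!all(need %in% names(rates))) {
    abort(paste0("`rates` must have columns ", paste(need, collapse = ", ")))
  }
  check_sample_type(rates$sample_type)
  full <- tidyr::expand_grid(marker = panel, sample_type = c("DRE", "FV"))
  key <- function(d) paste(d$marker, d$sample_type)
  if (!setequal(key(rates), key(full)) || anyDuplicated(key(rates))) {
    abort("`rates` must cover every (panel marker, sample type) pair exactly once.")
  }
  probs <- c(rates$p_case, rates$p_control, paired_agreement, group2_fraction)
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].")
  }
  fr <- c(fraction_paired, fraction_dre_only, fraction_fv_only)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    abort("Sample-type fractions must be non-negative and sum to 1.")
  }
  if (n_cases < 1 || n_controls < 1) {
    abort("Need at least one case and one control patient.")
  }
  if (!(signal_min >= 0 && signal_max > signal_min)) {
    abort("Require 0 <= signal_min < signal_max.")
  }
  if (burden_sd < 0) abort("`burden_sd` must be >= 0.")
  structure(
    list(
      panel = panel,
      rates = dplyr::arrange(rates, match(.data$marker, panel), .data$sample_type),
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      fraction_paired = fraction_paired,
      fraction_dre_only = fraction_dre_only,
      fraction_fv_only = fraction_fv_only,
      group2_fraction = group2_fraction, group2_shift = group2_shift,
      paired_agreement = paired_agreement, burden_sd = burden_sd,
      signal_min = signal_min, signal_max = signal_max,
      signal_digits = as.integer(signal_digits),
      psa_case = psa_case, psa_control = psa_control,
      age_case = age_case, age_control = age_control,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d markers, %d cases + %d controls, seed %d\n",
    length(x$panel), x$n_cases, x$n_controls, x$seed
  ))
  invisible(x)
}

#' Default generator configuration seeded from the bundled marker rates
#'
#' The 13 markers with bundled detection counts ([study_marker_rates()])
#' get `p_case` equal to their observed per-sample-type sensitivity and
#' `p_control` equal to one minus their observed specificity. The 19 legacy
#' panel markers, whose per-marker rates are not public, get mid-range
#' defaults (`p_case` 0.5, `p_control` 0.15 for both sample types),
#' representative of the published per-marker sensitivity range 0.19-0.87
#' and false-positive range 0.00-0.54.
#'
#' @param seed Integer seed stored in the configuration.
#' @param ... Further arguments passed to [generator_config()] to override
#'   cohort-level defaults.
#' @return Object of class `generator_config` over [default_panel()].
#' @export
#' @examples
#' cfg <- default_generator_config(seed = 7)
#' generate_cohort(cfg)
default_generator_config <- function(seed = 1L, ...) {
  obs <- study_marker_rates() |>
    dplyr::transmute(
      marker = .data$marker, sample_type = .data$sample_type,
      p_case = .data$pos_cases / .data$n_cases,
      p_control = 1 - .data$neg_controls / .data$n_controls
    )
  legacy <- tidyr::expand_grid(
    marker = legacy_marker_names(), sample_type = c("DRE", "FV")
  ) |>
    dplyr::mutate(p_case = 0.5, p_control = 0.15)
  generator_config(
    rates = dplyr::bind_rows(obs, legacy),
    panel = default_panel(),
    seed = seed,
    ...
  )
}

#' Generate a synthetic urine methylation cohort
#'
#' Draws a full [meth_cohort()] from a [generator_config()]:
#' patients are assigned a diagnosis, cases a grading group, and each a
#' sample-type pattern; every marker call is Bernoulli with the configured
#' class/sample-type probability, boosted on the log-odds scale for
#' elevated-risk cases (and optionally by a per-patient burden scalar);
#' a paired patient's first-void call is copied from the post-DRE call with
#' probability `paired_agreement`, otherwise redrawn; positive calls get a
#' uniform signal magnitude in `(signal_min, signal_max]`, negative calls
#' are exactly 0; PSA and age come from truncated normal draws. The same
#' configuration (including its seed) always yields the identical cohort.
#'
#' @param config A [generator_config()].
#' @return A [meth_cohort()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_cases + cfg$n_controls
  ids <- sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))
  diagnosis <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  grading <- ifelse(
    diagnosis == "control", 0L,
    ifelse(runif(n) < cfg$group2_fraction, 2L, 1L)
  )
  kind <- sample(
    c("both", "DRE", "FV"), n,
    replace = TRUE,
    prob = c(cfg$fraction_paired, cfg$fraction_dre_only, cfg$fraction_fv_only)
  )
  has_dre <- kind %in% c("both", "DRE")
  has_fv <- kind %in% c("both", "FV")

  m <- length(cfg$panel)
  rate_of <- function(stype, col) {
    r <- dplyr::filter(cfg$rates, .data$sample_type == stype)
    setNames(r[[col]], r$marker)[cfg$panel]
  }
  # per-patient x marker probability matrices on the logit scale
  shift <- ifelse(!is.na(grading) & grading == 2L, cfg$group2_shift, 0)
  burden <- if (cfg$burden_sd > 0) exp(rnorm(n, 0, cfg$burden_sd)) else rep(1, n)
  prob_matrix <- function(stype) {
    p_case <- rate_of(stype, "p_case")
    p_ctrl <- rate_of(stype, "p_control")
    base <- outer(diagnosis == "case", p_case) +
      outer(diagnosis != "case", p_ctrl) # n x m
    # burden and shift are length n: column-major recycling applies them per row
    lo <- qlogis(base) * burden + shift
    p <- plogis(lo)
    p[base == 0] <- 0 # keep hard zeros/ones exact under shifts
    p[base == 1] <- 1
    p
  }
  p_dre <- prob_matrix("DRE")
  p_fv <- prob_matrix("FV")

  call_dre <- matrix(rbinom(n * m, 1L, p_dre), n, m)
  copy <- matrix(runif(n * m) < cfg$paired_agreement, n, m)
  redraw <- matrix(rbinom(n * m, 1L, p_fv), n, m)
  call_fv <- ifelse(kind == "both" & copy, call_dre, redraw)

  signal_for <- function(calls, keep) {
    # calls: n x m 0/1; keep: logical length n
    idx <- which(keep)
    long <- tibble(
      patient_id = rep(ids[idx], each = m),
      marker = rep(cfg$panel, times = length(idx)),
      call = as.vector(t(calls[idx, , drop = FALSE]))
    )
    mag <- round(
      runif(nrow(long), cfg$signal_min, cfg$signal_max),
      cfg$signal_digits
    )
    mag <- pmax(mag, 10^(-cfg$signal_digits)) # strictly positive after rounding
    long$signal <- ifelse(long$call == 1L, mag, 0)
    long$call <- NULL
    long
  }
  sig <- dplyr::bind_rows(
    dplyr::mutate(signal_for(call_dre, has_dre), sample_type = "DRE"),
    dplyr::mutate(signal_for(call_fv, has_fv), sample_type = "FV")
  )

  draw_trunc <- function(n, pars, lower, upper, digits) {
    x <- rnorm(n, pars[1], pars[2])
    round(pmin(pmax(x, lower), upper), digits)
  }
  is_case <- diagnosis == "case"
  psa <- numeric(n)
  psa[is_case] <- draw_trunc(sum(is_case), cfg$psa_case, 0.5, 60, 2)
  psa[!is_case] <- draw_trunc(sum(!is_case), cfg$psa_control, 0.5, 60, 2)
  age <- numeric(n)
  age[is_case] <- draw_trunc(sum(is_case), cfg$age_case, 40, 90, 0)
  age[!is_case] <- draw_trunc(sum(!is_case), cfg$age_control, 40, 90, 0)

  patients <- tibble(
    patient_id = ids, diagnosis = diagnosis,
    grading_group = grading, psa = psa, age = age
  )
  meth_cohort(sig, patients, panel = cfg$panel)
}
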