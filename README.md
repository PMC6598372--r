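# methpanel

Diagnostic evaluation of cumulative DNA-methylation biomarker panels
measured in urine DNA by semi-quantitative methylation-specific qPCR
(MS-qPCR), built for the prostate-cancer screening setting: urine is
collected either after a digital rectal exam (DRE) or as first-void (FV),
a panel of CpG-island markers is assayed on bisulfite-converted DNA, and
the question is whether the *number* of methylated markers in a sample
predicts a positive biopsy.

The package is written for analysts working with such panels: it is
tidyverse-native (data frames in, tibbles out, `ggplot2` `autoplot()`
methods, broom-style `tidy()`/`glance()`), and every stage — from raw Cq
values to the final report bundle — is an exported, pipeable function.

## The statistics at the core

* **Signal transform.** MS-qPCR quantification cycles are mapped to an
  increasing methylation signal, `signal = max(0, 32 − Cq)`, with
  no amplification scored 0, giving the expected working range 0–15.
* **Cumulative scoring.** A marker is *positive* when any methylation is
  detected (`signal > 0`, no magnitude cutoff). Each sample gets
  `n_positive` (the "n of 32" count) and `avg_methylation`
  (sum of all 32 signals ÷ 32).
* **Threshold sweep.** For every threshold t, a sample is called positive
  when `n_positive ≥ t`; the resulting 2×2 tables give sensitivity
  Se = TP/(TP+FN), specificity Sp = TN/(TN+FP), PPV and NPV at cohort
  prevalence, with unclamped Wald 95% intervals
  `p ± 1.96·√(p(1−p)/n)` (upper bounds above 1 are reported as printed).
* **ROC/AUC.** Empirical ROC over all unique score thresholds; AUC by the
  Mann–Whitney statistic with half-credit ties,
  `AUC = [#(case > control) + ½·#(case = control)] / (n₁·n₂)`,
  which equals the trapezoidal area under the tied ROC curve.
* **Group and paired comparisons.** Wilcoxon rank-sum across CAPRA-based
  grading groups (0 = negative biopsy, 1 = CAPRA ≤ 2, 2 = CAPRA ≥ 3), and
  paired t tests of DRE − FV differences within patients contributing both
  sample types.
* **Synthetic cohorts.** A seeded generator draws per-marker Bernoulli
  detection calls with class- and sample-type-conditional probabilities
  (defaults taken from the bundled per-marker rate table), so the whole
  pipeline is testable without any patient-level data.

## Worked example

```r
library(methpanel)
library(dplyr)

cohort <- generate_cohort(default_generator_config(seed = 1))
cohort
#> <meth_cohort> 32 markers, 154 samples (88 DRE, 66 FV),
#>               94 patients (42 cases / 52 controls)

score_samples(cohort) |> head(3)
#>   patient_id sample_type diagnosis grading_group n_positive avg_methylation
#> 1 P0001      DRE         case                  2         21            5.42
#> 2 P0002      DRE         case                  2         17            4.83
#> 3 P0003      DRE         case                  1         19            4.61

threshold_sweep(cohort, "DRE") |>
  filter(threshold == 10) |>
  format_diagnostics()
#>   label  sample_type cases sensitivity sens_ci      controls specificity ...
#> 1 10of32 DRE         37/37 1.00        (1.00, 1.00) 50/51    0.98        ...
```

Each sweep row is one referral rule: "recommend a biopsy at ≥ t of 32
methylated markers", with its 2×2 counts and metrics. (The synthetic
default cohort separates more sharply than a real one because markers are
drawn independently per patient; see the methods vignette.)

The bundled reference tables let you work with the published cumulative
counts of the original 85-DRE / 65-FV cohort directly:

```r
evaluate_binary(rep(c(TRUE, FALSE), c(29, 7)),    # 29/36 cases positive
                rep(c(FALSE, TRUE), c(37, 12)),   # 37/49 controls negative
                label = "10of32", sample_type = "DRE") |>
  format_diagnostics()
#>   label  ... cases sensitivity sens_ci      controls specificity spec_ci      ppv  npv
#> 1 10of32 ... 29/36 0.81        (0.68, 0.93) 37/49    0.76        (0.63, 0.88) 0.71 0.84

d <- reconstruct_study_distributions("DRE")
median(expand_counts(d$cases))     # 16 methylated markers (cases)
median(expand_counts(d$controls))  # 5  (controls)
auc_mann_whitney(expand_counts(d$cases), expand_counts(d$controls))
#> 0.8784014
```

So at the 10-of-32 referral threshold the DRE data give 81% sensitivity
and 76% specificity, and the count statistic separates cases from controls
with AUC ≈ 0.88.

## Command line

A thin wrapper over the same functions lives at
`inst/scripts/methpanel.R`:

```sh
Rscript inst/scripts/methpanel.R simulate --out sim --seed 1
Rscript inst/scripts/methpanel.R evaluate --cohort sim/cohort.csv \
    --metadata sim/patients.csv --out report
```

`evaluate` writes the per-marker table, the full threshold sweep, ROC
points, grading-group summaries, the paired DRE/FV analysis, demographics
and a JSON summary.
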