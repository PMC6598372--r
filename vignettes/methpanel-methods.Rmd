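---
title: "Methods: cumulative urine methylation panel diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative urine methylation panel diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

## The measurement model

Methylation-specific qPCR on bisulfite-converted urine DNA yields, per
sample and per CpG-island marker, a quantification cycle Cq (or no
amplification at all). `transform_cq()` maps this onto an increasing
scale: no amplification becomes 0, otherwise
`signal = max(0, max_cycles − Cq)` with a 32-cycle ceiling, so signals
run from 0 up to about 15 when Cq values bottom out near 17 cycles.
Signals above 15 are retained with a warning rather than clamped: a lower
Cq means more methylated template, and the stated range is an empirical
observation, not a physical bound.

A marker is **positive** whenever its signal exceeds 0. This deliberately
applies no magnitude cutoff: low-level signal may be genuine low-copy
methylation or incomplete-deamination artefact, and rather than arbitrate
per marker, the convention folds all potential false positives into the
observed per-marker rates and eliminates false negatives. Two sample-level
statistics follow:

* `n_positive` — the number of positive markers out of the panel
  (0–32 on the default panel), and
* `avg_methylation` — the sum of all panel signals divided by the **full**
  panel size, zero markers included. Dividing by 32 rather than by the
  number of detected markers keeps the statistic monotone in added signal
  and exactly 0 for a fully negative sample.

A referral rule at threshold t calls a sample positive when
`n_positive ≥ t` ("at least t of 32"). The at-least semantics make the
sweep cumulative: case-positive counts are non-increasing and
control-negative counts non-decreasing in t, which the tests assert on
every generated cohort.

## Diagnostic evaluation

`evaluate_binary()` reduces call vectors to a 2×2 table conditioned on
biopsy outcome. Sensitivity and specificity carry **Wald** 95% intervals,
`p ± z·√(p(1−p)/n)` with z fixed at 1.96, deliberately *not* truncated to
[0, 1]; at p = 0 or 1 the interval collapses to zero width. The fixed z
(rather than an inverse-normal call at arbitrary α) makes printed
two-decimal intervals exactly reproducible. PPV and NPV come directly
from the table at the cohort's own prevalence — no Bayes adjustment to an
external prevalence — and are reported as `"na"` when their denominator
is empty. Report tables round half away from zero at two decimals
(`round_half_up()`); all internal values stay at full precision.

One discrepancy is worth documenting: in the reference cohort's published
sweep, the NPVs printed for the DRE rows at thresholds 9 and 10 (0.84 and
0.85) are the transpose of what the direct formula gives (33/39 = 0.846
and 37/44 = 0.841). The package implements the direct formula and makes
no attempt to match those two cells.

## ROC and AUC

`auc_mann_whitney()` uses the Mann–Whitney convention with half-credit
ties. On integer counts ties are the norm, and half credit is exactly
what makes the pairwise statistic equal the trapezoidal area under the
empirical ROC drawn through every unique threshold (`roc_points()` checks
this to 1e−12 in the tests, against a literal double-loop oracle). The
implementation is rank-based (O(n log n)); the oracle stays quadratic and
independent.

`reconstruct_pmf()` closes the loop between published cumulative count
columns and these statistics: an at-or-above column S(t) inverts to a
per-score distribution via `pmf(c) = S(c) − S(c+1)` and
`pmf(0) = n − S(1)`. Applied to the bundled DRE columns
(`study_threshold_counts()`) this yields case counts supported on 3–31
with median 16, control counts on 0–17 with median 5, and a
count-statistic AUC of 1549.5/1764 ≈ 0.878. The same reconstruction for
FV gives a case median of 15.5 under this package's median convention
(mean of the central order statistics for even n) where the published
summary says 16 — the two central FV case values straddle 15 and 16 — so
desk-scale checks pin the DRE medians only.

## Group and paired comparisons

Grading groups follow CAPRA: 0 = negative biopsy, 1 = CAPRA ≤ 2,
2 = CAPRA ≥ 3, plus the combined group 1+2. `group_summaries()` reports
box-plot quantities — median, first/third quartiles by linear
interpolation (quantile type 7; no convention is fixed by the source
material, so one is fixed here to make hinge tests deterministic) — and
Wilcoxon rank-sum comparisons of 0 vs 1+2 and 1 vs 2. The rank-sum test
uses the exact distribution when both groups have ≤ 10 tie-free
observations and the tie-corrected normal approximation otherwise,
without continuity correction by default (a `correct` flag toggles it);
when every pooled value is tied the null variance vanishes and p = 1 is
returned. Cases reclassified on clinical follow-up (negative biopsy,
cancer diagnosed within two years) count as cases everywhere but carry no
CAPRA group, so they are excluded from the group contrasts.

`paired_marker_analysis()` uses only patients with both sample types and
fixes the orientation **DRE − FV**: positive mean differences mean better
recovery from post-DRE urine. Constant difference vectors (zero variance)
are reported as the infinite-t limit (p → 0) or, when identically zero,
t = 0 and p = 1, rather than erroring.

The case-PSA summary applies an iterated outlier rule: remove the maximum
while it exceeds twice the highest remaining value. Dichotomised
demographics use inclusive lower strata (Gleason ≤ 7, positive cores ≤ 3).

## The synthetic-cohort generator

`generate_cohort()` emulates the study conditions the analysis assumes:
42 cases and 52 controls; each patient contributes both sample types,
only DRE, or only FV with probabilities 58/92, 27/92 and 7/92 (the
analyzed reference cohort had 58 paired patients, 27 DRE-only and 7
FV-only after sample losses; applied to 94 patients these fractions give
~150 analyzable samples in expectation); each marker fires Bernoulli with
a class- and sample-type-conditional probability. The 13 markers with
bundled rates use their observed sensitivity as `p_case` and 1 −
specificity as `p_control`; the 19 legacy markers, whose per-marker rates
are not public, get mid-range defaults (0.5 / 0.15) chosen once to sit
inside the observed ranges (sensitivity 0.19–0.87, false-positive rate
0.00–0.54). Elevated-risk (group 2) cases get a +1 log-odds boost
(`group2_shift`), encoding their visibly higher cumulative methylation;
55% of cases are group 2, matching the reference DRE grading split
(18 of 33 graded cases). Positive signals are uniform on (0.5, 15] —
magnitudes only affect `avg_methylation`, so the default targets range
fidelity — rounded to 3 decimals so written cohorts round-trip through
decimal text bit-exactly. A paired patient's FV call copies the DRE call
with probability `paired_agreement = 0.8` (no quantitative DRE/FV
concordance is published; this is a flagged modeling choice), otherwise
it is redrawn independently. PSA and age are truncated normal draws at
the reference cohort's means and SDs.

**What the generator does not emulate.** Markers are independent across
the panel by default (no covariance structure is published). Real
patients share a latent tumor burden that correlates markers, widening
the count distributions: the reference count reconstruction spans 3–31 in
cases and 0–17 in controls, while independent draws concentrate near
their means. Consequently the default synthetic cohort separates classes
more sharply (count AUC ≈ 0.99) than the reference data (≈ 0.88), and its
10-of-32 row is better than the published one. Passing tests on synthetic
cohorts therefore validate the *pipeline* (rates, monotonicity,
reconstruction, pairing, determinism), not the clinical operating
characteristics. An optional per-patient lognormal burden scalar
(`burden_sd > 0`) multiplies all marker log-odds to induce such
correlation; it is off by default, matching the stated independence
assumption.

## Numerical and design choices

* No-amplification encodings: in signal-layout files the literal 0; in
  Cq-layout files an empty cell or `"Undetermined"`, mirroring qPCR
  export conventions. Blank cells in signal files are an error, not 0.
* Seeded determinism: a configuration (including its seed) always
  generates the byte-identical cohort; `run_simulate()` writes the exact
  configuration alongside the data as provenance.
* Probabilities of exactly 0 or 1 are preserved under log-odds shifts
  (they are fixed points of the logistic map).
* Thresholds are validated against the panel size; sweep labels are
  `"<t>of<panel size>"`.
* The sample-QC (imprinted-gene control) flag is supplied in metadata as
  a boolean; no Cq cutoff is invented for it.

## Problem sizes and limitations

The test suite runs generated cohorts at the study scale (~94 patients),
property checks over 200 random score distributions, exact rank-sum
enumeration up to 6 + 6 observations, and generator rate recovery at
10,000 samples per class within four binomial standard errors; the whole
suite completes in well under a minute. Quantities that require the
original per-sample records — the exact grading-group Wilcoxon p-values,
the PSA AUC, which five markers differ between DRE and FV, and which
statistic produced each published ROC endpoint — cannot be recomputed
from the printed cumulative tables alone; the package substitutes
synthetic-cohort property checks (shift recovery in the paired analysis,
PSA ROC plumbing) and leaves those numbers unasserted. No multivariable
PSA/age modeling is provided: the package evaluates urine methylation as
a standalone marker.
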