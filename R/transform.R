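#' Transform qPCR Cq values to methylation signals
#'
#' Converts quantification-cycle (Cq) values from methylation-specific qPCR
#' into an increasing methylation signal by subtracting each Cq from the
#' cycle ceiling: `signal = max(0, max_cycles - cq)`. A reaction with no
#' amplification (encoded as `NA`) maps to signal 0, so the scale runs from
#' 0 (no amplification) upwards; with the default 32-cycle ceiling and Cq
#' values down to 17 cycles the expected range is 0 to 15. Signals above 15
#' are kept (a lower Cq simply means more methylated template) but trigger a
#' warning because they fall outside the expected assay range.
#'
#' @param cq Numeric vector of Cq values in cycles. `NA` means the reaction
#'   never crossed threshold (no amplification). Values must be finite and
#'   strictly positive where present.
#' @param max_cycles Cycle ceiling subtracted from each Cq. Default 32, the
#'   run length of the assay protocol.
#' @return Numeric vector of non-negative methylation signals, same length
#'   as `cq`.
#' @export
#' @examples
#' transform_cq(c(NA, 17, 32, 25)) # 0, 15, 0, 7
transform_cq <- function(cq, max_cycles = 32) {
  if (!is.numeric(max_cycles) || length(max_cycles) != 1L ||
    !is.finite(max_cycles) || max_cycles <= 0) {
    abort("`max_cycles` must be a single positive number.")
  }
  if (!is.numeric(cq)) {
    abort("`cq` must be numeric (use NA for no amplification).")
  }
  present <- !is.na(cq)
  if (any(!is.finite(cq[present]) | cq[present] <= 0)) {
    abort("Cq values must be finite and > 0 (use NA for no amplification).")
  }
  signal <- ifelse(present, pmax(0, max_cycles - cq), 0)
  n_high <- sum(signal > 15)
  if (n_high > 0L) {
    warn(sprintf(
      "%d signal(s) exceed 15 (Cq < %s): outside the expected 0-15 assay range.",
      n_high, format(max_cycles - 15)
    ))
  }
  signal
}

#' Is a methylation signal positive?
#'
#' A marker is called methylated whenever any signal was detected
#' (`signal > 0`), with no magnitude cutoff: weak signals count the same as
#' strong ones, which deliberately folds potential low-level false positives
#' into the per-marker rates rather than introducing subjective thresholds.
#'
#' @param signal Numeric vector of non-negative methylation signals.
#' @return Logical vector, `TRUE` where the marker is methylated.
#' @export
#' @examples
#' is_positive(c(0, 0.1, 15)) # FALSE TRUE TRUE
is_positive <- function(signal) {
  if (!is.numeric(signal)) {
    abort("`signal` must be numeric.")
  }
  if (any(signal < 0, na.rm = TRUE)) {
    abort("Methylation signals must be non-negative.")
  }
  signal > 0
}
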