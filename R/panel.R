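#' The default 32-marker urine methylation panel
#'
#' The panel combines 13 CpG-island markers assayed in this package's
#' bundled reference tables (FRZB, GPR147, GPR62, GRASP, HOXA11as, HOXBAS3,
#' HOXCrcAS3, HOXD3c, HOXD4rc, HOXD8rc, KLK10, RASSF1, SLC16A5rc) with a
#' legacy panel of 19 markers validated earlier on the same cohort. Only six
#' of the legacy marker names are public (AOX1, GFRA2, NEUROG3, HOXD3,
#' HOXA7, CXCL14); the remaining 13 carry `LEGACY` placeholder names. Any
#' character vector of unique names can be used as a panel instead, so the
#' pipeline is not tied to this particular assay set.
#'
#' @return Character vector of 32 unique marker names.
#' @seealso [new_marker_names()] for the 13-marker subset with bundled
#'   per-marker detection rates.
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  c(new_marker_names(), legacy_marker_names())
}

#' The 13 markers with bundled per-marker detection rates
#'
#' @return Character vector of 13 marker names, in the order used by the
#'   bundled rate table (see [study_marker_rates()]).
#' @export
new_marker_names <- function() {
  c(
    "HOXA11as", "KLK10", "GPR147", "GPR62", "HOXD4rc", "HOXD3c", "FRZB",
    "GRASP", "HOXBAS3", "HOXCrcAS3", "HOXD8rc", "RASSF1", "SLC16A5rc"
  )
}

legacy_marker_names <- function() {
  c(
    "AOX1", "GFRA2", "NEUROG3", "HOXD3", "HOXA7", "CXCL14",
    sprintf("LEGACY%02d", 7:19)
  )
}

# validate a panel: non-empty, unique, non-missing names
check_panel <- function(panel, call = rlang::caller_env()) {
  if (!is.character(panel) || length(panel) == 0L) {
    abort("`panel` must be a non-empty character vector of marker names.",
      call = call
    )
  }
  if (anyNA(panel) || any(!nzchar(panel))) {
    abort("`panel` must not contain missing or empty marker names.", call = call)
  }
  if (anyDuplicated(panel)) {
    abort(
      paste0(
        "`panel` contains duplicated marker names: ",
        paste(unique(panel[duplicated(panel)]), collapse = ", ")
      ),
      call = call
    )
  }
  invisible(panel)
}

check_sample_type <- function(sample_type, call = rlang::caller_env()) {
  bad <- setdiff(unique(sample_type), c("DRE", "FV"))
  if (length(bad) > 0L) {
    abort(
      paste0(
        "`sample_type` must be \"DRE\" or \"FV\"; found: ",
        paste(bad, collapse = ", ")
      ),
      call = call
    )
  }
  invisible(sample_type)
}
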