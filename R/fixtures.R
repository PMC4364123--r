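#' Packaged study-table transcriptions
#'
#' The package ships verbatim transcriptions of the printed summary tables of
#' the reference two-pipeline cortical thickness study as CSV fixtures:
#'
#' * `"T1"` — cohort demographics (group sizes 69/37/27/52, MMSE, ApoE).
#' * `"T3"` — cross-sectional ROI contrasts (delta mean, sigma) per pipeline.
#' * `"T4"` — longitudinal (baseline to month 24) per-group ROI changes with
#'   the Tukey-Kramer pairwise significance flags (CTR-pMCI, CTR-AD,
#'   sMCI-pMCI, sMCI-AD).
#' * `"ROI28"` — the registry of the 28 Harvard-Oxford cortical regions used,
#'   with lobe groupings.
#' * `"QC23"` — the 23-item sulcus visual quality-control checklist. One
#'   checklist name (slot VI) is not recoverable from the available source
#'   text and is reconstructed; the `source` column marks it.
#'
#' Transcriptions are immutable records of the printed values, including
#' their apparent typos; they are used as oracle inputs, never re-derived.
#'
#' @param table_id one of `"T1"`, `"T3"`, `"T4"`, `"QC23"`, `"ROI28"`.
#' @return object of class `fixture_table`: list with `table_id` and
#'   `records` (a data frame).
#' @export
load_fixture_table <- function(table_id) {
  files <- c(T1 = "table1_demographics.csv",
             T3 = "table3_cross_sectional.csv",
             T4 = "table4_longitudinal.csv",
             QC23 = "qc_sulci.csv",
             ROI28 = "roi_registry.csv")
  if (!table_id %in% names(files)) {
    stop("unknown fixture table id: ", table_id)
  }
  path <- system.file("extdata", files[[table_id]], package = "corticompare",
                      mustWork = TRUE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(table_id = table_id, records = rec), class = "fixture_table")
}

#' @export
print.fixture_table <- function(x, ...) {
  cat(sprintf("fixture_table %s: %d records\n", x$table_id, nrow(x$records)))
  invisible(x)
}

#' The 28-region cortical ROI registry
#'
#' @return data frame with `roi_id` (Harvard-Oxford cortical index), `name`
#'   and `lobe` (Frontal/Parietal/Occipital/Limbic/Temporal), 28 rows.
#' @export
roi_registry <- function() {
  load_fixture_table("ROI28")$records
}
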