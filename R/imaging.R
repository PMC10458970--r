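#' Region-of-interest summary table
#'
#' Post-reconstruction ROI statistics for a single scan: mean activity
#' concentration per region plus the injection record needed to normalise
#' them into SUVs.
#'
#' @param rows Data frame with columns `roi_label`, `mean_Bq_per_mL`, and
#'   optionally `volume_mm3`.
#' @param injected_activity Injected activity in MBq (> 0).
#' @param injection_to_scan Delay from injection to scan start in seconds.
#' @param body_mass Animal body mass in g (> 0).
#' @param nuclide The injected [nuclide] (for decay correction of the dose).
#' @return An object of class `roi_table`.
#' @export
roi_table <- function(rows, injected_activity, injection_to_scan, body_mass,
                      nuclide) {
  rows <- as.data.frame(rows)
  if (!all(c("roi_label", "mean_Bq_per_mL") %in% names(rows)))
    abort_validation("rows needs columns roi_label, mean_Bq_per_mL")
  if (any(rows$mean_Bq_per_mL < 0))
    abort_validation("concentrations must be non-negative")
  if (anyDuplicated(rows$roi_label))
    abort_validation("duplicate roi_label")
  check_scalar_number(injected_activity, "injected_activity", positive = TRUE)
  check_scalar_number(injection_to_scan, "injection_to_scan", nonneg = TRUE)
  check_scalar_number(body_mass, "body_mass", positive = TRUE)
  stopifnot(inherits(nuclide, "nuclide"))
  structure(list(rows = rows,
                 injected_activity = injected_activity,
                 injection_to_scan = injection_to_scan,
                 body_mass = body_mass,
                 nuclide = nuclide),
            class = "roi_table")
}

#' Standardized uptake value of a region
#'
#' `SUV = concentration / (decay-corrected injected activity / body mass)`
#' with tissue density taken as 1 g/mL; the injected dose is decayed from
#' injection to scan start over the table's `injection_to_scan` delay.
#'
#' @param table An [roi_table].
#' @param roi_label Region label.
#' @return Dimensionless SUV.
#' @export
suv <- function(table, roi_label) {
  stopifnot(inherits(table, "roi_table"))
  i <- match(roi_label, table$rows$roi_label)
  if (is.na(i)) abort_validation(sprintf("no ROI labelled '%s'", roi_label))
  dose_bq <- decay_correct(table$injected_activity, table$nuclide,
                           table$injection_to_scan) * 1e6
  if (dose_bq <= 0) abort_validation("decayed injected dose is zero")
  conc <- table$rows$mean_Bq_per_mL[i]
  conc / (dose_bq / table$body_mass)
}

#' Standardized uptake value ratio
#'
#' Ratio of target to reference SUV (e.g. tumor to contralateral muscle).
#' Injected dose, body mass and decay cancel in the ratio, so the SUVR
#' equals the ratio of the raw concentrations.
#'
#' @param table An [roi_table].
#' @param target_label Target region label.
#' @param reference_label Reference region label.
#' @return Dimensionless SUVR.
#' @export
suvr <- function(table, target_label, reference_label) {
  s_ref <- suv(table, reference_label)
  if (s_ref <= 0) abort_validation("reference SUV is zero; ratio undefined")
  suv(table, target_label) / s_ref
}
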