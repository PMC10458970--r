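#' Read a production-campaign log
#'
#' Columns `run_id, target_mass_mg, beam_current_uA, time_h, eob_yield_MBq`;
#' `'#'` comments allowed.
#'
#' @param path CSV path.
#' @return Data frame with the columns above.
#' @export
load_campaign <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("run_id", "target_mass_mg", "beam_current_uA", "time_h",
            "eob_yield_MBq")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort_format(sprintf("campaign CSV is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  df
}

#' Read a titration series
#'
#' Accepts either a `dota_nmol` or a `dota_ug` column (micrograms are
#' converted with the packaged DOTA molar mass), plus `fraction_bound`.
#'
#' @param path CSV path.
#' @param spiked_activity Spiked activity per tube in MBq.
#' @return A [titration_series].
#' @export
load_titration <- function(path, spiked_activity) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#")
  if (!"fraction_bound" %in% names(df))
    abort_format("titration CSV needs a fraction_bound column")
  nmol <- if ("dota_nmol" %in% names(df)) df$dota_nmol
          else if ("dota_ug" %in% names(df)) dota_ug_to_nmol(df$dota_ug)
          else abort_format("titration CSV needs dota_nmol or dota_ug")
  titration_series(spiked_activity, nmol, df$fraction_bound)
}

#' Read a radio-TLC trace with its integration regions
#'
#' @param trace_path CSV with columns `position_mm, counts`.
#' @param regions_path CSV with columns `label, start_mm, end_mm`.
#' @return A [tlc_trace].
#' @export
load_tlc <- function(trace_path, regions_path) {
  for (p in c(trace_path, regions_path))
    if (!file.exists(p)) abort_format(sprintf("file not found: %s", p))
  tr <- utils::read.csv(trace_path, comment.char = "#")
  if (!all(c("position_mm", "counts") %in% names(tr)))
    abort_format("TLC CSV needs columns position_mm, counts")
  rg <- utils::read.csv(regions_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  tlc_trace(tr$position_mm, tr$counts, rg)
}

#' Read an ROI table with its YAML sidecar
#'
#' @param roi_path CSV with columns `roi_label, mean_Bq_per_mL` (and
#'   optionally `volume_mm3`).
#' @param meta_path YAML sidecar with keys `injected_MBq, delay_s,
#'   body_mass_g, nuclide`.
#' @param nuclides Named nuclide library, as from [load_nuclides].
#' @return An [roi_table].
#' @export
load_roi <- function(roi_path, meta_path, nuclides = load_nuclides()) {
  for (p in c(roi_path, meta_path))
    if (!file.exists(p)) abort_format(sprintf("file not found: %s", p))
  rows <- utils::read.csv(roi_path, comment.char = "#",
                          stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(meta_path)
  need <- c("injected_MBq", "delay_s", "body_mass_g", "nuclide")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    abort_format(sprintf("ROI sidecar is missing key(s): %s",
                         paste(missing, collapse = ", ")))
  n <- nuclides[[meta$nuclide]]
  if (is.null(n))
    abort_validation(sprintf("unknown nuclide '%s' in ROI sidecar", meta$nuclide))
  roi_table(rows, meta$injected_MBq, meta$delay_s, meta$body_mass_g, n)
}

#' Published single-energy cross-sections of the deuteron channels on calcium
#'
#' The packaged table of 9 MeV cross-sections for every (d,p), (d,n), (d,2n)
#' and (d,alpha) channel open on the calcium isotopes, used to pin synthetic
#' excitation functions and to enumerate co-production channels.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Data frame with columns `reaction_id, target_isotope, product,
#'   energy_MeV, sigma_mb`.
#' @export
load_reaction_pins <- function(path = system.file("extdata",
                                                  "reactions_ca_9MeV.csv",
                                                  package = "radioyield")) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
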