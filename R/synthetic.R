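#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the generator with defaults set to the study
#' conditions the pipeline is designed around: a 9 MeV deuteron beam on
#' enriched CaO pellets of 4.6–22.4 mg at 1–8 uA for roughly 8 h runs
#' (23-run campaign), a decade-spaced DOTA titration, and Gaussian TLC
#' peaks on a linear baseline. All randomness derives from `seed`.
#'
#' @param seed Integer seed; fixes every random draw.
#' @param campaign_size Number of production runs to simulate.
#' @param mass_range Target-mass range in mg.
#' @param current_range Beam-current range in uA.
#' @param duration_range Irradiation-duration range in hours.
#' @param incident_energy Beam energy E0 in MeV.
#' @param xs_threshold,xs_peak Reaction threshold and peak position in MeV
#'   of the synthetic excitation function.
#' @param xs_pin Optional `c(energy_MeV, sigma_mb)` the curve must pass
#'   through (e.g. a published single-energy cross-section).
#' @param stopping_a,stopping_p Power-law stopping model
#'   `S(E) = a * E^-p` (MeV cm^2/g with E in MeV); `p` must lie in (0, 2).
#' @param noise_cv Lognormal coefficient of variation on experimental yields.
#' @param true_bias Multiplicative bias of experiment relative to model
#'   (`experimental = model * (1 + true_bias) * noise`).
#' @param titration_true_ama Ground-truth apparent molar activity (MBq/nmol).
#' @param titration_spike Spiked activity per titration tube (MBq).
#' @param tlc_peaks Data frame `center_mm, width_mm, area` of TLC peaks;
#'   the last row is taken as the product peak.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             campaign_size = 23L,
                             mass_range = c(4.6, 22.4),
                             current_range = c(1, 8),
                             duration_range = c(7.5, 10),
                             incident_energy = 9,
                             xs_threshold = 0.5,
                             xs_peak = 8,
                             xs_pin = c(9, 104.73),
                             stopping_a = 260,
                             stopping_p = 0.8,
                             noise_cv = 0.1,
                             true_bias = -0.207,
                             titration_true_ama = 6,
                             titration_spike = 5,
                             tlc_peaks = data.frame(center_mm = c(15, 70),
                                                    width_mm = c(3, 3),
                                                    area = c(1000, 9000))) {
  if (xs_threshold >= xs_peak)
    abort_validation("xs_threshold must lie below xs_peak")
  if (stopping_p <= 0 || stopping_p >= 2)
    abort_validation("stopping_p must lie in (0, 2)")
  if (noise_cv < 0) abort_validation("noise_cv must be non-negative")
  structure(list(seed = as.integer(seed),
                 campaign_size = as.integer(campaign_size),
                 mass_range = mass_range, current_range = current_range,
                 duration_range = duration_range,
                 incident_energy = incident_energy,
                 xs_threshold = xs_threshold, xs_peak = xs_peak,
                 xs_pin = xs_pin,
                 stopping_a = stopping_a, stopping_p = stopping_p,
                 noise_cv = noise_cv, true_bias = true_bias,
                 titration_true_ama = titration_true_ama,
                 titration_spike = titration_spike,
                 tlc_peaks = tlc_peaks),
            class = "generator_config")
}

#' Generate a synthetic excitation function
#'
#' A smooth threshold-rise/peak/decline shape
#' `sigma(E) = A * u^2 * exp(2 * (1 - u))` with
#' `u = (E - threshold)/(peak - threshold)`, zero below threshold, sampled
#' densely so the piecewise-linear reader reproduces it closely. When
#' `xs_pin` is set the curve is rescaled to pass exactly through the pinned
#' `(energy, sigma)` point at a grid knot.
#'
#' @param cfg A [generator_config].
#' @param reaction_id,target_isotope,product Reaction metadata for the table.
#' @param Emax Upper end of the energy grid (MeV).
#' @param n_points Number of grid points.
#' @return A [cross_section_table].
#' @export
gen_excitation_function <- function(cfg, reaction_id = "Ca-42(d,n)Sc-43",
                                    target_isotope = "Ca-42",
                                    product = "Sc-43",
                                    Emax = 16, n_points = 400L) {
  stopifnot(inherits(cfg, "generator_config"))
  thr <- cfg$xs_threshold; pk <- cfg$xs_peak
  E <- seq(thr, Emax, length.out = n_points)
  if (!is.null(cfg$xs_pin)) E <- sort(unique(c(E, cfg$xs_pin[1])))
  shape <- function(E) {
    u <- pmax(E - thr, 0) / (pk - thr)
    u^2 * exp(2 * (1 - u))
  }
  amp <- if (!is.null(cfg$xs_pin)) cfg$xs_pin[2] / shape(cfg$xs_pin[1]) else 100
  cross_section_table(reaction_id, target_isotope, product, E, amp * shape(E))
}

#' Generate a synthetic stopping-power table
#'
#' Pure power law `S(E) = a * E^-p` sampled on a log-spaced grid, which the
#' log-log interpolation of [interp_stopping] reproduces exactly at every
#' interior energy.
#'
#' @param cfg A [generator_config].
#' @param material_id Material label.
#' @param Emin,Emax Grid range in MeV.
#' @param n_points Number of grid points.
#' @return A [stopping_power_table].
#' @export
gen_stopping_table <- function(cfg, material_id = "CaO",
                               Emin = 0.1, Emax = 20, n_points = 50L) {
  stopifnot(inherits(cfg, "generator_config"))
  E <- exp(seq(log(Emin), log(Emax), length.out = n_points))
  stopping_power_table(material_id, E, cfg$stopping_a * E^(-cfg$stopping_p))
}

#' Enriched calcium-oxide target material
#'
#' CaO with the isotopic breakdown of commercially enriched Ca-42 stock
#' (94.37% or 96.30% Ca-42 plus the minor natural isotopes), one reactive
#' Ca atom per formula unit. The certificate abundances are renormalised to
#' sum exactly to 1 (they are printed to limited precision).
#'
#' @param source `"ORNL"` (94.37% Ca-42) or `"Isoflex"` (96.30%).
#' @return A [material].
#' @export
enriched_cao_material <- function(source = c("ORNL", "Isoflex")) {
  source <- match.arg(source)
  iso <- c("Ca-40", "Ca-42", "Ca-43", "Ca-44", "Ca-46", "Ca-48")
  frac <- switch(source,
    ORNL    = c(5.01, 94.37, 0.06, 0.55, 0.001, 0.01),
    Isoflex = c(3.03, 96.30, 0.10, 0.55, 0.005, 0.02)) / 100
  frac <- frac / sum(frac)
  comp <- isotopic_composition(iso, frac)
  m_ca <- sum(c(39.9626, 41.9586, 42.9588, 43.9555, 45.9537, 47.9525) * frac)
  material("CaO", m_ca + 15.999, 1L, comp)
}

#' Generate pinned excitation functions for a whole reaction set
#'
#' One synthetic excitation function per row of a single-energy
#' cross-section table (as from [load_reaction_pins]), each sharing the
#' configured threshold/peak shape but rescaled to pass through its own
#' pinned point.
#'
#' @param cfg A [generator_config].
#' @param pins Data frame with columns `reaction_id, target_isotope,
#'   product, energy_MeV, sigma_mb`.
#' @return List of [cross_section_table] objects.
#' @export
gen_reaction_set <- function(cfg, pins = load_reaction_pins()) {
  lapply(seq_len(nrow(pins)), function(i) {
    cfg$xs_pin <- c(pins$energy_MeV[i], pins$sigma_mb[i])
    gen_excitation_function(cfg,
                            reaction_id = pins$reaction_id[i],
                            target_isotope = pins$target_isotope[i],
                            product = pins$product[i])
  })
}

#' Simulate a production campaign
#'
#' Draws irradiation setups uniformly inside the configured mass, current
#' and duration ranges, computes the model EOB yield for each, and corrupts
#' it into an "experimental" yield with a multiplicative bias and lognormal
#' noise (unit mean): `experimental = model * (1 + true_bias) * noise`.
#' The ground truth is returned alongside for recovery tests.
#'
#' @param cfg A [generator_config].
#' @param xs A [cross_section_table] (default: [gen_excitation_function]).
#' @param S A [stopping_power_table] (default: [gen_stopping_table]).
#' @param product The product [nuclide]; default Sc-43 from the packaged
#'   library.
#' @param mat Target [material]; default [enriched_cao_material()].
#' @return Data frame with columns `run_id, target_mass_mg, beam_current_uA,
#'   time_h, eob_yield_MBq, theoretical_MBq`; attributes `true_bias` and
#'   `noise_cv` record the ground truth.
#' @export
gen_campaign <- function(cfg, xs = gen_excitation_function(cfg),
                         S = gen_stopping_table(cfg),
                         product = load_nuclides()[["Sc-43"]],
                         mat = enriched_cao_material()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$campaign_size
  mass <- stats::runif(n, cfg$mass_range[1], cfg$mass_range[2])
  cur <- stats::runif(n, cfg$current_range[1], cfg$current_range[2])
  dur <- stats::runif(n, cfg$duration_range[1], cfg$duration_range[2])
  theo <- vapply(seq_len(n), function(i) {
    setup <- irradiation_setup(cur[i], cfg$incident_energy, dur[i] * 3600,
                               mass[i], mat)
    thick_target_yield(setup, xs, S, product)
  }, numeric(1))
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  noise <- if (cfg$noise_cv > 0)
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(1, n)
  out <- data.frame(run_id = sprintf("run%02d", seq_len(n)),
                    target_mass_mg = mass, beam_current_uA = cur,
                    time_h = dur,
                    eob_yield_MBq = theo * (1 + cfg$true_bias) * noise,
                    theoretical_MBq = theo,
                    stringsAsFactors = FALSE)
  attr(out, "true_bias") <- cfg$true_bias
  attr(out, "noise_cv") <- cfg$noise_cv
  out
}

#' Simulate a DOTA titration series
#'
#' Bound fraction follows a smooth step in the tube's labeling capacity
#' `c = dota_nmol * true_ama / spike`: `f = 1 / (1 + c^-h)` with a sharp
#' Hill-type exponent, so tubes with capacity well above 1 label completely
#' and tubes below barely at all. Amounts default to the decade series
#' 16.3, 1.63, 0.163, 0.0489, 0.00163 micrograms of DOTA.
#'
#' @param cfg A [generator_config].
#' @param dota_ug Chelator masses in micrograms.
#' @param hill Sharpness of the binding step.
#' @return A [titration_series]; attribute `true_ama` records the truth.
#' @export
gen_titration <- function(cfg,
                          dota_ug = c(16.3, 1.63, 0.163, 0.0489, 0.00163),
                          hill = 8) {
  stopifnot(inherits(cfg, "generator_config"))
  nmol <- dota_ug_to_nmol(dota_ug)
  capacity <- nmol * cfg$titration_true_ama / cfg$titration_spike
  f <- 1 / (1 + capacity^(-hill))
  s <- titration_series(cfg$titration_spike, nmol, pmin(pmax(f, 0), 1))
  attr(s, "true_ama") <- cfg$titration_true_ama
  s
}

#' Simulate a radio-TLC trace
#'
#' Gaussian peaks with prescribed areas on a linear baseline, Poisson
#' counting noise per channel. Integration regions are placed at
#' `center +/- 4 * width` around each peak; the last configured peak is
#' labelled `"product"`, the first `"origin"`.
#'
#' @param cfg A [generator_config].
#' @param lane_mm Lane length in mm.
#' @param step_mm Scan step in mm.
#' @param baseline `c(intercept, slope)` of the baseline in counts (per
#'   channel) at position 0 and per mm.
#' @param poisson Logical; add Poisson noise (default `TRUE`).
#' @return A [tlc_trace]; attribute `true_areas` records the peak areas.
#' @export
gen_tlc <- function(cfg, lane_mm = 100, step_mm = 0.5,
                    baseline = c(5, 0.05), poisson = TRUE) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 1L)
  pos <- seq(0, lane_mm, by = step_mm)
  mu <- baseline[1] + baseline[2] * pos
  pk <- cfg$tlc_peaks
  for (i in seq_len(nrow(pk))) {
    dens <- stats::dnorm(pos, pk$center_mm[i], pk$width_mm[i])
    mu <- mu + pk$area[i] * dens * step_mm
  }
  cts <- if (poisson) stats::rpois(length(mu), mu) else mu
  labels <- c("origin", rep("peak", max(0, nrow(pk) - 2)), "product")
  labels <- labels[seq_len(nrow(pk))]
  if (nrow(pk) == 1) labels <- "product"
  regions <- data.frame(label = labels,
                        start_mm = pk$center_mm - 4 * pk$width_mm,
                        end_mm = pk$center_mm + 4 * pk$width_mm)
  tr <- tlc_trace(pos, cts, regions)
  attr(tr, "true_areas") <- stats::setNames(pk$area, labels)
  tr
}

#' Simulate an ROI table from prescribed SUVs
#'
#' Constructs activity concentrations that reproduce a prescribed SUV per
#' region exactly under the package's SUV convention (dose decay-corrected
#' to scan start, density 1 g/mL), so SUV/SUVR computations round-trip.
#'
#' @param cfg A [generator_config].
#' @param suv_values Named numeric vector of prescribed SUVs per ROI label.
#' @param injected_activity Injected activity in MBq.
#' @param injection_to_scan Uptake delay in seconds (default 2 h).
#' @param body_mass Body mass in g.
#' @param nuclide Injected [nuclide]; default Sc-43 from the packaged
#'   library.
#' @return An [roi_table]; attribute `true_suv` records the prescription.
#' @export
gen_roi <- function(cfg,
                    suv_values = c(tumor = 6.458, muscle = 0.05),
                    injected_activity = 5.66,
                    injection_to_scan = 2 * 3600,
                    body_mass = 25,
                    nuclide = load_nuclides()[["Sc-43"]]) {
  stopifnot(inherits(cfg, "generator_config"))
  dose_bq <- decay_correct(injected_activity, nuclide, injection_to_scan) * 1e6
  conc <- unname(suv_values) * dose_bq / body_mass
  tbl <- roi_table(data.frame(roi_label = names(suv_values),
                              mean_Bq_per_mL = conc,
                              volume_mm3 = rep(100, length(suv_values)),
                              stringsAsFactors = FALSE),
                   injected_activity, injection_to_scan, body_mass, nuclide)
  attr(tbl, "true_suv") <- suv_values
  tbl
}

#' Write a complete synthetic fixture directory
#'
#' Emits every input file the pipeline readers consume — nuclide library,
#' excitation function, stopping powers, campaign log, titration, TLC trace
#' with regions, and ROI table with its YAML sidecar — plus `truth.yaml`
#' recording the generator's ground truth. Re-running with the same seed
#' reproduces the directory byte for byte.
#'
#' @param cfg A [generator_config].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(cfg, dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
    path
  }
  file.copy(system.file("extdata", "nuclides.csv", package = "radioyield"),
            file.path(dir, "nuclides.csv"), overwrite = TRUE)
  files <- c(files, file.path(dir, "nuclides.csv"))

  xs <- gen_excitation_function(cfg)
  w(data.frame(energy_MeV = xs$energy_MeV, sigma_mb = signif(xs$sigma_mb, 10)),
    sprintf("xs_%s.csv", gsub("[(),]", "_", xs$reaction_id)))
  S <- gen_stopping_table(cfg)
  w(data.frame(energy_MeV = signif(S$energy_MeV, 10),
               S_MeV_cm2_g = signif(S$S_MeV_cm2_g, 10)),
    sprintf("stopping_%s.csv", S$material_id))

  camp <- gen_campaign(cfg, xs = xs, S = S)
  w(data.frame(run_id = camp$run_id,
               target_mass_mg = signif(camp$target_mass_mg, 10),
               beam_current_uA = signif(camp$beam_current_uA, 10),
               time_h = signif(camp$time_h, 10),
               eob_yield_MBq = signif(camp$eob_yield_MBq, 10)),
    "campaign.csv")
  w(data.frame(run_id = camp$run_id,
               theoretical_MBq = signif(camp$theoretical_MBq, 10)),
    "theory.csv")

  tit <- gen_titration(cfg)
  w(data.frame(dota_nmol = signif(tit$points$dota_nmol, 10),
               fraction_bound = signif(tit$points$fraction_bound, 10)),
    "titration.csv")

  tr <- gen_tlc(cfg)
  w(data.frame(position_mm = tr$position_mm, counts = tr$counts), "tlc.csv")
  w(tr$regions, "regions.csv")

  roi <- gen_roi(cfg)
  w(roi$rows, "roi.csv")
  roi_meta <- list(injected_MBq = roi$injected_activity,
                   delay_s = roi$injection_to_scan,
                   body_mass_g = roi$body_mass,
                   nuclide = roi$nuclide$symbol)
  yaml::write_yaml(roi_meta, file.path(dir, "roi_meta.yaml"))
  files <- c(files, file.path(dir, "roi_meta.yaml"))

  truth <- list(seed = cfg$seed,
                true_bias = cfg$true_bias,
                noise_cv = cfg$noise_cv,
                titration_true_ama = cfg$titration_true_ama,
                titration_spike = cfg$titration_spike,
                tlc_true_areas = as.list(attr(tr, "true_areas")),
                roi_true_suv = as.list(attr(roi, "true_suv")))
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  files <- c(files, file.path(dir, "truth.yaml"))
  invisible(files)
}
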