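#' Describe an irradiation
#'
#' Bundles the beam and target parameters of a production run: current,
#' incident energy, duration, pellet mass and diameter, and the target
#' material. The areal density seen by the beam is derived as
#' `mass / (pi * (diameter/2)^2)` in g/cm^2 under the assumption that the
#' pellet fully intercepts a uniform beam.
#'
#' @param beam_current Beam current in microamps.
#' @param incident_energy Incident particle energy E0 in MeV.
#' @param duration Irradiation time in seconds.
#' @param target_mass Pellet mass in mg.
#' @param material A [material] describing the pellet.
#' @param pellet_diameter Pellet diameter in mm (default 7).
#' @param particle_charge Projectile charge state in elementary charges
#'   (deuteron = 1).
#' @return An object of class `irradiation_setup`.
#' @export
irradiation_setup <- function(beam_current, incident_energy, duration,
                              target_mass, material,
                              pellet_diameter = 7, particle_charge = 1) {
  check_scalar_number(beam_current, "beam_current", positive = TRUE)
  check_scalar_number(incident_energy, "incident_energy", positive = TRUE)
  check_scalar_number(duration, "duration", nonneg = TRUE)
  check_scalar_number(target_mass, "target_mass", positive = TRUE)
  check_scalar_number(pellet_diameter, "pellet_diameter", positive = TRUE)
  check_scalar_number(particle_charge, "particle_charge", positive = TRUE)
  stopifnot(inherits(material, "material"))
  structure(list(beam_current = beam_current,
                 incident_energy = incident_energy,
                 duration = duration,
                 target_mass = target_mass,
                 pellet_diameter = pellet_diameter,
                 particle_charge = particle_charge,
                 material = material),
            class = "irradiation_setup")
}

#' Areal density of an irradiation target
#'
#' @param setup An [irradiation_setup].
#' @return Areal density in g/cm^2.
#' @export
areal_density <- function(setup) {
  stopifnot(inherits(setup, "irradiation_setup"))
  mass_g <- setup$target_mass / 1000
  radius_cm <- setup$pellet_diameter / 2 / 10
  mass_g / (pi * radius_cm^2)
}

# Exact integral of dE/S(E) over [a, b] under the log-log interpolation
# model: each segment is a pure power law S = S1 * (E/E1)^k, whose inverse
# integrates in closed form. This is the particle range (in areal density
# units, g/cm^2) lost between energies a and b.
range_integral <- function(S, a, b) {
  if (b <= a) return(0)
  E <- S$energy_MeV
  Sv <- S$S_MeV_cm2_g
  total <- 0
  for (i in seq_len(length(E) - 1L)) {
    lo <- max(a, E[i]); hi <- min(b, E[i + 1L])
    if (hi <= lo) next
    k <- log(Sv[i + 1L] / Sv[i]) / log(E[i + 1L] / E[i])
    c0 <- E[i]^k / Sv[i]       # 1/S(E) = c0 * E^-k
    total <- total + if (abs(1 - k) < 1e-12) {
      c0 * log(hi / lo)
    } else {
      c0 * (hi^(1 - k) - lo^(1 - k)) / (1 - k)
    }
  }
  total
}

#' Beam exit energy after traversing the target
#'
#' Solves for the energy Ee at which the integral of dE/S(E) from Ee up to
#' the incident energy E0 equals the target's areal density: the continuous
#' slowing-down exit energy of the beam. Returns 0 when the target is thick
#' enough to stop the beam entirely (the residual range at the table's lower
#' edge is smaller than the areal density).
#'
#' @param E0 Incident energy in MeV; must lie inside the stopping table range.
#' @param rho_dx Areal density in g/cm^2.
#' @param S A [stopping_power_table].
#' @return Exit energy Ee in MeV (0 if the beam is stopped).
#' @export
exit_energy <- function(E0, rho_dx, S) {
  stopifnot(inherits(S, "stopping_power_table"))
  check_scalar_number(E0, "E0", positive = TRUE)
  check_scalar_number(rho_dx, "rho_dx", nonneg = TRUE)
  Emin <- S$energy_MeV[1]
  Emax <- S$energy_MeV[length(S$energy_MeV)]
  if (E0 > Emax || E0 < Emin)
    abort_range(sprintf("E0 = %.6g MeV outside stopping table range [%.6g, %.6g]",
                        E0, Emin, Emax))
  if (rho_dx == 0) return(E0)
  full <- range_integral(S, Emin, E0)
  if (full <= rho_dx) return(0)
  f <- function(Ee) range_integral(S, Ee, E0) - rho_dx
  stats::uniroot(f, lower = Emin, upper = E0, tol = 1e-9)$root
}

#' Saturation factor of activation
#'
#' The fraction `1 - exp(-lambda * t)` of the infinite-irradiation activity
#' reached after irradiating for time `t`; 0 at `t = 0`, 0.5 after one
#' half-life, approaching 1 from below.
#'
#' @param lambda Decay constant in 1/s (>= 0).
#' @param t Irradiation time in s (>= 0).
#' @return Fraction in `[0, 1)`.
#' @export
saturation_factor <- function(lambda, t) {
  check_scalar_number(lambda, "lambda", nonneg = TRUE)
  check_scalar_number(t, "t", nonneg = TRUE)
  -expm1(-lambda * t)
}

# Integral of sigma(E)/S(E) dE over [Elow, Ehigh], sigma in mb.
# Split at every knot of either table so each piece is smooth, then use
# adaptive quadrature per piece. Returns mb * MeV / (MeV cm^2 / g) = mb g/cm^2.
yield_energy_integral <- function(xs, S, Elow, Ehigh) {
  if (Ehigh <= Elow) return(0)
  # below the reaction threshold sigma is identically 0
  Elow <- max(Elow, xs$energy_MeV[1])
  if (Ehigh <= Elow) return(0)
  knots <- c(xs$energy_MeV, S$energy_MeV)
  knots <- sort(unique(c(Elow, Ehigh, knots[knots > Elow & knots < Ehigh])))
  f <- function(E) interp_sigma(xs, E) / interp_stopping(S, E)
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    piece <- stats::integrate(f, knots[i], knots[i + 1L],
                              rel.tol = 1e-10, subdivisions = 200L)
    total <- total + piece$value
  }
  total
}

#' Thick-target activation yield at end of bombardment
#'
#' Evaluates the thick-target yield equation
#' \deqn{A_{EOB} = \frac{N_A I_p f n}{M} (1 - e^{-\lambda t})
#'       \int_{E_e}^{E_0} \frac{\sigma(E)}{S(E)} dE}
#' where \eqn{I_p} is the particle flux (beam current over charge state),
#' \eqn{f} the atom fraction of the reaction's target isotope, \eqn{n} the
#' reactive atoms per formula unit, \eqn{M} the compound molar mass,
#' \eqn{\lambda} the product's decay constant, and \eqn{E_e} the exit energy
#' from [exit_energy]. Cross-sections are converted from millibarn to cm^2
#' internally; the result is the product activity at EOB in MBq.
#'
#' @param setup An [irradiation_setup].
#' @param reaction A [cross_section_table]; its `target_isotope` must appear
#'   in the material's isotopic composition.
#' @param S A [stopping_power_table] for the target material.
#' @param product The product [nuclide]; must be radioactive.
#' @return EOB activity in MBq.
#' @examples
#' comp <- isotopic_composition("Ca-42", 1)
#' mat <- material("Ca", 41.96, 1, comp)
#' xs <- cross_section_table("Ca-42(d,n)Sc-43", "Ca-42", "Sc-43",
#'                           c(0.5, 16), c(104.73, 104.73))
#' sp <- stopping_power_table("Ca", c(0.1, 20), c(500, 500))
#' sc43 <- nuclide("Sc-43", 43, 42.9612, half_life = 3.891 * 3600)
#' setup <- irradiation_setup(4, 9, 8 * 3600, 17, mat)
#' thick_target_yield(setup, xs, sp, sc43)
#' @export
thick_target_yield <- function(setup, reaction, S, product) {
  stopifnot(inherits(setup, "irradiation_setup"),
            inherits(reaction, "cross_section_table"),
            inherits(S, "stopping_power_table"),
            inherits(product, "nuclide"))
  if (!is_radioactive(product))
    abort_validation(sprintf("product '%s' is stable; no activity is produced",
                             product$symbol))
  f_iso <- atom_fraction_of(setup$material$composition, reaction$target_isotope)
  if (is.na(f_iso))
    abort_validation(sprintf(
      "target isotope '%s' absent from material composition",
      reaction$target_isotope))
  if (f_iso == 0) return(0)
  rho_dx <- areal_density(setup)
  Ee <- exit_energy(setup$incident_energy, rho_dx, S)
  Elow <- max(Ee, S$energy_MeV[1])
  integral <- yield_energy_integral(reaction, S, Elow, setup$incident_energy)
  particle_flux <- setup$beam_current * 1e-6 /
    (setup$particle_charge * ELEMENTARY_CHARGE)
  atoms_per_gram <- AVOGADRO * f_iso * setup$material$reactive_atoms_per_formula /
    setup$material$compound_molar_mass
  sat <- saturation_factor(product$decay_constant, setup$duration)
  a_bq <- particle_flux * atoms_per_gram * sat * integral * MB_TO_CM2
  a_bq / 1e6
}

#' Radionuclide inventory
#'
#' A set of (nuclide, activity) entries referenced to a common time,
#' measured in seconds relative to end of bombardment (0 = EOB).
#'
#' @param nuclides List of [nuclide] objects (one entry per nuclide).
#' @param activity_MBq Activities in MBq, non-negative, same length.
#' @param reference_time Reference time in seconds relative to EOB.
#' @return An object of class `radionuclide_inventory`.
#' @export
radionuclide_inventory <- function(nuclides, activity_MBq, reference_time = 0) {
  if (length(nuclides) != length(activity_MBq))
    abort_validation("nuclides and activities differ in length")
  if (any(activity_MBq < 0))
    abort_validation("activities must be non-negative")
  syms <- vapply(nuclides, function(n) n$symbol, character(1))
  if (anyDuplicated(syms))
    abort_validation("one entry per nuclide: duplicate symbol in inventory")
  structure(list(reference_time = reference_time,
                 nuclides = stats::setNames(nuclides, syms),
                 activity_MBq = stats::setNames(as.numeric(activity_MBq), syms)),
            class = "radionuclide_inventory")
}

#' @export
print.radionuclide_inventory <- function(x, ...) {
  cat(sprintf("<radionuclide_inventory> t_ref = %g s relative to EOB\n",
              x$reference_time))
  for (s in names(x$activity_MBq))
    cat(sprintf("  %-8s %12.6g MBq\n", s, x$activity_MBq[[s]]))
  invisible(x)
}

#' Co-production inventory across all open reaction channels
#'
#' Runs [thick_target_yield] for every supplied reaction and sums the
#' contributions per product nuclide (the same product can be fed by several
#' channels, e.g. (d,n) on one isotope and (d,2n) on its neighbour). A
#' reaction whose target isotope has zero abundance contributes nothing;
#' a stable product is listed with activity 0.
#'
#' @param setup An [irradiation_setup].
#' @param reactions List of [cross_section_table] objects. Every reaction's
#'   target isotope must appear in the material composition.
#' @param S A [stopping_power_table].
#' @param nuclides Named list of [nuclide] objects covering every product
#'   symbol (as from [load_nuclides]).
#' @return A [radionuclide_inventory] at EOB (`reference_time = 0`).
#' @export
coproduction_inventory <- function(setup, reactions, S, nuclides) {
  acts <- list()
  prods <- list()
  for (rx in reactions) {
    f_iso <- atom_fraction_of(setup$material$composition, rx$target_isotope)
    if (is.na(f_iso))
      abort_validation(sprintf(
        "target isotope '%s' absent from material composition",
        rx$target_isotope))
    prod <- nuclides[[rx$product]]
    if (is.null(prod))
      abort_validation(sprintf("unknown product nuclide '%s'", rx$product))
    a <- if (prod$stable || f_iso == 0) 0 else
      thick_target_yield(setup, rx, S, prod)
    key <- prod$symbol
    acts[[key]] <- (acts[[key]] %||% 0) + a
    prods[[key]] <- prod
  }
  radionuclide_inventory(unname(prods[names(acts)]),
                         unlist(acts, use.names = FALSE),
                         reference_time = 0)
}

#' Decay-correct an activity
#'
#' `activity * exp(-lambda * dt)`: `dt > 0` decays forward in time, `dt < 0`
#' back-corrects (e.g. a measurement taken after a cooling period referred
#' back to EOB).
#'
#' @param activity Activity in MBq (vectorised).
#' @param nuclide A [nuclide].
#' @param dt Time difference in seconds (may be negative).
#' @return Corrected activity in MBq.
#' @export
decay_correct <- function(activity, nuclide, dt) {
  stopifnot(inherits(nuclide, "nuclide"))
  activity * exp(-nuclide$decay_constant * dt)
}

#' Inventory activity fractions at a given time
#'
#' Decay-corrects every entry of an inventory to `at_time` and normalises to
#' fractions summing to 1 — the form in which radionuclidic purity is
#' quoted (e.g. percent Sc-46/Sc-47/Sc-48 decay-corrected to EOB).
#'
#' @param inv A [radionuclide_inventory].
#' @param at_time Target time in seconds relative to EOB.
#' @return Data frame with columns `symbol` and `fraction`.
#' @export
inventory_fractions <- function(inv, at_time = 0) {
  stopifnot(inherits(inv, "radionuclide_inventory"))
  dt <- at_time - inv$reference_time
  corrected <- mapply(function(n, a) decay_correct(a, n, dt),
                      inv$nuclides, inv$activity_MBq)
  total <- sum(corrected)
  if (total <= 0)
    abort_validation("all inventory activities are zero; fractions undefined")
  data.frame(symbol = names(inv$activity_MBq),
             fraction = as.numeric(corrected) / total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare experimental with theoretical yields
#'
#' Per-run percent difference, defined with the model in the denominator:
#' `100 * (experimental - theoretical) / theoretical`, and the mean absolute
#' percent difference as the headline statistic.
#'
#' @param runs Data frame with columns `run_id`, `experimental_MBq`,
#'   `theoretical_MBq`, and optionally `target_mass_mg` (carried through for
#'   difference-vs-mass plots).
#' @return An object of class `yield_comparison`: the per-run table with a
#'   `percent_difference` column plus `mean_abs_percent_difference`.
#' @export
compare_yields <- function(runs) {
  runs <- as.data.frame(runs)
  need <- c("run_id", "experimental_MBq", "theoretical_MBq")
  if (!all(need %in% names(runs)))
    abort_validation(sprintf("runs must have columns: %s",
                             paste(need, collapse = ", ")))
  bad <- which(runs$theoretical_MBq <= 0)
  if (length(bad))
    abort_validation(sprintf(
      "non-positive theoretical yield for run(s): %s",
      paste(runs$run_id[bad], collapse = ", ")))
  runs$percent_difference <-
    100 * (runs$experimental_MBq - runs$theoretical_MBq) / runs$theoretical_MBq
  structure(list(runs = runs,
                 mean_abs_percent_difference = mean(abs(runs$percent_difference))),
            class = "yield_comparison")
}

#' @export
print.yield_comparison <- function(x, ...) {
  cat(sprintf("<yield_comparison> %d runs, mean |%%diff| = %.2f%%\n",
              nrow(x$runs), x$mean_abs_percent_difference))
  print(utils::head(x$runs, 10))
  if (nrow(x$runs) > 10) cat(sprintf("  ... %d more runs\n", nrow(x$runs) - 10))
  invisible(x)
}
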