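#' Tabulated excitation function
#'
#' Holds a reaction's cross-section sigma(E) on an increasing energy grid,
#' the sigma(E) of the thick-target yield integral. Interpolation is
#' piecewise linear, zero below the first tabulated energy (reaction
#' threshold convention) and clamped to the last value above the grid.
#'
#' @param reaction_id Reaction label, e.g. `"Ca-42(d,n)Sc-43"`.
#' @param target_isotope Target isotope symbol, e.g. `"Ca-42"`.
#' @param product Product nuclide symbol, e.g. `"Sc-43"`.
#' @param energy_MeV Strictly increasing energies (MeV), at least 2.
#' @param sigma_mb Non-negative cross-sections (millibarn).
#' @return An object of class `cross_section_table`.
#' @export
cross_section_table <- function(reaction_id, target_isotope, product,
                                energy_MeV, sigma_mb) {
  if (length(energy_MeV) < 2L)
    abort_validation("cross-section table needs at least 2 points")
  if (length(sigma_mb) != length(energy_MeV))
    abort_validation("energy and sigma vectors differ in length")
  if (any(diff(energy_MeV) <= 0))
    abort_validation("cross-section energies must be strictly increasing")
  if (any(sigma_mb < 0))
    abort_validation("cross-sections must be non-negative")
  structure(list(reaction_id = reaction_id,
                 target_isotope = target_isotope,
                 product = product,
                 energy_MeV = as.numeric(energy_MeV),
                 sigma_mb = as.numeric(sigma_mb)),
            class = "cross_section_table")
}

#' @export
print.cross_section_table <- function(x, ...) {
  cat(sprintf("<cross_section_table> %s: %d points, %.3g-%.3g MeV, max %.4g mb\n",
              x$reaction_id, length(x$energy_MeV), min(x$energy_MeV),
              max(x$energy_MeV), max(x$sigma_mb)))
  invisible(x)
}

#' Interpolate a cross-section
#'
#' @param table A [cross_section_table].
#' @param E Energies in MeV (vectorised), all `>= 0`.
#' @return sigma in millibarn: linear between knots, 0 strictly below the
#'   first knot, the last tabulated value at and above the last knot.
#' @export
interp_sigma <- function(table, E) {
  stopifnot(inherits(table, "cross_section_table"))
  if (any(E < 0)) abort_validation("energies must be non-negative")
  y <- stats::approx(table$energy_MeV, table$sigma_mb, xout = E,
                     method = "linear", rule = 2)$y
  y[E < table$energy_MeV[1]] <- 0
  y
}

#' Tabulated mass stopping power
#'
#' S(E) of the projectile in the target material, in MeV cm^2/g, on an
#' increasing energy grid. Interpolation is linear in log-log space
#' (stopping power is near power-law over the few-MeV range of interest),
#' and extrapolation is refused: beam transport must stop at the table edge.
#'
#' @param material_id Material label, e.g. `"CaO"`.
#' @param energy_MeV Strictly increasing energies (MeV), positive.
#' @param S_MeV_cm2_g Strictly positive stopping powers.
#' @return An object of class `stopping_power_table`.
#' @export
stopping_power_table <- function(material_id, energy_MeV, S_MeV_cm2_g) {
  if (length(energy_MeV) < 2L)
    abort_validation("stopping-power table needs at least 2 points")
  if (length(S_MeV_cm2_g) != length(energy_MeV))
    abort_validation("energy and S vectors differ in length")
  if (any(energy_MeV <= 0))
    abort_validation("stopping-power energies must be strictly positive")
  if (any(diff(energy_MeV) <= 0))
    abort_validation("stopping-power energies must be strictly increasing")
  if (any(S_MeV_cm2_g <= 0))
    abort_validation("stopping power must be strictly positive")
  structure(list(material_id = material_id,
                 energy_MeV = as.numeric(energy_MeV),
                 S_MeV_cm2_g = as.numeric(S_MeV_cm2_g)),
            class = "stopping_power_table")
}

#' @export
print.stopping_power_table <- function(x, ...) {
  cat(sprintf("<stopping_power_table> %s: %d points, %.3g-%.3g MeV\n",
              x$material_id, length(x$energy_MeV), min(x$energy_MeV),
              max(x$energy_MeV)))
  invisible(x)
}

#' Interpolate a mass stopping power (log-log)
#'
#' @param table A [stopping_power_table].
#' @param E Energies in MeV (vectorised), inside the tabulated range.
#' @return S(E) in MeV cm^2/g.
#' @export
interp_stopping <- function(table, E) {
  stopifnot(inherits(table, "stopping_power_table"))
  lo <- table$energy_MeV[1]
  hi <- table$energy_MeV[length(table$energy_MeV)]
  if (any(E < lo) || any(E > hi))
    abort_range(sprintf(
      "energy outside stopping-power table range [%.6g, %.6g] MeV", lo, hi))
  exp(stats::approx(log(table$energy_MeV), log(table$S_MeV_cm2_g),
                    xout = log(E), method = "linear", rule = 1)$y)
}

#' Isotopic composition of a target element
#'
#' Atom fractions of each isotope of the reactive element (e.g. 94.37%
#' Ca-42 in an enriched calcium target plus its minor isotopes). Fractions
#' must sum to 1 within 1e-6.
#'
#' @param isotope Character vector of isotope symbols.
#' @param atom_fraction Numeric fractions in `[0, 1]`.
#' @return An object of class `isotopic_composition`.
#' @export
isotopic_composition <- function(isotope, atom_fraction) {
  if (length(isotope) != length(atom_fraction) || length(isotope) == 0)
    abort_validation("isotope and atom_fraction must be non-empty, equal length")
  if (any(atom_fraction < 0 | atom_fraction > 1))
    abort_validation("atom fractions must lie in [0, 1]")
  if (abs(sum(atom_fraction) - 1) > 1e-6)
    abort_validation(sprintf("atom fractions sum to %.8f, not 1",
                             sum(atom_fraction)))
  if (anyDuplicated(isotope))
    abort_validation("duplicate isotope in composition")
  structure(list(isotope = as.character(isotope),
                 atom_fraction = as.numeric(atom_fraction)),
            class = "isotopic_composition")
}

atom_fraction_of <- function(comp, isotope) {
  i <- match(isotope, comp$isotope)
  if (is.na(i)) return(NA_real_)
  comp$atom_fraction[i]
}

#' Target material description
#'
#' Generalises the atomic weight of the yield equation to compound targets:
#' a CaO pellet has one reactive Ca atom per formula unit of molar mass
#' ~57 g/mol, and the reactive element carries an isotopic composition
#' (enrichment). A pure-element target uses `reactive_atoms_per_formula = 1`
#' and the elemental molar mass, recovering the elemental form.
#'
#' @param formula_id Formula label, e.g. `"CaO"`.
#' @param compound_molar_mass Molar mass of the formula unit (g/mol).
#' @param reactive_atoms_per_formula Reactive atoms per formula unit (>= 1).
#' @param composition An [isotopic_composition] for the reactive element.
#' @return An object of class `material`.
#' @export
material <- function(formula_id, compound_molar_mass,
                     reactive_atoms_per_formula = 1L, composition) {
  check_scalar_number(compound_molar_mass, "compound_molar_mass", positive = TRUE)
  if (reactive_atoms_per_formula < 1)
    abort_validation("'reactive_atoms_per_formula' must be >= 1")
  stopifnot(inherits(composition, "isotopic_composition"))
  structure(list(formula_id = formula_id,
                 compound_molar_mass = compound_molar_mass,
                 reactive_atoms_per_formula = as.integer(reactive_atoms_per_formula),
                 composition = composition),
            class = "material")
}

#' Read an excitation function from CSV
#'
#' Columns `energy_MeV, sigma_mb`; `'#'` comments allowed. Reaction metadata
#' can be embedded in the filename convention `xs_<reaction>.csv` or passed
#' explicitly.
#'
#' @param path CSV path.
#' @param reaction_id,target_isotope,product Metadata; parsed from
#'   `reaction_id` of the form `"Ca-42(d,n)Sc-43"` when not given.
#' @return A [cross_section_table].
#' @export
load_cross_section <- function(path, reaction_id = NULL,
                               target_isotope = NULL, product = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("energy_MeV", "sigma_mb") %in% names(df)))
    abort_format("cross-section CSV needs columns energy_MeV, sigma_mb")
  if (is.null(reaction_id))
    reaction_id <- sub("^xs_", "", sub("\\.csv$", "", basename(path)))
  parsed <- parse_reaction_id(reaction_id)
  cross_section_table(reaction_id,
                      target_isotope %||% parsed$target,
                      product %||% parsed$product,
                      df$energy_MeV, df$sigma_mb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_reaction_id <- function(id) {
  m <- regmatches(id, regexec("^([^(]+)\\(([^)]+)\\)(.+)$", id))[[1]]
  if (length(m) == 4) return(list(target = m[2], product = m[4]))
  # filename-sanitised form, e.g. "Ca-42_d_n_Sc-43"
  m2 <- regmatches(id, regexec("^([A-Za-z]+-[0-9]+)_.*_([A-Za-z]+-[0-9]+)$",
                               id))[[1]]
  if (length(m2) == 3) return(list(target = m2[2], product = m2[3]))
  list(target = NA_character_, product = NA_character_)
}

#' Read a stopping-power table from CSV
#'
#' Columns `energy_MeV, S_MeV_cm2_g`; `'#'` comments allowed.
#'
#' @param path CSV path.
#' @param material_id Material label; defaults to the filename stem.
#' @return A [stopping_power_table].
#' @export
load_stopping_power <- function(path, material_id = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("energy_MeV", "S_MeV_cm2_g") %in% names(df)))
    abort_format("stopping-power CSV needs columns energy_MeV, S_MeV_cm2_g")
  if (is.null(material_id))
    material_id <- sub("^stopping_", "", sub("\\.csv$", "", basename(path)))
  stopping_power_table(material_id, df$energy_MeV, df$S_MeV_cm2_g)
}
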