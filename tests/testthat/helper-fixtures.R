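# Shared fixtures and independent oracles used across test files.

nuclide_lib <- load_nuclides()
sc43 <- nuclide_lib[["Sc-43"]]
sc47 <- nuclide_lib[["Sc-47"]]

pure_ca42_material <- function(molar_mass = 41.9586) {
  material("Ca", molar_mass, 1L, isotopic_composition("Ca-42", 1))
}

constant_stopping <- function(S = 500, Emin = 0.1, Emax = 20) {
  stopping_power_table("const", c(Emin, Emax), c(S, S))
}

constant_sigma_table <- function(sigma = 104.73, Emin = 0.5, Emax = 16) {
  cross_section_table("Ca-42(d,n)Sc-43", "Ca-42", "Sc-43",
                      c(Emin, Emax), c(sigma, sigma))
}

# Brute-force segment-search linear interpolator, independent of approx().
brute_interp_sigma <- function(tab, E) {
  vapply(E, function(e) {
    x <- tab$energy_MeV; y <- tab$sigma_mb
    if (e < x[1]) return(0)
    if (e >= x[length(x)]) return(y[length(y)])
    for (i in seq_len(length(x) - 1L)) {
      if (e >= x[i] && e <= x[i + 1L]) {
        w <- (e - x[i]) / (x[i + 1L] - x[i])
        return((1 - w) * y[i] + w * y[i + 1L])
      }
    }
    stop("unreachable")
  }, numeric(1))
}

# Independent re-implementation of log-log interpolation.
brute_interp_stopping <- function(tab, E) {
  x <- tab$energy_MeV; y <- tab$S_MeV_cm2_g
  vapply(E, function(e) {
    i <- max(which(x <= e))
    if (i == length(x)) return(y[i])
    k <- (log(y[i + 1L]) - log(y[i])) / (log(x[i + 1L]) - log(x[i]))
    exp(log(y[i]) + k * (log(e) - log(x[i])))
  }, numeric(1))
}

# Fine-grid transport oracle: accumulate areal density dE/S(E) on a dense
# energy grid downward from E0 and locate where it reaches rho_dx.
euler_exit_energy <- function(E0, rho_dx, S, n_steps = 1e6) {
  Emin <- S$energy_MeV[1]
  E <- seq(E0, Emin, length.out = n_steps + 1L)
  mid <- (E[-1] + E[-length(E)]) / 2
  dE <- -diff(E)
  thick <- cumsum(dE / interp_stopping(S, mid))
  if (thick[length(thick)] <= rho_dx) return(0)
  i <- which(thick >= rho_dx)[1]
  t0 <- if (i == 1) 0 else thick[i - 1L]
  w <- (rho_dx - t0) / (thick[i] - t0)
  E[i] * (1 - w) + E[i + 1L] * w
}

# 1e6-point trapezoid evaluation of the yield energy integral (mb g/cm^2).
trapezoid_yield_integral <- function(xs, S, Elow, Ehigh, n = 1e6) {
  E <- seq(Elow, Ehigh, length.out = n)
  f <- interp_sigma(xs, E) / interp_stopping(S, E)
  sum((f[-1] + f[-n]) / 2 * diff(E))
}
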