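test_that("nuclide construction derives the decay constant and flags stability", {
  n <- nuclide("Sc-43", 43, 42.9612, half_life = 14007.6)
  expect_equal(n$decay_constant, log(2) / 14007.6, tolerance = 1e-12)
  s <- nuclide("Sc-45", 45, 44.9559, stable = TRUE)
  expect_identical(s$decay_constant, 0)
  expect_error(nuclide("X-1", 1, 1, half_life = -5),
               class = "radioyield_validation_error")
})

test_that("the packaged nuclide library carries the published constants", {
  expect_equal(sc43$half_life, 3.891 * 3600, tolerance = 1e-6)
  expect_equal(sc47$half_life, 3.3492 * 86400, tolerance = 1e-6)
  # every radioactive entry satisfies lambda = ln2 / t_half to 1e-12
  for (n in nuclide_lib) {
    if (n$stable) {
      expect_identical(n$decay_constant, 0)
    } else {
      expect_equal(n$decay_constant * n$half_life, log(2), tolerance = 1e-12)
    }
    expect_true(all(n$emission_lines$energy_keV > 0))
  }
})

test_that("load_nuclides reports malformed files by name", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("symbol,mass_number,molar_mass_g_mol,stable,lines\nA,1,1,false,", p)
  expect_error(load_nuclides(p), "half_life_s",
               class = "radioyield_format_error")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("symbol,mass_number,molar_mass_g_mol,half_life_s,stable,lines",
               "A-1,1,1,-3,false,"), p2)
  expect_error(load_nuclides(p2), class = "radioyield_validation_error")
})

test_that("cross-section interpolation is linear, thresholded and clamped", {
  tab <- cross_section_table("r", "t", "p", c(8, 10), c(100, 120))
  expect_equal(interp_sigma(tab, 9), 110)
  expect_equal(interp_sigma(tab, 5), 0)        # below threshold
  expect_equal(interp_sigma(tab, 8), 100)      # knot reproduction
  expect_equal(interp_sigma(tab, 12), 120)     # clamped above range
  expect_error(cross_section_table("r", "t", "p", 8, 100),
               class = "radioyield_validation_error")
  expect_error(cross_section_table("r", "t", "p", c(10, 8), c(1, 1)),
               class = "radioyield_validation_error")
})

test_that("interp_sigma matches a brute-force segment-search interpolator", {
  cfg <- generator_config(seed = 11)
  tab <- gen_excitation_function(cfg)
  set.seed(42)
  E <- runif(1000, 0, 18)
  expect_equal(interp_sigma(tab, E), brute_interp_sigma(tab, E),
               tolerance = 1e-12)
})

test_that("stopping-power interpolation is log-log with no extrapolation", {
  tab <- stopping_power_table("pl", c(1, 100), c(1000, 10))  # exact E^-1
  expect_equal(interp_stopping(tab, 10), 100, tolerance = 1e-12)
  expect_equal(interp_stopping(tab, 1), 1000)   # knot
  expect_equal(interp_stopping(tab, 100), 10)   # knot
  expect_error(interp_stopping(tab, 0.5), class = "radioyield_range_error")
  expect_error(interp_stopping(tab, 101), class = "radioyield_range_error")
})

test_that("interp_stopping matches an independent re-implementation", {
  cfg <- generator_config(seed = 7)
  tab <- gen_stopping_table(cfg)
  set.seed(7)
  E <- runif(1000, min(tab$energy_MeV), max(tab$energy_MeV))
  expect_equal(interp_stopping(tab, E), brute_interp_stopping(tab, E),
               tolerance = 1e-12)
})

test_that("peak matching assigns the scandium signature lines", {
  res <- match_peaks(c(511.0, 372.8), nuclide_lib, tolerance = 2)
  expect_true("Sc-43" %in% res$symbol)
  expect_equal(res$n_matched[res$symbol == "Sc-43"], 2L)
  res47 <- match_peaks(159.3, list(sc43, sc47), tolerance = 1)
  expect_identical(res47$symbol, "Sc-47")
  expect_equal(nrow(match_peaks(numeric(0), nuclide_lib)), 0L)
  expect_error(match_peaks(511, list()), class = "radioyield_validation_error")
})

test_that("peak matching is invariant to permutations of peaks and library", {
  obs <- c(511.0, 372.8, 159.4, 1460.8)
  a <- match_peaks(obs, nuclide_lib, tolerance = 2)
  b <- match_peaks(rev(obs), rev(nuclide_lib), tolerance = 2)
  expect_identical(a$symbol, b$symbol)
  expect_identical(a$n_matched, b$n_matched)
})

test_that("isotopic compositions and materials are validated", {
  expect_error(isotopic_composition(c("a", "b"), c(0.6, 0.5)),
               class = "radioyield_validation_error")
  comp <- isotopic_composition(c("Ca-42", "Ca-40"), c(0.9437, 0.0563))
  expect_equal(sum(comp$atom_fraction), 1, tolerance = 1e-12)
  expect_error(material("CaO", -1, 1, comp),
               class = "radioyield_validation_error")
  expect_error(material("CaO", 57, 0, comp),
               class = "radioyield_validation_error")
})

test_that("cross-section and stopping CSV round-trips preserve the tables", {
  d <- withr::local_tempdir()
  cfg <- generator_config(seed = 3)
  write_fixtures(cfg, d)
  xs <- load_cross_section(file.path(d, "xs_Ca-42_d_n_Sc-43.csv"),
                           reaction_id = "Ca-42(d,n)Sc-43")
  expect_equal(xs$target_isotope, "Ca-42")
  expect_equal(xs$product, "Sc-43")
  expect_equal(interp_sigma(xs, 9), 104.73, tolerance = 1e-9)
  S <- load_stopping_power(file.path(d, "stopping_CaO.csv"))
  ref <- gen_stopping_table(cfg)
  expect_equal(S$S_MeV_cm2_g, ref$S_MeV_cm2_g, tolerance = 1e-9)
})
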