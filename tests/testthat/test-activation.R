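test_that("exit energy has the constant-S closed form and stopped-beam limit", {
  S <- constant_stopping(500)
  expect_equal(exit_energy(9, 0.004, S), 7, tolerance = 1e-9)
  expect_equal(exit_energy(9, 1, S), 0)            # beam fully stopped
  expect_equal(exit_energy(9, 0, S), 9)
  expect_error(exit_energy(25, 0.004, S), class = "radioyield_range_error")
})

test_that("exit energy agrees with a 1e6-step fine-grid transport oracle", {
  cfg <- generator_config(seed = 5)
  S <- gen_stopping_table(cfg)
  for (rho in c(0.005, 0.02, 0.05)) {
    expect_equal(exit_energy(9, rho, S), euler_exit_energy(9, rho, S),
                 tolerance = 1e-5)
  }
})

test_that("saturation factor identities hold", {
  expect_equal(saturation_factor(1e-4, 0), 0)
  expect_equal(saturation_factor(sc43$decay_constant,
                                 sc43$half_life), 0.5, tolerance = 1e-12)
  expect_equal(saturation_factor(sc43$decay_constant, 8 * 3600),
               1 - 2^(-8 / 3.891), tolerance = 1e-9)
  expect_error(saturation_factor(-1, 10), class = "radioyield_validation_error")
  # always in [0, 1): approaches 1 from below
  expect_true(saturation_factor(1, 30) < 1)
  expect_gt(saturation_factor(1, 30), 1 - 1e-12)
})

test_that("thick-target yield matches the closed form for constant sigma and S", {
  Sconst <- 500
  sigma <- 104.73
  S <- constant_stopping(Sconst)
  xs <- constant_sigma_table(sigma, Emin = 0.1, Emax = 20)
  mat <- pure_ca42_material()
  setup <- irradiation_setup(4, 9, 8 * 3600, 5, mat)
  rho <- areal_density(setup)
  Ee <- 9 - Sconst * rho   # 5 mg keeps the beam above the table's lower edge
  Ip <- 4e-6 / 1.602176634e-19
  closed <- 6.02214076e23 * Ip / 41.9586 *
    (1 - exp(-sc43$decay_constant * 8 * 3600)) *
    sigma * 1e-27 * (9 - Ee) / Sconst / 1e6
  expect_equal(thick_target_yield(setup, xs, S, sc43), closed,
               tolerance = 1e-9)
})

test_that("yield vanishes for null cross-section and zero beam time", {
  S <- constant_stopping(500)
  xs0 <- cross_section_table("r", "Ca-42", "Sc-43", c(0.1, 20), c(0, 0))
  mat <- pure_ca42_material()
  setup <- irradiation_setup(4, 9, 8 * 3600, 17, mat)
  expect_equal(thick_target_yield(setup, xs0, S, sc43), 0)
  setup0 <- irradiation_setup(4, 9, 0, 17, mat)
  xs <- constant_sigma_table()
  expect_equal(thick_target_yield(setup0, xs, S, sc43), 0)
  expect_error(thick_target_yield(setup, xs, S,
                                  nuclide_lib[["Ca-43"]]),
               class = "radioyield_validation_error")  # stable product
})

test_that("adaptive quadrature matches a 1e6-point trapezoid integral", {
  cfg <- generator_config(seed = 9)
  xs <- gen_excitation_function(cfg)
  S <- gen_stopping_table(cfg)
  Ee <- exit_energy(9, 0.04, S)
  ours <- radioyield:::yield_energy_integral(xs, S, Ee, 9)
  expect_equal(ours, trapezoid_yield_integral(xs, S, Ee, 9),
               tolerance = 1e-7)
})

test_that("yield is monotone in current, time and mass, and saturates with mass", {
  cfg <- generator_config(seed = 2)
  xs <- gen_excitation_function(cfg)
  S <- gen_stopping_table(cfg)
  mat <- enriched_cao_material()
  y <- function(cur, hrs, mass)
    thick_target_yield(irradiation_setup(cur, 9, hrs * 3600, mass, mat),
                       xs, S, sc43)
  expect_true(y(4, 8, 17) < y(8, 8, 17))
  expect_true(y(4, 4, 17) < y(4, 8, 17))
  expect_true(y(4, 8, 5) < y(4, 8, 17))
  # once the beam is stopped, extra mass changes nothing
  y_thick <- y(4, 8, 500)
  y_thicker <- y(4, 8, 1000)
  expect_equal(y_thicker, y_thick, tolerance = 1e-9)
})

test_that("thin-target limit converges to the integrand at E0", {
  cfg <- generator_config(seed = 2)
  xs <- gen_excitation_function(cfg)
  S <- gen_stopping_table(cfg)
  mat <- pure_ca42_material()
  sat <- saturation_factor(sc43$decay_constant, 8 * 3600)
  Ip <- 1e-6 / 1.602176634e-19
  limit <- 6.02214076e23 * Ip / 41.9586 * sat *
    interp_sigma(xs, 9) * 1e-27 / 1e6   # per unit areal density, sigma at E0
  masses <- c(0.05, 0.01)
  ratios <- vapply(masses, function(m) {
    setup <- irradiation_setup(1, 9, 8 * 3600, m, mat)
    thick_target_yield(setup, xs, S, sc43) / areal_density(setup)
  }, numeric(1))
  err <- abs(ratios - limit) / limit
  expect_true(err[2] < err[1])          # converging
  expect_lt(err[2], 5e-3)
})

test_that("decay correction satisfies half-life and inverse-pair identities", {
  expect_equal(decay_correct(1000, sc43, sc43$half_life), 500,
               tolerance = 1e-12)
  fwd <- decay_correct(123.4, sc47, 7200)
  expect_equal(decay_correct(fwd, sc47, -7200), 123.4, tolerance = 1e-12)
  # measurement after one hour of cooling, referred back to EOB
  expect_equal(decay_correct(962.0, sc43, -3600),
               962.0 * 2^(1 / 3.891), tolerance = 1e-9)
})

test_that("inventory fractions normalise, and common decay cancels", {
  inv1 <- radionuclide_inventory(list(sc47), 100)
  expect_equal(inventory_fractions(inv1)$fraction, 1)
  twin <- nuclide("Sc-47m", 47, 46.9524, half_life = sc47$half_life)
  inv2 <- radionuclide_inventory(list(sc47, twin), c(50, 50))
  fr <- inventory_fractions(inv2, at_time = 86400)
  expect_equal(fr$fraction, c(0.5, 0.5), tolerance = 1e-12)
  # sums to 1 and is invariant under uniform rescaling
  inv3 <- radionuclide_inventory(
    list(nuclide_lib[["Sc-46"]], sc47, nuclide_lib[["Sc-48"]]),
    c(0.9, 90, 8))
  f3 <- inventory_fractions(inv3, at_time = 3 * 86400)
  expect_equal(sum(f3$fraction), 1, tolerance = 1e-12)
  inv3s <- radionuclide_inventory(
    list(nuclide_lib[["Sc-46"]], sc47, nuclide_lib[["Sc-48"]]),
    c(0.9, 90, 8) * 17)
  expect_equal(inventory_fractions(inv3s, at_time = 3 * 86400)$fraction,
               f3$fraction, tolerance = 1e-12)
  inv0 <- radionuclide_inventory(list(sc47), 0)
  expect_error(inventory_fractions(inv0), class = "radioyield_validation_error")
})

test_that("co-production sums channels per product and zeroes stable products", {
  cfg <- generator_config(seed = 4)
  S <- gen_stopping_table(cfg)
  reactions <- gen_reaction_set(cfg)
  mat <- enriched_cao_material()
  setup <- irradiation_setup(4, 9, 8 * 3600, 17, mat)
  inv <- coproduction_inventory(setup, reactions, S, nuclide_lib)
  # stable products listed with zero activity
  expect_true(all(c("Ca-43", "Ca-44", "K-41", "Sc-45") %in%
                    names(inv$activity_MBq)))
  expect_equal(unname(inv$activity_MBq[["Ca-43"]]), 0)
  # Sc-43 fed by both (d,n) on Ca-42 and (d,2n) on Ca-43: additivity
  single <- vapply(reactions[vapply(reactions, function(r)
    r$product == "Sc-43", logical(1))], function(r)
      thick_target_yield(setup, r, S, sc43), numeric(1))
  expect_equal(unname(inv$activity_MBq[["Sc-43"]]), sum(single),
               tolerance = 1e-12)
  # a composition without a reaction's target isotope is rejected
  mat42 <- pure_ca42_material()
  setup42 <- irradiation_setup(4, 9, 8 * 3600, 17, mat42)
  expect_error(coproduction_inventory(setup42, reactions, S, nuclide_lib),
               class = "radioyield_validation_error")
})

test_that("zero-abundance channels contribute nothing", {
  cfg <- generator_config(seed = 4)
  S <- gen_stopping_table(cfg)
  reactions <- gen_reaction_set(cfg)
  iso <- c("Ca-40", "Ca-42", "Ca-43", "Ca-44", "Ca-46", "Ca-48")
  comp <- isotopic_composition(iso, c(0, 1, 0, 0, 0, 0))
  mat <- material("CaO", 57.96, 1L, comp)
  setup <- irradiation_setup(4, 9, 8 * 3600, 17, mat)
  inv <- coproduction_inventory(setup, reactions, S, nuclide_lib)
  ca42_products <- c("Ca-43", "Sc-43", "K-40")
  for (sym in names(inv$activity_MBq)) {
    if (!sym %in% ca42_products)
      expect_equal(unname(inv$activity_MBq[[sym]]), 0)
  }
  expect_gt(inv$activity_MBq[["Sc-43"]], 0)
})

test_that("yield comparison computes signed and mean-absolute differences", {
  runs <- data.frame(run_id = c("a", "b"),
                     experimental_MBq = c(100, 200),
                     theoretical_MBq = c(100, 200))
  cmp <- compare_yields(runs)
  expect_equal(cmp$runs$percent_difference, c(0, 0))
  expect_equal(cmp$mean_abs_percent_difference, 0)
  runs$theoretical_MBq <- 1.25 * runs$experimental_MBq
  cmp2 <- compare_yields(runs)
  expect_equal(cmp2$runs$percent_difference, c(-20, -20), tolerance = 1e-12)
  expect_equal(cmp2$mean_abs_percent_difference, 20, tolerance = 1e-12)
  # invariant to run order
  cmp3 <- compare_yields(runs[2:1, ])
  expect_equal(cmp3$mean_abs_percent_difference,
               cmp2$mean_abs_percent_difference)
  runs$theoretical_MBq[1] <- 0
  expect_error(compare_yields(runs), "a",
               class = "radioyield_validation_error")
})
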