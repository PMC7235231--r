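test_that("parse_formula computes molar mass and electron count", {
  si <- parse_formula("SiO2")
  expect_equal(si$A, 60.083, tolerance = 1e-4)
  expect_identical(si$Z, 30L)

  ker <- parse_formula("C175H102O9N4S2")
  expect_identical(ker$Z, 1284L)  # 175*6 + 102*1 + 9*8 + 4*7 + 2*16

  h <- parse_formula("H")
  expect_equal(h$A, 1.008)
  expect_identical(h$Z, 1L)

  # repeated symbols accumulate
  expect_equal(parse_formula("OCO")$A, parse_formula("CO2")$A)
})

test_that("parse_formula rejects malformed input", {
  expect_error(parse_formula("SiQ2"), "unknown element")
  expect_error(parse_formula("Xx2"), "unknown element")
  expect_error(parse_formula("C0H4"), "positive")
  expect_error(parse_formula("C-4"), "characters")
})

test_that("A/Z ratios reproduce the reference values", {
  expect_equal(a_over_z("SiO2", decimals = 1), 2)
  expect_equal(a_over_z("Fe2O3", decimals = 1), 2.1)
  expect_equal(a_over_z("Fe3O4", decimals = 1), 2.1)
  expect_equal(a_over_z("C175H102O9N4S2", decimals = 2), 1.92)
})

test_that("a_over_z is invariant under formula scaling", {
  expect_equal(a_over_z("SiO2"), a_over_z("Si2O4"), tolerance = 1e-12)
  expect_equal(a_over_z("C175H102O9N4S2"), a_over_z("C350H204O18N8S4"),
               tolerance = 1e-12)
})

test_that("delta <-> electron density conversion and round trips", {
  b <- beam_geometry(6.2)
  expect_equal(b$wavelength_angstrom, 12.398420 / 6.2)
  expect_equal(b$wavelength_angstrom * b$photon_energy_keV, 12.398420,
               tolerance = 1e-6)

  expect_identical(electron_density_from_delta(0, b), 0)
  # hand evaluation: 2*pi*1.435e-5 / (1.99974^2 * 2.8179403262e-5)
  expect_equal(electron_density_from_delta(1.435e-5, b), 0.800,
               tolerance = 2e-3)

  # round trip to 1e-12 relative
  for (d in c(1e-6, 1.435e-5, -2e-6, 5e-5)) {
    back <- delta_from_electron_density(electron_density_from_delta(d, b), b)
    expect_equal(back, d, tolerance = 1e-12)
  }
})

test_that("mass density conversion: examples, linearity, full round trip", {
  expect_identical(mass_density_from_electron_density(0, "SiO2"), 0)
  expect_equal(mass_density_from_electron_density(quartz_ne(), "SiO2"), 2.66,
               tolerance = 1e-10)
  expect_equal(mass_density_from_electron_density(1.6, "SiO2"),
               2 * mass_density_from_electron_density(0.8, "SiO2"),
               tolerance = 1e-12)

  # rho -> n_e -> delta -> n_e -> rho identity to 1e-10 relative
  b <- beam_geometry(6.2)
  comps <- c("SiO2", "Fe2O3", "Fe3O4", "C175H102O9N4S2", "CaCO3")
  set.seed(42)
  for (f in comps) {
    for (rho in stats::runif(5, 0.5, 6)) {
      ne <- electron_density_from_mass_density(rho, f)
      d <- delta_from_electron_density(ne, b)
      back <- mass_density_from_electron_density(
        electron_density_from_delta(d, b), f)
      expect_equal(back, rho, tolerance = 1e-10)
    }
  }
})

test_that("density_estimate propagates sigma linearly", {
  est <- density_estimate(0.8, 0.016, "SiO2")
  expect_equal(est$mass_density_sigma / est$mass_density, 0.016 / 0.8,
               tolerance = 1e-12)
  expect_error(density_estimate(0.8, -0.1, "SiO2"))
})

test_that("match_candidates reproduces the iron-oxide discrimination", {
  est <- density_estimate(
    electron_density_from_mass_density(4.82, "Fe2O3"),
    electron_density_from_mass_density(0.08, "Fe2O3"), "Fe2O3")
  cand <- data.frame(name = c("hematite", "magnetite", "maghemite"),
                     reference_density_g_cm3 = c(5.24, 5.18, 4.87))
  m <- match_candidates(est, cand)
  expect_identical(m$name[1], "maghemite")
  expect_true(m$within_k_sigma[1])
  expect_false(any(m$within_k_sigma[m$name %in% c("hematite", "magnetite")]))
})

test_that("match_candidates: quartz matrix, single candidate, invariances", {
  est <- density_estimate(
    electron_density_from_mass_density(2.68, "SiO2"),
    electron_density_from_mass_density(0.03, "SiO2"), "SiO2")
  m <- match_candidates(est, data.frame(name = "quartz",
                                        reference_density_g_cm3 = 2.66))
  expect_identical(m$name[1], "quartz")
  expect_true(m$within_k_sigma[1])

  # ranking is permutation-invariant
  cand <- mineral_candidates()
  set.seed(7)
  for (i in 1:5) {
    perm <- cand[sample(nrow(cand)), ]
    expect_identical(match_candidates(est, perm)$name,
                     match_candidates(est, cand)$name)
  }
  expect_error(match_candidates(est, cand[0, ]), "empty")
})

test_that("carbonaceous classification uses the maturity density windows", {
  expect_identical(classify_carbonaceous(1.39), "mature_kerogen")
  expect_identical(classify_carbonaceous(1.50), "mature_kerogen")
  expect_identical(classify_carbonaceous(2.30), "graphitic_or_amorphous")
  # boundaries inclusive for the kerogen interval, >2 strict for graphite
  expect_identical(classify_carbonaceous(1.19), "mature_kerogen")
  expect_identical(classify_carbonaceous(1.77), "mature_kerogen")
  expect_identical(classify_carbonaceous(2.0), "indeterminate")
  expect_identical(classify_carbonaceous(1.0), "indeterminate")
  est <- density_estimate(
    electron_density_from_mass_density(1.39, "C175H102O9N4S2"),
    0.01, "C175H102O9N4S2")
  expect_identical(classify_carbonaceous(est), "mature_kerogen")
})

test_that("bundled candidate table carries the reference densities", {
  cand <- mineral_candidates()
  get <- function(n) cand$reference_density_g_cm3[cand$name == n]
  expect_equal(get("quartz"), 2.66)
  expect_equal(get("hematite"), 5.24)
  expect_equal(get("magnetite"), 5.18)
  expect_equal(get("maghemite"), 4.87)
  ker <- cand[cand$name == "mature kerogen", ]
  expect_equal(c(ker$band_low, ker$band_high), c(1.25, 1.40))
})
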