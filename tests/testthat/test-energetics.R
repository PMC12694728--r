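test_that("thermal energy is RT in kcal/mol", {
  expect_equal(thermal_energy(298.15), 0.5925, tolerance = 1e-4)
  expect_equal(thermal_energy(2 * 310), 2 * thermal_energy(310), tolerance = 1e-12)
  expect_error(thermal_energy(0), "> 0")
})

test_that("small-potential conductance scales as expected", {
  g1 <- conductance_small_potential(1e-8, 1e-6)
  expect_equal(conductance_small_potential(1e-8, 2e-6), 2 * g1, tolerance = 1e-12)
  # condition ratios are independent of area (and the constant prefactor)
  r_small <- conductance_small_potential(1e-8, 1e-6, A_cm2 = 1e-4) /
    conductance_small_potential(2e-8, 1e-6, A_cm2 = 1e-4)
  r_big <- conductance_small_potential(1e-8, 1e-6, A_cm2 = 5) /
    conductance_small_potential(2e-8, 1e-6, A_cm2 = 5)
  expect_equal(r_small, r_big, tolerance = 1e-12)
})

test_that("barrier-free permeability is D/d and RT ln 10 is a decade", {
  expect_equal(permeability_from_barrier(1e-6, 4, 0), 1e-6 / 4e-7, tolerance = 1e-12)
  rt_ln10 <- thermal_energy(298.15) * log(10)
  expect_equal(permeability_from_barrier(1e-6, 4, 16 + rt_ln10),
               permeability_from_barrier(1e-6, 4, 16) / 10, tolerance = 1e-12)
})

test_that("permeability matches an independent arithmetic evaluation", {
  # independent constants-level oracle, evaluated from scratch
  R_kcal <- 1.987204259e-3
  oracle <- (1e-6 / (4 * 1e-7)) * exp(-16 / (R_kcal * 298.15))
  expect_equal(permeability_from_barrier(1e-6, 4, 16, 298.15), oracle,
               tolerance = 1e-12)
})

test_that("composition identity: conductance from barrier equals the direct form", {
  par <- energetics_params()
  R_J <- 8.314462618; F_C <- 96485.33212; R_kcal <- 1.987204259e-3
  P <- (par$diffusion_D_cm2_s / (par$thickness_d_nm * 1e-7)) *
    exp(-par$barrier_dG_kcal_mol / (R_kcal * par$temperature_K))
  g_direct <- F_C^2 * par$membrane_area_cm2 * P *
    (par$interfacial_conc_S_M / 1000) / (R_J * par$temperature_K)
  expect_equal(g0_from_barrier(par), g_direct, tolerance = 1e-12)
})

test_that("dielectric rescaling reproduces the printed barrier arithmetic", {
  expect_equal(rescale_barrier_dielectric(16, 2.1, 2.3), 14.6, tolerance = 0.05)
  expect_equal(rescale_barrier_dielectric(23.6, 2, 2.2), 21.5, tolerance = 0.1)
  expect_equal(rescale_barrier_dielectric(9, 2.1, 2.1), 9)
  # strictly decreasing in eps_new
  dg <- vapply(seq(1.5, 3, by = 0.1), function(e)
    rescale_barrier_dielectric(16, 2.1, e), numeric(1))
  expect_true(all(diff(dg) < 0))
})

test_that("Boltzmann fold changes match the printed estimates", {
  expect_equal(fold_change_from_barriers(23.6, 21.5), 35, tolerance = 3)
  expect_equal(fold_change_from_barriers(16, rescale_barrier_dielectric(16, 2.1, 2.3)),
               10, tolerance = 1)
  expect_equal(fold_change_from_barriers(5, 5), 1)
  # reciprocity
  expect_equal(fold_change_from_barriers(20, 17) * fold_change_from_barriers(17, 20),
               1, tolerance = 1e-12)
  # fold change > 1 iff the barrier decreased
  expect_gt(fold_change_from_barriers(16, 14.6), 1)
  expect_lt(fold_change_from_barriers(14.6, 16), 1)
})

test_that("Born energy follows its closed form and scaling laws", {
  # independent CODATA-constants oracle
  e <- 1.602176634e-19; NA_ <- 6.02214076e23; eps0 <- 8.8541878128e-12
  oracle <- e^2 * NA_ / (8 * pi * eps0 * 0.2e-9) * (1 / 2 - 1 / 78) / 4184
  expect_equal(born_energy(1, 0.2, 2, 78), oracle, tolerance = 1e-9)
  expect_equal(born_energy(1, 0.4, 2, 78), born_energy(1, 0.2, 2, 78) / 2,
               tolerance = 1e-12)
  expect_equal(born_energy(2, 0.2, 2, 78), 4 * born_energy(1, 0.2, 2, 78),
               tolerance = 1e-12)
  expect_equal(born_energy(1, 0.2, 40, 40), 0)
  expect_error(born_energy(1, -0.1, 2), "> 0")
})

test_that("Born scaling with mass is the inverse cube root", {
  expect_equal(born_scaling_from_mass(8), 0.5, tolerance = 1e-12)
  expect_equal(born_scaling_from_mass(1), 1)
  expect_equal(born_scaling_from_mass(4.3), 4.3^(-1 / 3), tolerance = 1e-12)
  expect_equal(born_scaling_from_mass(4.3), 0.615, tolerance = 1e-3)
})

test_that("dipole energy converts zF*phi to kcal/mol with the right sign", {
  expect_equal(dipole_energy(1, 250), 5.77, tolerance = 0.01)
  expect_equal(dipole_energy(-1, 250), -dipole_energy(1, 250))
  expect_equal(dipole_energy(1, 0), 0)
})

test_that("weak-acid speciation reproduces Henderson-Hasselbalch", {
  expect_equal(round(100 * charged_fraction(5.0, 6.1, "acid")), 7)
  expect_equal(round(100 * charged_fraction(7.4, 6.1, "acid")), 95)
  expect_equal(charged_fraction(6.1, 6.1, "acid"), 0.5)
  expect_equal(charged_fraction(6.1, 6.1, "base"), 0.5)
  # acid charged fraction strictly increasing in pH
  f <- vapply(seq(3, 10, by = 0.5), charged_fraction, numeric(1), pKa = 6.1,
              kind = "acid")
  expect_true(all(diff(f) > 0))
})

test_that("Nernst potential matches the 10-fold gradient benchmark", {
  expect_equal(nernst_potential(0.150, 0.015), -59.2, tolerance = 0.05)
  expect_equal(nernst_potential(0.1, 0.1), 0)
  expect_equal(nernst_potential(0.150, 0.015, z = 2),
               nernst_potential(0.150, 0.015) / 2, tolerance = 1e-12)
})

test_that("GHK reduces to Nernst for a single permeant ion", {
  one <- data.frame(z = 1, P = 3.3, c_side1 = 0.150, c_side2 = 0.015)
  expect_equal(ghk_potential(one), nernst_potential(0.150, 0.015),
               tolerance = 1e-9)
  anion <- data.frame(z = -1, P = 2, c_side1 = 0.150, c_side2 = 0.015)
  expect_equal(ghk_potential(anion), nernst_potential(0.150, 0.015, z = -1),
               tolerance = 1e-9)
})

test_that("GHK is 0 for symmetric solutions and tracks the dominant ion", {
  ions <- data.frame(z = c(1, -1), P = c(1, 5),
                     c_side1 = c(0.1, 0.1), c_side2 = c(0.1, 0.1))
  expect_equal(ghk_potential(ions), 0)
  # proton permeability advantage of ~6e6 over Na+ pins V_r near the H+ Nernst value
  ions <- data.frame(z = c(1, 1), P = c(6e6, 1),
                     c_side1 = c(1e-5, 0.015), c_side2 = c(1e-7, 0.015))
  expect_lt(abs(ghk_potential(ions) - nernst_potential(1e-5, 1e-7)), 1)
})

test_that("GHK input validation", {
  expect_error(ghk_potential(data.frame()), "at least one")
  expect_error(ghk_potential(data.frame(z = 2, P = 1, c_side1 = 1, c_side2 = 1)),
               "monovalent")
})

test_that("barrier decomposition totals its components", {
  bd <- barrier_decomposition(10, 5.77, 0.3)
  expect_equal(bd$dG_total, 16.07, tolerance = 1e-9)
})
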