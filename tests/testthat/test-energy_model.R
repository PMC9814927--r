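# Lattice-energy model: exp-6 lattice sums, Ewald electrostatics,
# close-contact rule, enthalpy.

test_that("null force field and zero charges give exactly zero energy", {
  at <- rigid_molecule("Ar", matrix(0, 1, 3), name = "Ar")
  s <- crystal_structure(lattice(6, 7, 8, 90, 100, 90), list(Ar = at),
                         list(placement("Ar", c(0.2, 0.3, 0.4))))
  ff <- force_field("Ar", A = 0, B = 1, C = 0)
  expect_identical(lattice_energy(s, ff), 0)
})

test_that("dispersion-only lattice sum matches the brute-force image sum", {
  at <- rigid_molecule("Ar", matrix(0, 1, 3), name = "Ar")
  ff <- force_field("Ar", A = 0, B = 1, C = 100)
  es <- energy_settings(taper_width = 0) # hard cutoff: exact sum comparison
  for (a in c(5.2, 7.1)) {
    lat <- lattice(a, a, a)
    s <- crystal_structure(lat, list(Ar = at), list(placement("Ar", c(0, 0, 0))))
    expect_equal(lattice_energy(s, ff, es), oracle_r6_sum(lat, 100, 15),
                 tolerance = 1e-10)
  }
})

test_that("low-density dispersion sum matches a triple-loop oracle at 3x cutoff", {
  # cell sparse enough that the tail beyond the 15 A cutoff is < 1e-5
  at <- rigid_molecule("Ar", matrix(0, 1, 3), name = "Ar")
  ff <- force_field("Ar", A = 0, B = 1, C = 100)
  es <- energy_settings(taper_width = 0)
  lat <- lattice(20, 20, 20)
  s <- crystal_structure(lat, list(Ar = at), list(placement("Ar", c(0, 0, 0))))
  expect_equal(lattice_energy(s, ff, es), oracle_r6_sum(lat, 100, 45),
               tolerance = 1e-5)
})

test_that("Ewald agrees with the direct image sum on a zero-dipole charge toy", {
  s <- charge_toy(40)
  ff <- force_field("C", A = 0, B = 1, C = 0)
  e <- lattice_energy(s, ff, energy_settings(), components = TRUE)
  elec <- attr(e, "components")[["elec"]]
  direct <- oracle_coulomb_sum(to_cartesian(s), cell_matrix(s$lattice), 6) /
    n_formula_units(s)
  expect_lt(abs(elec - direct), 1e-4) # absolute, kJ/mol
})

test_that("non-neutral cells are rejected for charge-only electrostatics", {
  m <- rigid_molecule("C", matrix(0, 1, 3), charges = 0.3, name = "ion")
  s <- crystal_structure(lattice(20, 20, 20), list(ion = m),
                         list(placement("ion", c(0, 0, 0))))
  ff <- force_field("C", A = 0, B = 1, C = 0)
  expect_error(lattice_energy(s, ff), "non-neutral")
})

test_that("energy is invariant under rigid translation and coordinate wrapping", {
  fx <- fx_pocket()
  s <- fx$minima[[1]]$structure
  e0 <- lattice_energy(s, fx$ff, fx$settings)
  # translate all molecules by the same arbitrary vector
  s_t <- s
  shift <- c(0.31, -1.27, 2.04)
  for (i in seq_along(s_t$placements)) {
    s_t$placements[[i]]$frac <- s_t$placements[[i]]$frac + shift
  }
  expect_equal(lattice_energy(s_t, fx$ff, fx$settings), e0, tolerance = 1e-8)
  # wrapping of fractional coordinates does not change the energy
  s_w <- s
  s_w$placements[[2]]$frac <- wrap_frac(s_w$placements[[2]]$frac) + c(3, -2, 1)
  expect_equal(lattice_energy(s_w, fx$ff, fx$settings), e0, tolerance = 1e-8)
})

test_that("a 2x1x1 P1 supercell leaves the per-formula-unit energy unchanged", {
  at <- rigid_molecule("Ar", matrix(0, 1, 3), name = "Ar")
  ff <- force_field("Ar", A = 1e5, B = 3.0, C = 500)
  s1 <- crystal_structure(lattice(5.5, 5.5, 5.5), list(Ar = at),
                          list(placement("Ar", c(0, 0, 0))))
  s2 <- crystal_structure(lattice(11, 5.5, 5.5), list(Ar = at),
                          list(placement("Ar", c(0, 0, 0)),
                               placement("Ar", c(0.5, 0, 0))))
  expect_equal(lattice_energy(s1, ff), lattice_energy(s2, ff),
               tolerance = 1e-6)
})

test_that("close-contact rule uses covalent radii + margin with strict inequality", {
  m <- rigid_molecule("C", matrix(0, 1, 3), name = "C1")
  ff <- force_field("C", A = 1, B = 1, C = 1)
  mk <- function(d) crystal_structure(
    lattice(30, 30, 30), list(C1 = m),
    list(placement("C1", c(0, 0, 0)), placement("C1", c(d / 30, 0, 0))))
  # threshold for C-C: 0.76 + 0.76 + 0.3 = 1.82
  expect_true(check_close_contacts(mk(2.0), ff)$ok)
  res <- check_close_contacts(mk(1.80), ff)
  expect_false(res$ok)
  expect_equal(res$threshold, 1.82)
  expect_equal(res$distance, 1.80, tolerance = 1e-9)
  # exactly at the threshold: "shorter than" is strict, so this passes
  expect_true(check_close_contacts(mk(1.82), ff)$ok)
  # isolated molecule in a huge cell
  iso <- crystal_structure(lattice(50, 50, 50), list(C1 = m),
                           list(placement("C1", c(0.5, 0.5, 0.5))))
  expect_true(check_close_contacts(iso, ff)$ok)
})

test_that("enthalpy adds P V per formula unit with the documented conversion", {
  at <- rigid_molecule("Ar", matrix(0, 1, 3), name = "Ar")
  ff <- force_field("Ar", A = 0, B = 1, C = 100)
  s <- crystal_structure(lattice(10, 10, 10), list(Ar = at),
                         list(placement("Ar", c(0, 0, 0))))
  e <- lattice_energy(s, ff)
  expect_equal(enthalpy(s, ff, pressure = 0), e, tolerance = 1e-12)
  expect_equal(enthalpy(s, ff, pressure = 0.1), e + 0.1 * 1000 * 0.6022140857,
               tolerance = 1e-9)
  # doubling the cell (2 formula units) leaves per-fu enthalpy unchanged
  s2 <- crystal_structure(lattice(20, 10, 10), list(Ar = at),
                          list(placement("Ar", c(0, 0, 0)),
                               placement("Ar", c(0.5, 0, 0))))
  expect_equal(enthalpy(s2, ff, pressure = 0.1),
               enthalpy(s, ff, pressure = 0.1), tolerance = 1e-6)
})
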