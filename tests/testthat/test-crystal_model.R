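# Geometry layer: lattices, rigid molecules, space-group expansion.

test_that("fractional/Cartesian round trip is exact for random lattices", {
  set.seed(1)
  for (rep in 1:20) {
    lat <- lattice(runif(1, 3, 20), runif(1, 3, 20), runif(1, 3, 20),
                   runif(1, 60, 120), runif(1, 60, 120), runif(1, 60, 120))
    f <- matrix(runif(15, -2, 3), 5, 3)
    back <- cart_to_frac(frac_to_cart(f, lat), lat)
    expect_lt(max(abs(back - f)), 1e-10)
    # volume from the metric equals the triple product of cell vectors
    A <- cell_matrix(lat)
    expect_equal(cell_volume(lat), abs(det(A)), tolerance = 1e-10)
  }
})

test_that("lattice validation rejects degenerate cells", {
  expect_error(lattice(-1, 5, 5), "positive")
  expect_error(lattice(5, 5, 5, 0, 90, 90), "angles")
  expect_error(lattice(5, 5, 5, 10, 10, 179), "degenerate|3-D")
})

test_that("to_cartesian places molecules by quaternion and centre", {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  # identity orientation at the origin: atoms at their local coordinates
  s0 <- crystal_structure(lattice(10, 10, 10), list(CO = m),
                          list(placement("CO", c(0, 0, 0))))
  sites <- to_cartesian(s0)
  expect_equal(sites$coords, m$local, tolerance = 1e-12)
  # centre at fractional (.5,.5,.5) in a cubic a=10 cell -> Cartesian (5,5,5)
  s1 <- crystal_structure(lattice(10, 10, 10), list(CO = m),
                          list(placement("CO", c(0.5, 0.5, 0.5))))
  com <- colSums(to_cartesian(s1)$coords * m$masses) / sum(m$masses)
  expect_equal(as.numeric(com), c(5, 5, 5), tolerance = 1e-10)
  # random orientations never distort the rigid geometry
  set.seed(7)
  dref <- as.matrix(dist(m$local))
  for (rep in 1:10) {
    s2 <- crystal_structure(lattice(10, 10, 10), list(CO = m),
                            list(placement("CO", runif(3), quat_random())))
    d <- as.matrix(dist(to_cartesian(s2)$coords))
    expect_lt(max(abs(d - dref)), 1e-10)
  }
})

test_that("asymmetric-unit expansion yields Z = n_ops x n_asym", {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  lat_tric <- lattice(6, 7, 8, 85, 95, 100)
  lat_mono <- lattice(6, 7, 8, 90, 100, 90)
  s_p1 <- crystal_structure(lat_tric, list(CO = m),
                            list(placement("CO", c(0.1, 0.2, 0.3))),
                            setting = builtin_setting("P1"))
  expect_equal(structure_z(s_p1), 1)
  full <- expand_asymmetric_unit(s_p1)
  expect_equal(full[[1]]$frac, c(0.1, 0.2, 0.3))
  # one molecule in P21 -> two in the cell; in P21/c -> four
  s_p21 <- crystal_structure(lat_mono, list(CO = m),
                             list(placement("CO", c(0.1, 0.2, 0.3))),
                             setting = builtin_setting("P21"))
  expect_equal(structure_z(s_p21), 2)
  s_p21c <- crystal_structure(lat_mono, list(CO = m),
                              list(placement("CO", c(0.1, 0.2, 0.3))),
                              setting = builtin_setting("P21/c"))
  expect_equal(structure_z(s_p21c), 4)
  expect_equal(length(expand_asymmetric_unit(s_p21c)), 4)
  # monoclinic operators are incompatible with a triclinic cell
  s_bad <- crystal_structure(lat_tric, list(CO = m),
                             list(placement("CO", c(0.1, 0.2, 0.3))),
                             setting = builtin_setting("P21"))
  expect_error(expand_asymmetric_unit(s_bad), "incompatible")
})

test_that("operator sets must be closed and contain the identity", {
  expect_error(spacegroup_setting("bad", list(
    list(W = diag(c(-1, 1, -1)), w = c(0, 0.5, 0))
  )), "identity")
  expect_error(spacegroup_setting("bad", list(
    list(W = diag(3), w = c(0, 0, 0)),
    list(W = diag(c(-1, 1, -1)), w = c(0, 0.25, 0))
  )), "closed")
})

test_that("quaternion conventions: operator composes on the left", {
  # rotate 90 deg about z, then apply an operator rotating 90 deg about x:
  # the composition must equal R_x %*% R_z
  qz <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  qx <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  Rcomp <- quat_to_matrix(quat_multiply(qx, qz))
  expect_equal(Rcomp, quat_to_matrix(qx) %*% quat_to_matrix(qz),
               tolerance = 1e-12)
  # matrix -> quaternion -> matrix round trip
  set.seed(3)
  for (rep in 1:10) {
    q <- quat_random()
    expect_equal(quat_to_matrix(quat_from_matrix(quat_to_matrix(q))),
                 quat_to_matrix(q), tolerance = 1e-9)
  }
})

test_that("improper operators create enantiomeric copies, flagged by parity", {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  s <- crystal_structure(lattice(8, 8, 8, 80, 85, 95), list(CO = m),
                         list(placement("CO", c(0.1, 0.2, 0.3))),
                         setting = builtin_setting("P-1"))
  full <- expand_asymmetric_unit(s)
  expect_equal(length(full), 2)
  expect_equal(full[[2]]$inv, -1L)
  expect_equal(full[[2]]$frac, -c(0.1, 0.2, 0.3))
})

test_that("intramolecular radius matches the brute-force pair maximum", {
  one <- rigid_molecule("C", matrix(0, 1, 3))
  expect_equal(intramolecular_radius(one), 0)
  dia <- rigid_molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  expect_equal(intramolecular_radius(dia), 1.2, tolerance = 1e-12)
  sq <- rigid_molecule(rep("C", 4),
                       rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  brute <- max(dist(sq$local))
  expect_equal(intramolecular_radius(sq), brute)
  expect_equal(brute, sqrt(2), tolerance = 1e-12)
})

test_that("expansion then symmetry re-check recovers the operator images", {
  # every operator applied to the asymmetric placement must reproduce one of
  # the expanded placements (frac modulo lattice translations)
  s <- toy_p21_structure()
  full <- expand_asymmetric_unit(s)
  for (op in s$setting$ops) {
    img <- (as.numeric(op$W %*% s$placements[[1]]$frac) + op$w) %% 1
    hits <- vapply(full, function(p) {
      max(abs((p$frac %% 1) - img)) < 1e-8
    }, TRUE)
    expect_true(any(hits))
  }
})

test_that("formula units and density behave for homo- and heteromolecular cells", {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  g <- rigid_molecule("Ar", matrix(0, 1, 3), name = "Ar")
  s <- crystal_structure(lattice(8, 8, 8), list(CO = m, Ar = g),
                         list(placement("CO", c(0, 0, 0)),
                              placement("Ar", c(0.5, 0.5, 0.5))))
  expect_equal(n_formula_units(s), 1)
  s2 <- crystal_structure(lattice(8, 8, 8), list(CO = m),
                          list(placement("CO", c(0, 0, 0)),
                               placement("CO", c(0.5, 0.5, 0.5))))
  expect_equal(n_formula_units(s2), 2)
  mass <- 2 * (12.011 + 15.999)
  expect_equal(structure_density(s2), 1.66053906660 * mass / 512,
               tolerance = 1e-9)
})
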