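# Monte Carlo move generator: degree-of-freedom bookkeeping, cutoffs,
# distributions, symmetry propagation.

test_that("move-type probabilities follow the degree-of-freedom shares", {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  s_p1 <- crystal_structure(lattice(6, 7, 8, 85, 95, 100), list(CO = m),
                            list(placement("CO", c(0.1, 0.2, 0.3))),
                            setting = builtin_setting("P1"))
  dof <- move_dof(s_p1)
  expect_equal(unname(dof), c(3, 3, 3, 3, 1))
  expect_equal(sum(dof), 13) # p(translation) = 3/13
  s_p21c <- crystal_structure(lattice(6, 7, 8, 90, 100, 90), list(CO = m),
                              list(placement("CO", c(0.1, 0.2, 0.3))),
                              setting = builtin_setting("P21/c"))
  dof2 <- move_dof(s_p21c)
  expect_equal(unname(dof2), c(3, 3, 3, 1, 1)) # free cell: a, b, c, beta
  expect_equal(sum(dof2), 11) # p(cell_angle) = 1/11
  # empirical frequencies within 4 sigma of the binomial expectation
  set.seed(11)
  n <- 20000
  draws <- replicate(n, select_move_type(move_spec(), s_p21c))
  for (ty in names(dof2)) {
    p <- dof2[[ty]] / sum(dof2)
    sigma <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(draws == ty) - p), 4 * sigma + 1e-12)
  }
})

test_that("every proposal magnitude respects its cutoff and changes one block", {
  s <- toy_p21_structure()
  spec <- move_spec()
  set.seed(21)
  for (rep in 1:200) {
    pr <- propose_move(s, spec)
    if (pr$skipped) next
    sn <- pr$structure
    if (pr$type == "translation") {
      expect_lte(sqrt(sum(pr$payload^2)), spec$cutoffs[["translation"]] + 1e-12)
      expect_identical(sn$lattice, s$lattice)
      expect_identical(sn$placements[[1]]$quat, s$placements[[1]]$quat)
    } else if (pr$type == "rotation") {
      expect_lte(sqrt(sum(pr$payload^2)), spec$cutoffs[["rotation"]] + 1e-12)
      expect_identical(sn$lattice, s$lattice)
      expect_identical(sn$placements[[1]]$frac, s$placements[[1]]$frac)
      expect_equal(sum(sn$placements[[1]]$quat^2), 1, tolerance = 1e-12)
    } else if (pr$type == "cell_length") {
      expect_lte(abs(pr$payload), spec$cutoffs[["cell_length"]] + 1e-12)
      expect_identical(sn$placements, s$placements)
    } else if (pr$type == "cell_angle") {
      expect_identical(sn$placements, s$placements)
      expect_gte(sn$lattice$beta, 45)
      expect_lte(sn$lattice$beta, 135)
    } else if (pr$type == "volume") {
      z <- structure_z(s)
      expect_lte(abs(pr$payload), z * spec$cutoffs[["volume"]] + 1e-12)
    }
  }
})

test_that("volume moves scale centres isotropically, geometry untouched", {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  s <- crystal_structure(lattice(10, 10, 10), list(CO = m),
                         list(placement("CO", c(0.25, 0.5, 0.75))))
  v0 <- cell_volume(s$lattice)
  set.seed(31)
  pr <- propose_move(s, move_spec(), type = "volume")
  v1 <- cell_volume(pr$structure$lattice)
  f <- (v1 / v0)^(1 / 3)
  # 1000 -> 1030 example: centres scale by (1030/1000)^(1/3) ~ 1.00990
  expect_equal(v1, v0 + pr$payload, tolerance = 1e-8)
  com0 <- frac_to_cart(s$placements[[1]]$frac, s$lattice)
  com1 <- frac_to_cart(pr$structure$placements[[1]]$frac, pr$structure$lattice)
  expect_equal(as.numeric(com1), as.numeric(com0) * f, tolerance = 1e-9)
  d0 <- dist(to_cartesian(s)$coords)
  d1 <- dist(to_cartesian(pr$structure)$coords)
  # intramolecular distance unchanged (single molecule in cell)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  # explicit arithmetic check of the documented example
  expect_equal((1030 / 1000)^(1 / 3), 1.00990163, tolerance = 1e-7)
})

test_that("angle proposals are triangular, 90-degree-biased and bounded", {
  set.seed(41)
  # symmetric about 90 when currently at 90
  x90 <- replicate(20000, angle_bias_distribution(90, 0.5))
  expect_lt(abs(mean(x90) - 90), 0.02)
  expect_lte(max(abs(x90 - 90)), 0.5 + 1e-12)
  # drift towards 90 from 110
  x110 <- replicate(10000, angle_bias_distribution(110, 0.5))
  expect_lt(mean(x110), 110)
  # near the lower validity bound proposals may fall below 45 and are then
  # rejected by the proposal loop
  s <- toy_p21_structure()
  s$lattice$beta <- 46
  set.seed(43)
  for (rep in 1:200) {
    pr <- propose_move(s, move_spec(), type = "cell_angle")
    if (!pr$skipped) expect_gte(pr$structure$lattice$beta, 45)
  }
})

test_that("the proposal stream is exactly reproducible under a fixed seed", {
  s <- toy_p21_structure()
  run_stream <- function() {
    set.seed(99)
    lapply(1:25, function(i) propose_move(s, move_spec()))
  }
  a <- run_stream()
  b <- run_stream()
  expect_identical(a, b)
})

test_that("symmetry-constrained proposals keep the operator closure", {
  s <- toy_p21_structure()
  set.seed(51)
  for (rep in 1:25) {
    pr <- propose_move(s, move_spec())
    if (pr$skipped) next
    sn <- pr$structure
    full <- expand_asymmetric_unit(sn)
    # the symmetry image must be the operator transform of the asym molecule
    op <- sn$setting$ops[[2]]
    img <- as.numeric(op$W %*% sn$placements[[1]]$frac) + op$w
    expect_lt(max(abs(full[[2]]$frac - img)), 1e-8)
  }
})
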