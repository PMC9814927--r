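# Duplicate detection: powder screen + cluster comparison.

test_that("powder patterns are deterministic, normalized, Bragg-correct", {
  s <- toy_p21_structure()
  p1 <- simulate_powder_pattern(s)
  p2 <- simulate_powder_pattern(s)
  expect_identical(p1, p2)
  expect_equal(max(p1$intensity), 1)
  expect_true(all(p1$intensity >= 0))
  # simple cubic single atom, a = 5: first peak at 2 asin(lambda/(2 d_100))
  at <- rigid_molecule("C", matrix(0, 1, 3), name = "C1")
  sc <- crystal_structure(lattice(5, 5, 5), list(C1 = at),
                          list(placement("C1", c(0, 0, 0))))
  pc <- simulate_powder_pattern(sc)
  peaks <- which(diff(sign(diff(pc$intensity))) == -2) + 1
  expect_equal(pc$two_theta[peaks[1]], 2 * asin(1.5406 / 10) * 180 / pi,
               tolerance = 0.03)
})

test_that("pattern similarity is 1 for identical, 0 against empty, symmetric", {
  s <- toy_p21_structure()
  p <- simulate_powder_pattern(s)
  expect_equal(pattern_similarity(p, p), 1, tolerance = 1e-12)
  zero <- p
  zero$intensity <- rep(0, length(zero$intensity))
  expect_equal(pattern_similarity(p, zero), 0)
  s2 <- crystal_structure(lattice(6.3, 6.9, 8.2, 90, 99, 90), s$molecules,
                          s$placements, setting = s$setting)
  q <- simulate_powder_pattern(s2)
  expect_equal(pattern_similarity(p, q), pattern_similarity(q, p),
               tolerance = 1e-12)
  # supercell: same peak positions, similarity ~ 1
  full <- expand_asymmetric_unit(s)
  pl2 <- c(lapply(full, function(pl) placement("CO", pl$frac * c(0.5, 1, 1),
                                               pl$quat, pl$inv)),
           lapply(full, function(pl) placement("CO",
                                               pl$frac * c(0.5, 1, 1) + c(0.5, 0, 0),
                                               pl$quat, pl$inv)))
  ssup <- crystal_structure(lattice(12, 7, 8, 90, 100, 90), s$molecules, pl2)
  expect_gt(pattern_similarity(p, simulate_powder_pattern(ssup)), 0.99)
})

test_that("cluster matching is reflexive and survives re-descriptions", {
  s <- toy_p21_structure()
  cm <- cluster_match(s, s)
  expect_true(cm$match)
  expect_lt(cm$rmsd, 1e-8)
  # lattice translation
  s_t <- s
  s_t$placements[[1]]$frac <- s$placements[[1]]$frac + c(1, -2, 3)
  expect_true(is_duplicate(s, s_t))
  # supercell description
  ssup <- transform_cell(s, diag(c(2, 1, 1)))
  expect_true(is_duplicate(s, ssup))
  # cell re-setting with unit determinant (a <-> b swap, c negated)
  sw <- transform_cell(s, matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3))
  expect_true(is_duplicate(s, sw))
  # molecule permutation in the stored order
  p1 <- as_p1(s)
  perm <- p1
  perm$placements <- rev(perm$placements)
  expect_true(is_duplicate(p1, perm))
})

test_that("isotropic expansion is matched at 20% but not 1% distance tolerance", {
  s <- toy_p21_structure()
  sE <- s
  sE$lattice <- lattice(6 * 1.03, 7 * 1.03, 8 * 1.03, 90, 100, 90)
  expect_true(cluster_match(s, sE, match_criteria(distance_tol = 0.20))$match)
  expect_false(cluster_match(s, sE, match_criteria(distance_tol = 0.01))$match)
})

test_that("distinct fixture polymorphs are not duplicates; stoichiometry guards", {
  fx <- fx_pocket()
  expect_false(is_duplicate(fx$minima[[1]]$structure, fx$minima[[2]]$structure,
                            fx$criteria))
  expect_true(is_duplicate(fx$minima[[1]]$structure, fx$minima[[1]]$structure,
                           fx$criteria))
  # different stoichiometry: no-match with a reason
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  s1 <- crystal_structure(lattice(8, 8, 8), list(CO = m),
                          list(placement("CO", c(0, 0, 0))))
  g <- rigid_molecule("Ar", matrix(0, 1, 3), name = "Ar")
  s2 <- crystal_structure(lattice(8, 8, 8), list(CO = m, Ar = g),
                          list(placement("CO", c(0, 0, 0)),
                               placement("Ar", c(0.5, 0.5, 0.5))))
  res <- cluster_match(s1, s2)
  expect_false(res$match)
  expect_match(res$reason, "stoichiometry")
})

test_that("the energy pre-filter short-circuits clearly different minima", {
  s <- toy_p21_structure()
  expect_false(is_duplicate(s, s, e1 = -10, e2 = -8))
  expect_true(is_duplicate(s, s, e1 = -10, e2 = -10.2))
})

test_that("patterns export as two-column text", {
  s <- toy_p21_structure()
  p <- simulate_powder_pattern(s)
  f <- tempfile(fileext = ".xy")
  write_pattern(p, f)
  tab <- read.table(f, header = TRUE)
  expect_equal(nrow(tab), length(p$two_theta))
  expect_equal(tab$intensity, p$intensity, tolerance = 1e-6)
})
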