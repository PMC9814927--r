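# Quasi-random structure generation: Sobol' sequences, hull overlap
# resolution, the CSP loop.

test_that("Sobol' points are deterministic and index-addressable", {
  V <- NULL
  p0 <- sobol_point(0, 5)
  expect_equal(p0, rep(0, 5)) # index 0 is the origin (lower corner)
  s1 <- sobol_sequence(32, 4)
  s2 <- sobol_sequence(32, 4)
  expect_identical(s1, s2)
  # absolute indexing: offset slices match
  expect_equal(sobol_sequence(8, 4, offset = 16), s1[17:24, ])
  # dimension 1 is the van der Corput sequence
  expect_equal(s1[1:8, 1], c(0, 0.5, 0.75, 0.25, 0.375, 0.875, 0.625, 0.125))
  expect_true(all(s1 >= 0 & s1 < 1))
})

test_that("Sobol' centres have lower discrepancy than pseudorandom ones", {
  disc <- function(X, nb = 1500) {
    set.seed(123)
    U <- matrix(runif(nb * ncol(X)), nb)
    mx <- 0
    for (k in seq_len(nb)) {
      u <- U[k, ]
      frac <- mean(apply(t(X) <= u, 2, all))
      mx <- max(mx, abs(frac - prod(u)))
    }
    mx
  }
  X <- sobol_sequence(1024, 3)
  set.seed(2)
  Y <- matrix(runif(1024 * 3), 1024, 3)
  expect_lt(disc(X), disc(Y))
})

test_that("candidate generation is deterministic and respects the domain", {
  fx <- fx_pocket()
  dom <- sampling_domain(fx$molecules, fx$minima[[1]]$structure$setting,
                        c("host", "guest"), cell = fx$lattice)
  expect_equal(dom$dim, 6) # positions only: frozen cell and orientations
  a <- generate_candidate(dom, 7)
  b <- generate_candidate(dom, 7)
  expect_identical(a, b)
  set.seed(4)
  for (idx in sample(0:1023, 40)) {
    s <- generate_candidate(dom, idx)
    for (p in s$placements) {
      expect_true(all(p$frac >= 0 & p$frac < 1))
    }
    expect_identical(unlist(s$lattice[1:6]), unlist(fx$lattice[1:6]))
  }
})

test_that("geometrically impossible angle triples are skipped, not fatal", {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  dom <- sampling_domain(list(CO = m), builtin_setting("P1"), "CO")
  out <- lapply(0:31, function(i) generate_candidate(dom, i))
  # free triclinic sampling must hit at least one impossible combination in
  # the first indices and return NULL for it rather than erroring
  expect_true(any(vapply(out, is.null, TRUE)))
  ok <- out[!vapply(out, is.null, TRUE)]
  expect_gt(length(ok), 0)
  for (s_ in ok) expect_gt(cell_volume(s_$lattice), 0)
})

test_that("convex hull distance matches analytic separations", {
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  # two unit cubes shifted by 1.5 along x: gap 0.5
  d <- convex_distance(cube, sweep(cube, 2, c(1.5, 0, 0), "+"))
  expect_equal(d$distance, 0.5, tolerance = 1e-3)
  expect_equal(abs(d$axis[1]), 1, tolerance = 1e-2)
  # overlapping cubes: zero distance
  d2 <- convex_distance(cube, sweep(cube, 2, c(0.5, 0, 0), "+"))
  expect_lt(d2$distance, 1e-4)
  # point in cube
  d3 <- convex_distance(matrix(c(0.5, 0.5, 0.5), 1), cube)
  expect_lt(d3$distance, 1e-4)
})

test_that("overlap resolution expands until the separating-axis test passes", {
  m <- rigid_molecule(c("C", "C"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "C2")
  # overlapping pair in a small cell
  s <- crystal_structure(lattice(4, 4, 4), list(C2 = m),
                         list(placement("C2", c(0, 0, 0)),
                              placement("C2", c(0.15, 0, 0))))
  expect_true(xtalmc:::any_hull_overlap(s))
  r <- resolve_overlaps(s)
  expect_false(is.null(r))
  expect_false(xtalmc:::any_hull_overlap(r))
  # fractional centres and orientations untouched
  expect_equal(r$placements[[2]]$frac, s$placements[[2]]$frac)
  # non-overlapping input returned unchanged
  s_ok <- crystal_structure(lattice(12, 12, 12), list(C2 = m),
                            list(placement("C2", c(0, 0, 0)),
                                 placement("C2", c(0.5, 0.5, 0.5))))
  expect_identical(resolve_overlaps(s_ok), s_ok)
  # overlap only with a periodic image is detected too
  s_img <- crystal_structure(lattice(2.2, 9, 9), list(C2 = m),
                             list(placement("C2", c(0, 0.5, 0.5))))
  expect_true(xtalmc:::any_hull_overlap(s_img))
  expect_false(xtalmc:::any_hull_overlap(resolve_overlaps(s_img)))
})

test_that("the CSP loop delivers the target count and deduplicates", {
  fx <- fx_pocket()
  dom <- sampling_domain(fx$molecules, fx$minima[[1]]$structure$setting,
                        c("host", "guest"), cell = fx$lattice)
  land <- run_csp(dom, fx$ff, fx$settings, target = 12,
                  criteria = fx$criteria)
  expect_equal(land$n_success, 12)
  expect_lte(nrow(land$minima), 12)
  expect_equal(nrow(as.data.frame(land)), nrow(land$minima))
  expect_true(all(diff(land$minima$energy) >= 0))
  expect_true(all(land$minima$density > 0))
  # every landscape entry re-minimizes to itself (idempotence)
  top <- land$structures[[which.min(vapply(land$structures, function(s) {
    lattice_energy(s, fx$ff, fx$settings)
  }, 0))]]
  again <- minimize_structure(top, fx$ff, fx$settings, trust = Inf)
  expect_equal(again$energy, min(land$minima$energy), tolerance = 1e-4)
})
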