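# Threshold engine on analytic toy landscapes: lid semantics, registries,
# connections, grid merging.

test_that("a zero-lid schedule registers only the seed minimum", {
  tl <- make_toy_landscape(c(-10, -8), barriers = -4)
  sys <- toy_mc_system(tl)
  reg <- minima_registry()
  r <- run_threshold(sys, 0, lid_schedule(5, 0, 10), registry = reg,
                     rng_seed = 1)
  expect_equal(nrow(registry_minima(reg)), 1)
  expect_equal(nrow(r$log), 0)
  expect_equal(r$base_energy, -10)
})

test_that("lids below the barrier confine the walker; above, the second minimum appears", {
  tl <- make_toy_landscape(c(-10, -8), barriers = -4)
  sys <- toy_mc_system(tl, step = 0.08)
  # lids -8, -6 stay below the saddle at -4
  reg <- minima_registry()
  r_low <- run_threshold(sys, 0, lid_schedule(2, 2, 300), registry = reg,
                         rng_seed = 2)
  expect_equal(nrow(registry_minima(reg)), 1)
  # raising the lid to -4 opens the pass
  reg2 <- minima_registry()
  r_hi <- run_threshold(sys, 0, lid_schedule(2, 4, 300), registry = reg2,
                        rng_seed = 3)
  mins <- registry_minima(reg2)
  expect_equal(nrow(mins), 2)
  # the second minimum first appears at a lid >= the true barrier
  first <- r_hi$visits$first_lid_energy[r_hi$visits$id == 2]
  expect_gte(first, -4)
})

test_that("accepted unminimized energies never exceed the current lid", {
  tl <- make_toy_landscape(c(-10, -9, -8), barriers = c(-5, -2))
  sys <- toy_mc_system(tl)
  r <- run_threshold(sys, 0, lid_schedule(3, 3, 200),
                     registry = minima_registry(), rng_seed = 4)
  expect_true(all(r$log$e_unmin <= r$log$lid_energy + 1e-12))
})

test_that("the seed precondition rejects unconverged starting points", {
  tl <- make_toy_landscape(c(-10, -8), barriers = -4)
  sys <- toy_mc_system(tl)
  expect_error(run_threshold(sys, 0.3, lid_schedule(5, 1, 10),
                             registry = minima_registry(), rng_seed = 5),
               "not a converged minimum")
})

test_that("connections between trajectories carry the joint first-visit lid", {
  tl <- make_toy_landscape(c(-10, -8), barriers = -4)
  sys <- toy_mc_system(tl, step = 0.08)
  reg <- minima_registry()
  r1 <- run_threshold(sys, 0, lid_schedule(2, 4, 400), registry = reg,
                      rng_seed = 6, run_id = 1)
  r2 <- run_threshold(sys, 1, lid_schedule(2, 4, 400), registry = reg,
                      rng_seed = 7, run_id = 2)
  ev <- detect_connections(list(r1, r2))
  expect_equal(nrow(ev), 1)
  # estimated connection lid brackets the true barrier: B <= L <= B + inc
  expect_gte(ev$lid, -4)
  expect_lte(ev$lid, -4 + 2)
  # runs that never share a minimum produce no events
  tl2 <- make_toy_landscape(c(-10, -8), barriers = 50)
  sys2 <- toy_mc_system(tl2, step = 0.08)
  regb <- minima_registry()
  q1 <- run_threshold(sys2, 0, lid_schedule(2, 2, 100), registry = regb,
                      rng_seed = 8, run_id = 1)
  q2 <- run_threshold(sys2, 1, lid_schedule(2, 2, 100), registry = regb,
                      rng_seed = 9, run_id = 2)
  expect_equal(nrow(detect_connections(list(q1, q2))), 0)
  # a run against itself yields no self event
  expect_equal(nrow(detect_connections(list(q1, q1))), 0)
})

test_that("merging onto a common grid rounds lids UP to the new grid", {
  # grid laid from the lowest seed energy; a lid of -212.0 from a run seeded
  # at -214.5 maps to -209.2 on the grid anchored at -259.2
  fake_run <- function(base, inc = 5) {
    structure(list(run_id = 1, seed_id = 1, base_energy = base,
                   schedule = lid_schedule(inc, 10, 1),
                   lids = base + inc * (1:10),
                   visits = data.frame(id = 1, first_lid_energy = base,
                                       first_lid_index = 0)),
              class = "threshold_run")
  }
  runs <- list(fake_run(-259.2), fake_run(-214.5))
  conn <- data.frame(a = 1, b = 2, lid = -212.0)
  mg <- merge_onto_common_grid(runs, connections = conn)
  expect_equal(mg$grid[1], -259.2)
  expect_equal(mg$connections$lid, -209.2, tolerance = 1e-9)
  # a lid exactly on a grid point maps to itself
  conn2 <- data.frame(a = 1, b = 2, lid = -229.2)
  expect_equal(merge_onto_common_grid(runs, connections = conn2)$connections$lid,
               -229.2, tolerance = 1e-9)
  # single run: grid reproduces its own schedule
  mg1 <- merge_onto_common_grid(list(fake_run(-100)),
                                connections = data.frame(a = integer(0),
                                                         b = integer(0),
                                                         lid = numeric(0)))
  expect_equal(mg1$grid[1:11], -100 + 5 * (0:10))
  # inconsistent increments are refused
  expect_error(merge_onto_common_grid(list(fake_run(-100), fake_run(-90, 2))),
               "increments")
})

test_that("registry deduplication keeps the lower-energy representative", {
  tl <- make_toy_landscape(c(-10, -8), barriers = -4)
  sys <- toy_mc_system(tl)
  reg <- minima_registry()
  id1 <- register_minimum(reg, 1, -8, sys)
  # the same state reappearing with a slightly lower energy replaces it
  id2 <- register_minimum(reg, 1, -8.0001, sys)
  expect_equal(id1, id2)
  expect_equal(registry_minima(reg)$energy, -8.0001)
})

test_that("refining the lid increment never raises the toy barrier estimate", {
  tl <- make_toy_landscape(c(-10, -8), barriers = -4)
  estimate <- function(inc, steps) {
    sys <- toy_mc_system(tl, step = 0.08)
    reg <- minima_registry()
    r1 <- run_threshold(sys, 0, lid_schedule(inc, ceiling(8 / inc), steps),
                        registry = reg, rng_seed = 10, run_id = 1)
    r2 <- run_threshold(sys, 1, lid_schedule(inc, ceiling(8 / inc), steps),
                        registry = reg, rng_seed = 11, run_id = 2)
    min(detect_connections(list(r1, r2))$lid)
  }
  L5 <- estimate(5, 200)
  L1 <- estimate(1, 220) # >= 5x the sampling per unit lid
  expect_lte(L1, L5 + 1e-9)
  expect_gte(L1, -4) # still bounded below by the true barrier
})
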