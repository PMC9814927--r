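# xtalmc

Threshold Monte Carlo exploration of rigid-molecule crystal energy
landscapes, for computational chemists studying polymorphism: which crystal
packings of a molecule exist as lattice-energy minima, and how high are the
energy barriers separating them?

## What it does

The core is the **threshold (lid) algorithm**. Starting from a minimized
crystal structure, Monte Carlo moves (molecular translations and rotations,
cell length/angle/volume changes) are accepted only while the unminimized
energy of the perturbed structure stays below a ceiling — the *lid*:

- a walker confined below a lid can only explore the superbasin of its
  starting minimum;
- every accepted state is locally minimized (three steps, with a 0.1 GPa
  pressure stage that removes artificial voids) and the resulting minimum is
  registered, deduplicated by a two-step matcher (simulated powder-pattern
  screen, then a COMPACK-style 30-molecule cluster comparison);
- the lid is raised in fixed increments; the lowest lid at which two
  trajectories sample a common minimum is an upper bound on the energy
  barrier between their seeds, with resolution equal to the increment.

Energies are rigid-molecule lattice energies,
`E = 1/2 Σ [A exp(−B r) − C r⁻⁶ + q q'/r]` per mole of formula units
(exp-6 atom–atom repulsion–dispersion plus Ewald-summed point charges),
with the direct-space cutoff `max(15 Å, R_intra)` and close contacts below
covalent-radius sums + 0.3 Å rejected outright.

Around the core the package provides disconnectivity graphs (superbasin
trees with ultrametric merge energies, truncation and landmark
simplification), quasi-random (Sobol') crystal structure prediction with
convex-hull overlap resolution as the reference landscape generator,
hydrogen-bond motif classification (dimer / chain / other), and
ACSF/SOAP-REMatch descriptor featurization with HDBSCAN* clustering for
landscape analysis. Synthetic fixture systems with exactly computable
barrier oracles make the whole machinery testable without external data;
see the methods vignette (`vignettes/threshold-landscapes.Rmd`).

## Worked example

A two-well landscape with a known saddle at −4, explored from both minima:

```r
library(xtalmc)

tl  <- make_toy_landscape(c(-10, -8), barriers = -4)
sys <- toy_mc_system(tl, step = 0.08)
reg <- minima_registry()
sched <- lid_schedule(increment = 2, n_lids = 4, steps_per_lid = 300)

r1 <- run_threshold(sys, 0, sched, registry = reg, rng_seed = 1, run_id = 1)
r2 <- run_threshold(sys, 1, sched, registry = reg, rng_seed = 2, run_id = 2)
r1
#> threshold run 1: seed minimum #1 at -10.0000 kJ/mol, 4 lids x 300 steps, 2 minima visited

detect_connections(list(r1, r2))
#>   a b lid via
#> 1 1 2  -4   1

mg <- merge_onto_common_grid(list(r1, r2))
g  <- build_graph(registry_minima(reg), mg$connections, mg$grid)
g
#> disconnectivity graph: 2 minima, 1 superbasin nodes, 1 root(s)
merge_energy(g, r1$seed_id, r2$seed_id)
#> [1] -4
```

The connection appears exactly at the first lid at or above the true saddle
(−4): the estimate brackets the barrier from above with the increment as
resolution. `plot(g)` draws the disconnectivity tree.

The same engine runs on full crystals through `crystal_mc_system()`
(force field + energy settings + move spec + match criteria); built-in
fixture systems provide ready-made crystals with oracle barriers:

```r
fx  <- make_fixture_system("binary-pocket")
fx$barriers$p1$value            # grid flood-fill barrier oracle
sys <- crystal_mc_system(fx$ff, fx$settings, fx$movespec, fx$criteria)
run <- run_threshold(sys, fx$minima[[1]]$structure,
                     lid_schedule(5, 1, 100), rng_seed = 1)
```

and `run_csp()` generates the quasi-random energy–density landscape for the
same system. A thin command-line wrapper over these functions lives at
`inst/scripts/xtalmc.R` (`threshold`, `csp`, `match`, `fixtures`
subcommands, YAML run configuration).

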