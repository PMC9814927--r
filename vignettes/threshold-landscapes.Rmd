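---
title: "Threshold Monte Carlo on crystal energy landscapes: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold Monte Carlo on crystal energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Organic molecules usually have several crystalline packings (polymorphs)
close in lattice energy. Which polymorph appears, and whether it can convert
into another, is governed not by the minima alone but by the energy barriers
between them. `xtalmc` estimates those barriers for rigid-molecule crystals
with the threshold (lid) algorithm: staged Monte Carlo in which a move is
accepted only when the unminimized energy of the perturbed structure stays
below a ceiling (the lid). A walker confined below a lid can only explore the
superbasin around its starting minimum; raising the lid in fixed increments
reveals, lid by lid, which minima become mutually reachable. The lowest lid
at which the trajectories of two minima sample a common minimum is an upper
bound on the energy barrier between them, with resolution equal to the lid
increment. The resulting connectivity is summarized as a disconnectivity
graph: a tree whose leaves are minima and whose internal nodes mark the grid
energy at which superbasins merge.

Two key assumptions are inherited from the method itself: moves must be
small enough that a single perturbation cannot jump across a barrier, and
sampling under each lid should approach ergodicity within its pocket. Both
shape several design choices below.

## Energy model

The lattice energy per mole of formula units is

$$E = \tfrac12 \sum_{M,N}\sum_{i\in M, k\in N}
 \Big[ A_{\iota\kappa} e^{-B_{\iota\kappa} r_{ik}} - C_{\iota\kappa} r_{ik}^{-6}
 + \frac{q_i q_k}{4\pi\varepsilon_0 r_{ik}} \Big],$$

with exp-6 (Buckingham) repulsion-dispersion between atom types and point
charges for the electrostatics. Intramolecular pairs are excluded entirely:
molecules are rigid bodies, and only the intermolecular energy varies.
Charge-charge interactions are evaluated with Ewald summation (tinfoil
boundary); exp-6 terms and the real-space Ewald part are summed directly to
the cutoff `max(15 Å, R_intra)`, where `R_intra` is the largest
intramolecular atom-atom distance, so the cutoff always clears the first
shell of neighbours. Higher multipole ranks (through hexadecapole) used by
production CSP force fields are quantum-chemistry products; this package
evaluates rank 0 only and treats multipoles as out of scope — a known
limitation, stated here once.

Numerical choices worth knowing about:

* **Cutoff taper.** Atom pairs crossing a hard cutoff make the energy
  discontinuous at the 1e-4 kJ/mol level, which is fatal for
  finite-difference gradients. exp-6 terms are therefore switched to zero
  over a 2 Å smoothstep window below the cutoff (`taper_width` in
  `energy_settings()`, set 0 for a hard cutoff). The Ewald real-space term
  needs no taper: its value at the cutoff is below the Ewald accuracy target
  by construction.
* **exp-6 inner branch.** Below the inner maximum of each pair potential the
  \(-Cr^{-6}\) term diverges to \(-\infty\). The pair function is continued
  linearly upward below that radius; Monte Carlo never samples there (the
  close-contact rule rejects first), the continuation only protects
  minimizer line searches.
* **Ewald parameters.** The splitting parameter and reciprocal cutoff follow
  from one accuracy target (`ewald_accuracy`, default 1e-7 relative), with
  the real-space part truncated at the direct-space cutoff.
* **Close contacts.** A move is rejected outright when any intermolecular
  distance falls strictly below the sum of covalent radii + 0.3 Å. This also
  bounds the configuration space the walker can ever enter.

Direct-sum agreement is verified in the tests against naive triple-loop
image sums; the Ewald sum is compared on cells with zero net dipole moment,
because the plain image sum of a dipolar cell is only conditionally
convergent (its value depends on summation order through a shape-dependent
surface term), so only the zero-dipole case admits an unambiguous reference
value.

## Monte Carlo moves

Five move types perturb the asymmetric unit only; symmetry images follow
exactly because the full cell is always regenerated from the asymmetric unit
through the operator set: translations (cutoff 0.50 Å), rotations (0.05 rad,
axis uniform on the sphere), cell lengths (0.50 Å), cell angles (0.50°), and
volume changes (Z × 25 Å³, isotropic rescaling of the cell with fractional
centres fixed, so molecular geometry is untouched). Step sizes are uniform
within the cutoff. Move types are selected with probability proportional to
their share of the free degrees of freedom.

Cell angles are special: the proposal centre is pulled towards 90° by
`centre = current + (cutoff/45)(90 − current)` and symmetric triangular
noise of half-width `cutoff` is added; proposals outside [45°, 135°] are
resampled a bounded number of times and the move is skipped if none lands
inside. The linear pull is this package's concrete reading of a
"shift based on the divergence from 90 degrees"; it is isolated in
`angle_bias_distribution()` so alternatives can be swapped in. The bias
deliberately breaks detailed balance — the goal is structure exploration,
not ensemble averages.

## Minimization

Every accepted state is locally minimized in three steps: (1) minimize the
lattice energy at zero pressure — strictly downhill from the input, so no
barrier is crossed during minimization; (2) minimize the enthalpy
`E + P V` at 0.1 GPa, which collapses the artificial interlayer voids that
lid-limited sampling sometimes leaves behind; (3) re-minimize at zero
pressure to report an energy on the original landscape. If the pressure
excursion ends above the step-1 energy, the step-1 result is kept.

The optimizer is L-BFGS-B over the reduced coordinates (free cell
parameters, fractional centres, rotation vectors composed onto the current
quaternion — so orientations stay unit quaternions by construction), with
central finite-difference gradients scaled per coordinate type and
convergence declared when every gradient component is below `gtol`
(default 1e-4 kJ/mol per Å-equivalent). Cell angles are box-constrained to
[45°, 135°] during minimization as well, to avoid flat-cell pathologies.

One safeguard matters for the threshold method specifically: each optimizer
call is box-constrained to a trust radius (default 0.4 Å per coordinate)
around its starting point and restarted until it no longer touches the
boundary. A descent path assembled from such segments cannot jump across a
repulsive ridge wider than the radius, so the registry receives the minimum
of the basin the walker actually occupies. Structure-prediction
minimizations, where any minimum is acceptable, run unconstrained
(`trust = Inf`).

## Duplicate identification

Registered minima are deduplicated with a two-step strategy. A cheap screen
compares simulated powder X-ray patterns (Cu Kα, 5–50° 2θ, 0.02° grid,
Gaussian broadening of 0.3° FWHM, Lorentz-polarization and Cromer–Mann form
factors) through a weighted cross-correlation similarity; candidates below
the screen threshold (default 0.90) are declared distinct without further
work, as are pairs whose minimized energies differ by more than 0.5 kJ/mol.
Survivors go to a molecular-cluster comparison in the COMPACK spirit: a
cluster of 30 molecules (central molecule plus nearest neighbours by centre
of mass, hydrogens excluded) is extracted from each structure, a molecule
correspondence is found by superposing the clusters (the rotation is pinned
on the central molecule plus one neighbour, because a lone — possibly
linear — central molecule leaves it under-determined; improper alignments
are allowed so enantiomorphous descriptions match), and the match is
accepted when all intermolecular centre-of-mass distances agree within 20%
and molecular orientations within 20°. Matching compares only internal
cluster geometry, which is what makes it invariant under lattice
translation, molecule permutation, supercell description and cell
re-setting. Default tolerances are standard CSP practice; the screen
threshold was calibrated on the package's fixture systems.

Hydrogen-bond motifs are classified from H···acceptor contacts (distance
strictly below the vdW-radius sum + 0.1 Å, donor angle strictly above 125°)
aggregated into a molecule-level graph whose edges carry lattice
translations; a component is infinite precisely when some cycle closes with
a nonzero net translation. "Dimer" means every molecule sits in a
doubly-bonded pair, "chain" means every molecule lies on an infinite path.

## Disconnectivity graphs

Connections implied by the trajectories (two minima visited by one run are
connected at the larger of their first-visit lids; cross-run links arise
through shared minima) are merged onto a common energy grid anchored at the
lowest seed energy, with lids rounded up to the grid. A union-find sweep
from low to high grid energy emits an internal node whenever two or more
superbasins merge; merge energies are ultrametric by construction and are
tested against an independent Floyd–Warshall minimax-path oracle. Layout
groups low-barrier siblings adjacently; horizontal positions are
presentation only. Truncation (hide minima connecting to the landmarks only
above the highest landmark-pairwise merge) and landmark simplification
(contract everything but chosen leaves) operate on the built tree and
preserve landmark merge energies exactly.

## Quasi-random structure prediction

The reference landscape generator maps Sobol' points to molecular positions
(identity map on fractional coordinates), orientations (Shoemake map to
uniform rotations) and free cell parameters (length bounds derived from vdW
molecular volumes and a packing-coefficient window of 0.55–0.80). The
Sobol' generator is built from first principles: primitive polynomials over
GF(2) are enumerated programmatically (a polynomial is primitive iff x has
order 2^d − 1 in the quotient field) with unit initial direction numbers —
a valid low-discrepancy construction, verified against the van der Corput
sequence in dimension 1 and by star-discrepancy comparison with
pseudorandom sampling.

Because exp-6 is unphysical at short range, overlapping candidates are
repaired before minimization: molecular convex hulls (atoms inflated by half
their vdW radius) are tested pairwise, including periodic images, and the
cell is expanded isotropically by 5% per iteration until no overlap
remains; candidates needing more than a 12-fold expansion are discarded.
The overlap test computes the distance between convex hulls by projected
gradient descent over convex combinations — a positive distance certifies a
separating axis (which is returned), zero means overlap.

## Descriptor featurization

For landscape analysis the package computes element-resolved atom-centred
symmetry functions (radial G2 and angular G4 on an ANI-style grid; flattened
per structure with atoms ordered canonically so the vector is invariant
under atom permutations) and a compact SOAP (Gaussian radial basis × real
spherical harmonics to l = 3, power spectrum per element pair). Structure
similarity aggregates atomic environments with the REMatch kernel —
entropy-regularized optimal transport over the environment-similarity
matrix, computed with a log-domain Sinkhorn iteration; γ → ∞ recovers the
mean environment kernel and γ → 0 the best-match assignment kernel, both
verified in the tests. Kernel distances use d = √(2 − 2k). Clustering is
HDBSCAN* (own implementation: core distances, mutual reachability, MST,
condensed tree, excess-of-mass selection — validated on separable controls)
swept over a grid of minimum cluster sizes with no automatic selection, and
agreement with energy-basin labels is reported as the adjusted Rand index.

## Fixture systems: what they emulate, and what they do not

All quantitative tests run on synthetic systems whose ground truth is
computable exactly:

* **Toy landscapes** — piecewise-monotone 1-D multi-well functions with
  wells and saddles exactly at the requested energies (monotone cubic
  interpolation guarantees no spurious stationary points). They are the
  rigorous test of the lid semantics: barrier bracketing B ≤ L ≤ B +
  increment is asserted against the exact saddle.
* **Binary pocket** — an L-shaped framework molecule (held fixed) plus a
  single-atom guest in a frozen P1 cell. The accessible space is the guest's
  3-D position, so there are no symmetry-equivalent basin copies and an
  exhaustive 18³ grid flood fill (face connectivity; diagonal steps can
  tunnel through thin ridges) is an exact barrier oracle up to a declared
  0.3 kJ/mol resolution allowance. The energy scale of its exp-6 parameters
  is fixed once so that the barrier between the two lowest pockets sits
  about half a lid increment below the first lid of both test schedules:
  the walker then crosses through an energetically open channel, honouring
  the method's small-step assumption. (An earlier design with the barrier
  several increments above the seed showed exactly the failure mode the
  method warns about: crossing at a lid barely above the saddle requires
  threading a narrow channel and is unreliable at small step counts.)
* **Layer shift** — one L-shaped molecule in a frozen monoclinic P21 cell
  (translations only): two distinct stacking minima sharing one (trivial)
  hydrogen-bond motif, with a P1 twin carrying two independent molecules.
  Used for matcher distinction, motif equality, the descriptor set, and the
  constraint-relaxation comparison. Its basins are connected through
  low passes between symmetry-equivalent basin copies — the barrier oracle
  therefore floods between the full *families* of equivalent copies, found
  by minimizing from every grid-local minimum and classifying with the
  duplicate matcher.
* **Dimer vs chain** — a toy carboxylic-acid-like molecule with an
  engineered deep H···O pair well (parameters solved so the well minimum
  sits at 1.7 Å); reference packings realize a cyclic doubly-bonded dimer
  and an infinite translation chain, verified at build time.

These systems emulate the competition between packings — multiple minima,
interlocking repulsive ridges, nearly degenerate energies — but not the
chemistry of any real compound: no multipole electrostatics, no
conformational flexibility, molecule sizes of 1–4 atoms, and frozen cells
or orientations wherever that keeps the oracle exact. Passing tests
demonstrate the algorithms' contracts, not force-field accuracy for real
crystals.

## Study sizes and statistical conventions

The standard conditions used by the test suite and the acceptance script
(chosen once as a balance between statistical resolution and desk-scale
runtimes): on toy landscapes, walker steps of 0.05 with 2000 (increment 5)
or 800 (increment 1) attempted steps per lid — small steps so that a single
move cannot hop a thin ridge, with correspondingly more attempts so
diffusion still covers each pocket, and a 0.05-unit saddle-resolution
allowance on bracketing checks for the case where a lid lands within a
hair of the saddle (a finite-step walker cannot resolve thinner ridges);
100 (increment 5) or 200 (increment 1) steps per lid on the pocket fixture
with three seeded replicates each, pooled with fourteen toy replicates for
the 95% barrier-bracketing check; 30 steps per lid and ten replicates per
setting for the constrained-vs-P1 comparison; 200 successful minimizations
for the CSP landscape; 100 randomized re-descriptions for matcher
invariance; 100 random connection sets for the minimax-oracle
comparison.

Two conventions deserve a note. First, each measured connection lid is an
upper bound on the true first-connection lid, so when replicates are
compared across settings (P1 versus symmetry-constrained) the package
compares the replicate *minima* — the natural estimator for an upper-bound
family; per-replicate lids are additionally dominated by which of the two
walkers happens to cross first when seeds are nearly degenerate. Second,
barrier-bracketing assertions on crystal fixtures carry the grid oracle's
declared resolution allowance; on toy landscapes the saddle is analytic and
no allowance is applied.

## Open choices made here

* Orientations are parameterized as unit quaternions, composed as
  (operator ∘ orientation); improper operators act by the proper part of
  the Cartesian operator plus a parity flip of the molecular frame, so
  enantiomeric copies are explicit and structures mixing chiralities are
  permitted.
* The walker continues from the accepted unminimized state across lid
  raises (a documented `reset_at_lid` switch restores restarting).
* The 0.1 GPa step minimizes the enthalpy E + PV.
* Symmetry is not re-detected after P1 minimizations; settings are operator
  bookkeeping only.
* Run configuration files use YAML.
* Cell-parameter constraints are encoded as free/fixed masks per crystal
  system (triclinic: all free; monoclinic: α, γ fixed); the built-in
  settings are P1, P-1, P21 and P21/c.

## Limitations

Rank-0 electrostatics only; no conformational flexibility (rigid bodies
throughout); no analytic gradients, free energies or temperature effects;
no transition-path geometries (connection lids bound barriers, they do not
locate saddle points); no space-group determination or Niggli reduction
beyond what duplicate matching needs; screening-grade powder patterns, not
Rietveld-grade.
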