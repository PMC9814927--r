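# Synthetic fixture systems: small rigid molecules with hand-set exp-6
# parameters engineered so that at least two distinct packing minima exist,
# with oracle barriers computed by exhaustive low-dimensional grid scans.
# Fixture landscapes freeze the cell and the molecular orientations, so the
# accessible configuration space is spanned by molecular translations only
# and the grid oracles are exact up to the stated scan resolution. These
# systems stand in for force-field-parameterized real molecules in every test
# of the threshold machinery; they emulate the competition between packings,
# not the chemistry of any particular compound.

#' Minimax barrier between two basin families on a periodic energy grid
#'
#' Flood-fill oracle: grid cells are activated in order of increasing energy
#' (invalid cells — close contacts — never activate); the barrier is the
#' energy at which any cell of family `a` first shares a connected component
#' with any cell of family `b` (face-neighbour connectivity with periodic
#' wrapping; diagonal steps are excluded because they can tunnel through
#' thin ridges at coarse resolution). Families may contain several
#' symmetry-equivalent copies of the same physical minimum — the barrier
#' between two structures is the lowest pass between ANY pair of their
#' copies.
#' @param E energy array (2- or 3-dimensional); NA marks invalid cells
#' @param a,b integer index vectors, or matrices with one reference cell per
#'   row (family of equivalent minima)
#' @return minimax barrier energy (NA when never connected)
#' @export
grid_barrier <- function(E, a, b) {
  dims <- dim(E)
  nd <- length(dims)
  n <- prod(dims)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  uf <- seq_len(n)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  lin <- function(ix) {
    k <- ix[1]
    if (nd >= 2) k <- k + (ix[2] - 1) * dims[1]
    if (nd >= 3) k <- k + (ix[3] - 1) * dims[1] * dims[2]
    k
  }
  steps <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  steps <- steps[rowSums(steps != 0) == 1, , drop = FALSE]
  ia <- apply(a, 1, lin); ib <- apply(b, 1, lin)
  added <- logical(n)
  ord <- order(E, na.last = NA)
  arr_ix <- arrayInd(ord, dims)
  for (r in seq_along(ord)) {
    cell <- ord[r]
    added[cell] <- TRUE
    ix <- arr_ix[r, ]
    for (srow in seq_len(nrow(steps))) {
      jx <- ((ix + steps[srow, ] - 1) %% dims) + 1
      jc <- lin(jx)
      if (added[jc]) uf[find(cell)] <- find(jc)
    }
    ra <- unique(vapply(ia[added[ia]], function(i) as.integer(find(i)), 0L))
    rb <- unique(vapply(ib[added[ib]], function(i) as.integer(find(i)), 0L))
    if (length(ra) && length(rb) && length(intersect(ra, rb))) return(E[cell])
  }
  NA_real_
}

layer_shift_fixture <- function(seed, oracle, oracle_res) {
  kappa <- 0.6 # overall energy scale of the exp-6 parameters
  mol <- rigid_molecule(c("C", "N", "H"),
                        rbind(c(0, 0, 0), c(1.25, 0, 0), c(-0.35, 0.95, 0)),
                        name = "ell")
  ff <- force_field(c("C", "N", "H"),
                    A = kappa * c(369743, 254529, 11971),
                    B = c(3.60, 3.78, 3.74),
                    C = kappa * c(2439.8, 1378.4, 136.4))
  es <- energy_settings()
  lat <- lattice(5.0, 5.2, 6.4, 90, 100, 90)
  st <- constrain_setting(builtin_setting("P21"), fix_cell = TRUE,
                          fix_orientation = TRUE)
  mk <- function(x, z) crystal_structure(lat, list(ell = mol),
                                         list(placement("ell", c(x, 0.25, z))),
                                         setting = st)
  m1 <- minimize_structure(mk(0.475, 0.725), ff, es)
  m2 <- minimize_structure(mk(0.300, 0.300), ff, es)
  if (!m1$converged || !m2$converged) {
    stop("layer-shift fixture: reference minima failed to converge")
  }
  if (is_duplicate(m1$structure, m2$structure)) {
    stop("layer-shift fixture: reference minima are not distinct")
  }
  criteria <- match_criteria()
  # classify every grid-local minimum into the family of m1 or m2 by
  # minimizing from it and duplicate-matching: the barrier between the two
  # STRUCTURES is the lowest pass between any pair of symmetry-equivalent
  # copies of their basins, which the flood fill then finds
  classify_cells <- function(cells, start_fn) {
    famA <- famB <- NULL
    for (r in seq_len(nrow(cells))) {
      s <- start_fn(cells[r, ])
      if (!check_close_contacts(s, ff, es$contact_margin)$ok) next
      m <- tryCatch(minimize_structure(s, ff, es), error = function(e) NULL)
      if (is.null(m) || !m$converged) next
      if (is_duplicate(m$structure, m1$structure, criteria,
                       e1 = m$energy, e2 = m1$energy)) {
        famA <- rbind(famA, cells[r, ])
      } else if (is_duplicate(m$structure, m2$structure, criteria,
                              e1 = m$energy, e2 = m2$energy)) {
        famB <- rbind(famB, cells[r, ])
      }
    }
    list(A = famA, B = famB)
  }
  local_minima_cells <- function(E) {
    dims <- dim(E)
    nd <- length(dims)
    steps <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
    steps <- steps[rowSums(steps != 0) > 0, , drop = FALSE]
    out <- NULL
    it <- which(!is.na(E))
    arr <- arrayInd(it, dims)
    for (r in seq_along(it)) {
      e <- E[it[r]]
      ok <- TRUE
      for (srow in seq_len(nrow(steps))) {
        jx <- ((arr[r, ] + steps[srow, ] - 1) %% dims) + 1
        nb <- E[matrix(jx, 1)]
        if (!is.na(nb) && nb < e - 1e-9) { ok <- FALSE; break }
      }
      if (ok) out <- rbind(out, arr[r, ])
    }
    out
  }
  barriers <- list()
  if ("constrained" %in% oracle) {
    ng <- oracle_res[1]
    gs <- seq(0, 1 - 1 / ng, length.out = ng)
    E <- matrix(NA_real_, ng, ng)
    for (i in seq_len(ng)) for (j in seq_len(ng)) {
      s <- mk(gs[i], gs[j])
      if (check_close_contacts(s, ff, es$contact_margin)$ok) {
        E[i, j] <- lattice_energy(s, ff, es)
      }
    }
    lm <- local_minima_cells(E)
    fam <- classify_cells(lm, function(cell) mk(gs[cell[1]], gs[cell[2]]))
    if (is.null(fam$A) || is.null(fam$B)) {
      stop("layer-shift fixture: grid scan failed to locate both minima families")
    }
    barriers$constrained <- list(
      value = grid_barrier(E, fam$A, fam$B),
      resolution = ng, grid_spacing = lat$a / ng,
      n_copies = c(nrow(fam$A), nrow(fam$B)))
  }
  if ("p1" %in% oracle) {
    # relative-displacement landscape of the two molecules in P1
    ng <- oracle_res[2]
    gs <- seq(0, 1 - 1 / ng, length.out = ng)
    p1_1 <- as_p1(m1$structure)
    base <- p1_1$placements[[1]]$frac
    q2 <- p1_1$placements[[2]]$quat
    mkrel <- function(cell) {
      u <- gs[cell]
      crystal_structure(lat, list(ell = mol),
                        list(placement("ell", base),
                             placement("ell", base + u, quat = q2)),
                        setting = p1_1$setting)
    }
    E3 <- array(NA_real_, c(ng, ng, ng))
    for (i in seq_len(ng)) for (j in seq_len(ng)) for (k in seq_len(ng)) {
      s <- mkrel(c(i, j, k))
      if (check_close_contacts(s, ff, es$contact_margin)$ok) {
        E3[i, j, k] <- lattice_energy(s, ff, es)
      }
    }
    lm3 <- local_minima_cells(E3)
    fam3 <- classify_cells(lm3, mkrel)
    if (is.null(fam3$A) || is.null(fam3$B)) {
      stop("layer-shift fixture: P1 grid scan failed to locate both minima families")
    }
    barriers$p1 <- list(value = grid_barrier(E3, fam3$A, fam3$B),
                        resolution = ng, grid_spacing = lat$a / ng,
                        n_copies = c(nrow(fam3$A), nrow(fam3$B)))
  }
  donors <- data.frame(mol = "ell", d = 1, h = 3)
  acceptors <- data.frame(mol = "ell", a = 2)
  motifs <- vapply(list(m1, m2), function(m) {
    classify_hbond_motif(m$structure, donors, acceptors)$motif
  }, "")
  list(profile = "layer-shift", seed = seed,
       molecules = list(ell = mol), ff = ff, settings = es,
       setting_constrained = st,
       lattice = lat,
       minima = list(m1, m2),
       minima_p1 = lapply(list(m1, m2), function(m) as_p1(m$structure)),
       barriers = barriers,
       movespec = move_spec(probabilities = c(translation = 1)),
       criteria = match_criteria(),
       donors = donors, acceptors = acceptors, motifs = motifs)
}

# Host-guest ("binary pocket") fixture: an L-shaped framework molecule held
# fixed plus a single-atom guest in a frozen triclinic-shaped P1 cell. The
# accessible space is the guest's 3-D position, so the relative-displacement
# landscape has no symmetry-equivalent copies and the grid flood fill is an
# exact barrier oracle up to its resolution. The energy scale (kappa) is
# fixed so that the barrier between the two lowest pockets sits about half a
# lid increment below the first lid of both schedules used in testing: the
# threshold walker then has an energetically open channel at the first
# feasible lid, honouring the method's small-step assumption.
binary_pocket_fixture <- function(seed, oracle, oracle_res) {
  kappa <- 1.4
  host <- rigid_molecule(c("C", "N", "H"),
                         rbind(c(0, 0, 0), c(1.25, 0, 0), c(-0.35, 0.95, 0)),
                         name = "host")
  guest <- rigid_molecule("O", matrix(0, 1, 3), name = "guest")
  ff <- force_field(c("C", "N", "H", "O"),
                    A = kappa * c(369743, 254529, 11971, 284623),
                    B = c(3.60, 3.78, 3.74, 3.96),
                    C = kappa * c(2439.8, 1378.4, 136.4, 1334.7))
  es <- energy_settings()
  lat <- lattice(5.4, 5.6, 6.4, 90, 100, 90)
  st <- constrain_setting(builtin_setting("P1"), fix_cell = TRUE,
                          fix_orientation = TRUE)
  base <- c(0.1, 0.1, 0.1)
  mk <- function(u) crystal_structure(
    lat, list(host = host, guest = guest),
    list(placement("host", base, frozen = TRUE),
         placement("guest", base + u)), setting = st)
  m1 <- minimize_structure(mk(c(0.39, 0.5, 0.83)), ff, es)
  m2 <- minimize_structure(mk(c(0.44, 0.5, 0.17)), ff, es)
  if (!m1$converged || !m2$converged) {
    stop("binary-pocket fixture: reference minima failed to converge")
  }
  criteria <- match_criteria()
  if (is_duplicate(m1$structure, m2$structure, criteria)) {
    stop("binary-pocket fixture: reference minima are not distinct")
  }
  barriers <- list()
  if (length(oracle) && !identical(oracle, "none")) {
    ng <- oracle_res[2]
    gs <- seq(0, 1 - 1 / ng, length.out = ng)
    E3 <- array(NA_real_, c(ng, ng, ng))
    for (i in seq_len(ng)) for (j in seq_len(ng)) for (k in seq_len(ng)) {
      s <- mk(gs[c(i, j, k)])
      if (check_close_contacts(s, ff, es$contact_margin)$ok) {
        E3[i, j, k] <- lattice_energy(s, ff, es)
      }
    }
    lm <- pocket_local_minima(E3)
    famA <- famB <- NULL
    for (r in seq_len(nrow(lm))) {
      m <- tryCatch(minimize_structure(mk(gs[lm[r, ]]), ff, es),
                    error = function(e) NULL)
      if (is.null(m) || !m$converged) next
      if (is_duplicate(m$structure, m1$structure, criteria,
                       e1 = m$energy, e2 = m1$energy)) {
        famA <- rbind(famA, lm[r, ])
      } else if (is_duplicate(m$structure, m2$structure, criteria,
                              e1 = m$energy, e2 = m2$energy)) {
        famB <- rbind(famB, lm[r, ])
      }
    }
    if (is.null(famA) || is.null(famB)) {
      stop("binary-pocket fixture: grid scan failed to locate both pockets")
    }
    barriers$p1 <- list(value = grid_barrier(E3, famA, famB),
                        resolution = ng, grid_spacing = lat$a / ng,
                        tol = 0.3, # declared oracle resolution allowance
                        n_copies = c(nrow(famA), nrow(famB)))
  }
  list(profile = "binary-pocket", seed = seed,
       molecules = list(host = host, guest = guest), ff = ff, settings = es,
       lattice = lat,
       minima = list(m1, m2),
       barriers = barriers,
       movespec = move_spec(probabilities = c(translation = 1)),
       criteria = criteria,
       donors = NULL, acceptors = NULL, motifs = c(NA, NA))
}

pocket_local_minima <- function(E) {
  dims <- dim(E)
  steps <- as.matrix(do.call(expand.grid, rep(list(-1:1), length(dims))))
  steps <- steps[rowSums(steps != 0) > 0, , drop = FALSE]
  out <- NULL
  it <- which(!is.na(E))
  arr <- arrayInd(it, dims)
  for (r in seq_along(it)) {
    e <- E[it[r]]
    ok <- TRUE
    for (srow in seq_len(nrow(steps))) {
      jx <- ((arr[r, ] + steps[srow, ] - 1) %% dims) + 1
      nb <- E[matrix(jx, 1)]
      if (!is.na(nb) && nb < e - 1e-9) { ok <- FALSE; break }
    }
    if (ok) out <- rbind(out, arr[r, ])
  }
  out
}

dimer_chain_fixture <- function(seed) {
  # toy carboxylic-acid-like molecule: C, acceptor O, donor O, donor H
  loc <- rbind(c(0, 0, 0), c(0.6, 1.0, 0), c(0.6, -1.0, 0), c(1.55, -1.0, 0))
  mol <- rigid_molecule(c("C", "O", "O", "H"), loc, name = "acid")
  # exp-6 with an engineered deep H...O well at r0 = 1.7 Angstrom
  r0 <- 1.7; Bho <- 4.5; Cho <- 4000
  Aho <- 6 * Cho / (Bho * r0^7 * exp(-Bho * r0))
  types <- c("C", "O", "H")
  A <- outer(c(369743, 284623, 11971), c(369743, 284623, 11971),
             function(a, b) sqrt(a * b))
  B <- outer(c(3.60, 3.96, 3.74), c(3.60, 3.96, 3.74), function(a, b) (a + b) / 2)
  C <- outer(c(2439.8, 1334.7, 136.4), c(2439.8, 1334.7, 136.4),
             function(a, b) sqrt(a * b))
  A[2, 3] <- A[3, 2] <- Aho
  B[2, 3] <- B[3, 2] <- Bho
  C[2, 3] <- C[3, 2] <- Cho
  dimnames(A) <- dimnames(B) <- dimnames(C) <- list(types, types)
  ff <- force_field(types, A, B, C)
  es <- energy_settings()
  stP1 <- constrain_setting(builtin_setting("P1"), fix_cell = TRUE,
                            fix_orientation = TRUE)
  donors <- data.frame(mol = "acid", d = 3, h = 4)
  acceptors <- data.frame(mol = "acid", a = 2)
  masses <- lookup_table(ATOMIC_MASSES, c("C", "O", "O", "H"), "mass")
  com <- colSums(loc * masses) / sum(masses)

  # dimer packing: molecule + inverted copy about the point (1.925, 0, 0)
  lat_d <- lattice(9.5, 8.0, 6.0)
  Ad <- cell_matrix(lat_d)
  fA <- as.numeric(solve(Ad) %*% (com + c(2.5, 3.5, 3)))
  fB <- as.numeric(solve(Ad) %*% (c(2 * 1.925, 0, 0) - com + c(2.5, 3.5, 3)))
  s_dimer <- crystal_structure(lat_d, list(acid = mol),
                               list(placement("acid", fA),
                                    placement("acid", fB, inv = -1)),
                               setting = stP1)
  m_dimer <- minimize_structure(s_dimer, ff, es)

  # chain packing: one molecule per cell, rotated so the H-bond runs along a
  theta <- atan2(2, 2.65)
  qch <- quat_from_axis_angle(c(0, 0, 1), theta)
  lat_c <- lattice(sqrt(2.65^2 + 4), 7.0, 5.2)
  s_chain <- crystal_structure(lat_c, list(acid = mol),
                               list(placement("acid", c(0.1, 0.3, 0.3),
                                              quat = qch)),
                               setting = stP1)
  m_chain <- minimize_structure(s_chain, ff, es)
  if (!m_dimer$converged || !m_chain$converged) {
    stop("dimer-vs-chain fixture: reference minima failed to converge")
  }
  motif_d <- classify_hbond_motif(m_dimer$structure, donors, acceptors)$motif
  motif_c <- classify_hbond_motif(m_chain$structure, donors, acceptors)$motif
  if (motif_d != "dimer" || motif_c != "chain") {
    stop(sprintf("dimer-vs-chain fixture: motifs are %s/%s, expected dimer/chain",
                 motif_d, motif_c))
  }
  list(profile = "dimer-vs-chain", seed = seed,
       molecules = list(acid = mol), ff = ff, settings = es,
       minima = list(m_dimer, m_chain),
       movespec = move_spec(probabilities = c(translation = 1)),
       criteria = match_criteria(),
       donors = donors, acceptors = acceptors,
       motifs = c(motif_d, motif_c))
}

#' Build a synthetic fixture system
#'
#' Profiles:
#' \describe{
#'   \item{"layer-shift"}{one rigid L-shaped molecule in a frozen monoclinic
#'     P21 cell (orientations frozen, translations free): two distinct
#'     packing minima differing by the stacking offset, sharing the same
#'     (trivial) hydrogen-bond motif. Oracle barriers are computed by
#'     exhaustive grid scans of the 2-D constrained slice and of the 3-D
#'     relative-displacement space of the P1 twin.}
#'   \item{"dimer-vs-chain"}{a toy carboxylic-acid-like molecule with an
#'     engineered deep H...O pair well; two reference packings whose
#'     hydrogen-bond motifs differ: a cyclic doubly-bonded dimer and an
#'     infinite translation chain.}
#'   \item{"binary-pocket"}{a fixed L-shaped framework molecule plus a
#'     single-atom guest in a frozen P1 cell: the guest's two lowest binding
#'     pockets are distinct minima and the 3-D grid flood fill is an exact
#'     barrier oracle (no symmetry-equivalent basin copies).}
#' }
#' Construction is deterministic; `seed` is recorded for provenance.
#'
#' @param profile fixture profile name
#' @param seed integer recorded in the fixture
#' @param oracle which barrier oracles to compute for "layer-shift"
#'   (subset of c("constrained", "p1"); empty to skip the scans)
#' @param oracle_res grid resolutions for the constrained (2-D) and P1 (3-D)
#'   scans
#' @return a `fixture_system` list (molecules, ff, settings, minima,
#'   barriers, movespec, criteria, donor/acceptor tables, motif labels)
#' @export
make_fixture_system <- function(profile = c("layer-shift", "dimer-vs-chain",
                                            "binary-pocket"),
                                seed = 1, oracle = c("constrained", "p1"),
                                oracle_res = c(36, 18)) {
  profile <- match.arg(profile)
  fx <- switch(profile,
    "layer-shift" = layer_shift_fixture(seed, oracle, oracle_res),
    "dimer-vs-chain" = dimer_chain_fixture(seed),
    "binary-pocket" = binary_pocket_fixture(seed, oracle, oracle_res)
  )
  class(fx) <- "fixture_system"
  fx
}

#' @export
print.fixture_system <- function(x, ...) {
  cat(sprintf("fixture system '%s': %d reference minima (E = %s), motifs [%s]\n",
              x$profile, length(x$minima),
              paste(signif(vapply(x$minima, `[[`, 0, "energy"), 6),
                    collapse = ", "),
              paste(x$motifs, collapse = ", ")))
  for (nm in names(x$barriers)) {
    b <- x$barriers[[nm]]
    cat(sprintf("  %s barrier: %.4f kJ/mol (grid %d, spacing %.3f A)\n",
                nm, b$value, b$resolution, b$grid_spacing))
  }
  invisible(x)
}
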