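# Shared fixtures and independent oracles for the test suite. Heavy objects
# are built once per test run and memoized here.

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

fx_pocket <- function() memo("pocket", function() {
  make_fixture_system("binary-pocket", oracle = "p1")
})

fx_layer <- function() memo("layer", function() {
  make_fixture_system("layer-shift", oracle = "constrained")
})

fx_dimer_chain <- function() memo("dimerchain", function() {
  make_fixture_system("dimer-vs-chain")
})

# a small asymmetric P21 test structure used across files
toy_p21_structure <- function() memo("p21s", function() {
  m <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)),
                      name = "CO")
  set.seed(42)
  crystal_structure(lattice(6, 7, 8, 90, 100, 90), list(CO = m),
                    list(placement("CO", c(0.1, 0.2, 0.3),
                                   quat = quat_random())),
                    setting = builtin_setting("P21"))
})

# brute-force direct image sum of -C r^-6 for a single-atom P1 crystal
oracle_r6_sum <- function(lat, C, cutoff) {
  A <- cell_matrix(lat)
  nmax <- ceiling(cutoff / min(sqrt(colSums(A^2)))) + 2
  tot <- 0
  for (i in -nmax:nmax) for (j in -nmax:nmax) for (k in -nmax:nmax) {
    if (i == 0 && j == 0 && k == 0) next
    r2 <- sum((A %*% c(i, j, k))^2)
    if (r2 <= cutoff^2) tot <- tot - C / r2^3
  }
  tot / 2
}

# brute-force electrostatic image sum (plain 1/r, expanding shells), per cell
oracle_coulomb_sum <- function(sites, cell, nshell) {
  co <- sites$coords; q <- sites$charge; mol <- sites$molid
  tot <- 0
  for (i in -nshell:nshell) for (j in -nshell:nshell) for (k in -nshell:nshell) {
    tvec <- as.numeric(cell %*% c(i, j, k))
    for (a in seq_along(q)) for (b in seq_along(q)) {
      if (i == 0 && j == 0 && k == 0 && mol[a] == mol[b]) next
      r <- sqrt(sum((co[b, ] + tvec - co[a, ])^2))
      if (r > 1e-9) tot <- tot + 0.5 * q[a] * q[b] / r
    }
  }
  1389.35457644382 * tot
}

# zero-net-dipole charge toy: two antiparallel dipolar molecules in a big cell
charge_toy <- function(a = 40) {
  m <- rigid_molecule(c("C", "C"), rbind(c(-1, 0, 0), c(1, 0, 0)),
                      charges = c(0.5, -0.5), name = "dip")
  crystal_structure(lattice(a, a, a), list(dip = m),
                    list(placement("dip", c(0, 0, 0)),
                         placement("dip", c(0.5, 0.5, 0.5),
                                   quat = quat_from_axis_angle(c(0, 0, 1), pi))))
}

# Floyd-Warshall minimax path oracle over a connection table
minimax_oracle <- function(ids, connections) {
  n <- length(ids)
  D <- matrix(Inf, n, n)
  diag(D) <- -Inf
  for (r in seq_len(nrow(connections))) {
    i <- match(connections$a[r], ids); j <- match(connections$b[r], ids)
    D[i, j] <- D[j, i] <- min(D[i, j], connections$lid[r])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- min(D[i, j], max(D[i, k], D[k, j]))
  }
  dimnames(D) <- list(ids, ids)
  D
}

# random valid connection set over n minima (used by the disconnectivity
# oracle equivalence tests)
random_connection_set <- function(n, grid_min = -10, inc = 1) {
  energies <- sort(stats::runif(n, grid_min, grid_min + 3))
  minima <- data.frame(id = seq_len(n), energy = energies)
  grid <- seq(grid_min, grid_min + 20, by = inc)
  npair <- sample(1:(n * (n - 1) / 2), 1)
  pairs <- utils::combn(n, 2)
  sel <- pairs[, sample(ncol(pairs), min(npair, ncol(pairs))), drop = FALSE]
  lid <- vapply(seq_len(ncol(sel)), function(k) {
    lo <- max(energies[sel[1, k]], energies[sel[2, k]])
    grid[min(which(grid >= lo + stats::runif(1, 0, 6)))]
  }, 0)
  list(minima = minima,
       connections = data.frame(a = sel[1, ], b = sel[2, ], lid = lid),
       grid = grid)
}
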