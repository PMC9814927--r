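# Quasi-random crystal structure prediction: Sobol' points are mapped to the
# molecular positions, orientations and free lattice parameters of a
# space-group setting; molecular convex-hull overlaps (including periodic
# images) are removed by isotropic cell expansion before the close-contact
# check and the three-step lattice-energy minimization. The resulting unique
# minima form the reference energy-density landscape against which threshold
# sampling is compared.

#' Sampling domain for quasi-random structure generation
#'
#' The Sobol' coordinate layout is documented and fixed: for each asymmetric
#' molecule 3 position coordinates (fractional, identity-mapped) followed by
#' 3 orientation coordinates (Shoemake map to a uniform rotation, when
#' orientations are free), then one coordinate per free cell length, then one
#' per free cell angle. Cell length bounds default to
#' `(V_low^(1/3) * 0.6, V_high^(1/3) * 1.5)` where `V_low`/`V_high` bracket
#' the cell volume through vdW molecular volumes and a packing-coefficient
#' window of 0.55-0.80.
#'
#' @param molecules named list of [rigid_molecule()]s
#' @param setting a [spacegroup_setting()]
#' @param asym_mols character vector: molecule name per asymmetric placement
#' @param cell template [lattice()] providing the fixed parameters (and the
#'   whole cell when all parameters are frozen)
#' @param length_range optional c(lo, hi) bounds for free cell lengths
#' @param angle_range bounds for free cell angles [degrees]
#' @param packing_window packing-coefficient window used to derive default
#'   length bounds
#' @return a `sampling_domain`
#' @export
sampling_domain <- function(molecules, setting, asym_mols,
                            cell = lattice(10, 10, 10),
                            length_range = NULL, angle_range = c(45, 135),
                            packing_window = c(0.55, 0.80)) {
  if (!all(asym_mols %in% names(molecules))) stop("unknown molecule name")
  z <- length(asym_mols) * length(setting$ops)
  vmol <- sum(vapply(asym_mols, function(nm) molecule_volume(molecules[[nm]]), 0)) *
    length(setting$ops)
  if (is.null(length_range)) {
    vlo <- vmol / packing_window[2]
    vhi <- vmol / packing_window[1]
    length_range <- c(0.6 * vlo^(1 / 3), 1.5 * vhi^(1 / 3))
  }
  dim <- 3 * length(asym_mols) +
    (if (setting$rotations_free) 3 * length(asym_mols) else 0) +
    sum(setting$cell_free)
  structure(list(molecules = molecules, setting = setting,
                 asym_mols = asym_mols, cell = cell,
                 length_range = length_range, angle_range = angle_range,
                 dim = dim, z = z), class = "sampling_domain")
}

#' Generate a candidate structure from a Sobol' index
#'
#' Deterministic: the same index always yields a bit-identical structure.
#' Index 0 maps to the lower corner of the domain (all fractional positions
#' 0, lower length/angle bounds).
#' @param domain a [sampling_domain()]
#' @param index nonnegative Sobol' index
#' @param directions optional precomputed direction matrix
#' @return a [crystal_structure()], or `NULL` when the sampled cell angles
#'   are geometrically impossible (no 3-D cell exists; the index is skipped)
#' @export
generate_candidate <- function(domain, index, directions = NULL) {
  u <- sobol_point(index, domain$dim, directions)
  k <- 0
  placements <- list()
  for (nm in domain$asym_mols) {
    frac <- u[k + 1:3]; k <- k + 3
    if (domain$setting$rotations_free) {
      q <- quat_random(u[k + 1:3]); k <- k + 3
    } else {
      q <- c(1, 0, 0, 0)
    }
    placements[[length(placements) + 1]] <- placement(nm, frac, q)
  }
  pvec <- unlist(domain$cell[c("a", "b", "c", "alpha", "beta", "gamma")])
  free <- domain$setting$cell_free
  for (j in which(free)) {
    rng <- if (j <= 3) domain$length_range else domain$angle_range
    k <- k + 1
    pvec[j] <- rng[1] + u[k] * (rng[2] - rng[1])
  }
  lat <- tryCatch(lattice(pvec[1], pvec[2], pvec[3], pvec[4], pvec[5], pvec[6]),
                  error = function(e) NULL)
  if (is.null(lat)) return(NULL) # impossible angle combination
  crystal_structure(lat, domain$molecules, placements,
                    setting = domain$setting)
}

# Euclidean projection onto the probability simplex
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Distance between the convex hulls of two point sets
#'
#' Minimizes |P'lambda - Q'mu| over convex combinations by projected gradient
#' descent on the product of simplices. Used as the separating-axis overlap
#' test: a positive distance certifies a separating axis (returned as the
#' difference direction), distance zero means the hulls overlap.
#' @param P,Q point matrices (rows are points)
#' @param iters iteration budget
#' @return list(distance, axis)
#' @export
convex_distance <- function(P, Q, iters = 400) {
  np <- nrow(P); nq <- nrow(Q)
  lam <- rep(1 / np, np); mu <- rep(1 / nq, nq)
  L <- 2 * (max(rowSums(P^2)) + max(rowSums(Q^2))) + 1e-9
  step <- 1 / L
  for (it in seq_len(iters)) {
    z <- as.numeric(t(P) %*% lam - t(Q) %*% mu)
    if (sum(z^2) < 1e-16) break
    lam <- project_simplex(lam - step * 2 * as.numeric(P %*% z))
    mu <- project_simplex(mu + step * 2 * as.numeric(Q %*% z))
  }
  z <- as.numeric(t(P) %*% lam - t(Q) %*% mu)
  d <- sqrt(sum(z^2))
  list(distance = d, axis = if (d > 1e-12) z / d else c(NA, NA, NA))
}

# per-instance atom coordinate blocks and hull pads
molecule_blocks <- function(s, pad_scale = 0.5) {
  sites <- to_cartesian(s)
  ids <- sort(unique(sites$molid))
  lapply(ids, function(i) {
    ix <- sites$molid == i
    el <- sites$element[ix]
    list(atoms = sites$coords[ix, , drop = FALSE],
         pad = pad_scale * max(lookup_table(VDW_RADII, el, "vdW radius")))
  })
}

#' Detect and resolve molecular hull overlaps
#'
#' While any pair of molecular convex hulls (atoms inflated by half their vdW
#' radii; periodic images included) overlaps under the separating-axis test,
#' the lattice is scaled isotropically by `factor` with fractional centres
#' and orientations kept. Returns the expanded structure, or `NULL` when the
#' accumulated expansion exceeds `max_factor` (candidate discarded).
#' @param s a [crystal_structure()]
#' @param factor per-iteration isotropic expansion factor
#' @param max_factor give-up bound on the accumulated expansion
#' @param pad_scale fraction of the vdW radius used to inflate atoms
#' @return expanded `crystal_structure` or `NULL`
#' @export
resolve_overlaps <- function(s, factor = 1.05, max_factor = 12,
                             pad_scale = 0.5) {
  total <- 1
  repeat {
    if (!any_hull_overlap(s, pad_scale)) return(s)
    total <- total * factor
    if (total > max_factor) return(NULL)
    s$lattice$a <- s$lattice$a * factor
    s$lattice$b <- s$lattice$b * factor
    s$lattice$c <- s$lattice$c * factor
  }
}

any_hull_overlap <- function(s, pad_scale = 0.5, slack = 1e-6) {
  blocks <- molecule_blocks(s, pad_scale)
  A <- cell_matrix(s$lattice)
  radii <- vapply(blocks, function(b) {
    com <- colMeans(b$atoms)
    sqrt(max(rowSums(sweep(b$atoms, 2, com)^2))) + b$pad
  }, 0)
  reach <- 2 * max(radii)
  vol <- cell_volume(s$lattice)
  hn <- c(vol / sqrt(sum(pracma_cross(A[, 2], A[, 3])^2)),
          vol / sqrt(sum(pracma_cross(A[, 3], A[, 1])^2)),
          vol / sqrt(sum(pracma_cross(A[, 1], A[, 2])^2)))
  nm <- ceiling(reach / hn)
  shifts <- as.matrix(expand.grid(-nm[1]:nm[1], -nm[2]:nm[2], -nm[3]:nm[3]))
  nb <- length(blocks)
  for (k in seq_len(nrow(shifts))) {
    sh <- as.numeric(A %*% shifts[k, ])
    zero <- all(shifts[k, ] == 0)
    # avoid double-counting shift pairs: for nonzero shifts keep one half-space
    if (!zero && (shifts[k, 1] < 0 ||
                  (shifts[k, 1] == 0 && shifts[k, 2] < 0) ||
                  (shifts[k, 1] == 0 && shifts[k, 2] == 0 && shifts[k, 3] < 0))) next
    for (i in seq_len(nb)) {
      jstart <- if (zero) i + 1 else i
      if (jstart > nb) next
      for (j in jstart:nb) {
        Pi <- blocks[[i]]$atoms
        Qj <- sweep(blocks[[j]]$atoms, 2, sh, "+")
        ci <- colMeans(Pi); cj <- colMeans(Qj)
        if (sqrt(sum((ci - cj)^2)) > radii[i] + radii[j]) next
        d <- convex_distance(Pi, Qj)$distance
        if (d < blocks[[i]]$pad + blocks[[j]]$pad - slack) return(TRUE)
      }
    }
  }
  FALSE
}

#' Run a quasi-random CSP search
#'
#' Generate candidates from the Sobol' sequence, resolve hull overlaps,
#' reject remaining close contacts by further expansion, minimize (3-step),
#' and deduplicate against the accumulated minima until `target` successful
#' minimizations are recorded.
#'
#' @param domain a [sampling_domain()]
#' @param ff a [force_field()]
#' @param settings an [energy_settings()]
#' @param target number of successful minimizations to collect
#' @param criteria a [match_criteria()] for deduplication
#' @param start_index Sobol' index of the first candidate
#' @param max_attempts attempt budget (default 200 x target)
#' @param maxit minimizer iteration budget per stage
#' @param verbose print progress
#' @return a `csp_landscape`: list with `minima` (data.frame id, energy,
#'   density, hits), `structures`, `n_attempts`, `n_success`
#' @export
run_csp <- function(domain, ff, settings = energy_settings(), target = 10,
                    criteria = match_criteria(), start_index = 0,
                    max_attempts = 200 * target, maxit = 200,
                    verbose = FALSE) {
  V <- sobol_directions(domain$dim)
  entries <- list()
  n_success <- 0L; attempts <- 0L
  idx <- start_index
  while (n_success < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    if (attempts >= 300 && n_success / attempts < 0.01) {
      stop(sprintf("CSP success-rate collapse: %d successes in %d attempts",
                   n_success, attempts))
    }
    cand <- generate_candidate(domain, idx, V)
    idx <- idx + 1
    if (is.null(cand)) next
    cand <- resolve_overlaps(cand)
    if (is.null(cand)) next
    # residual close contacts: expand further until the contact rule passes
    ok <- TRUE
    total <- 1
    while (!check_close_contacts(cand, ff, settings$contact_margin)$ok) {
      cand$lattice$a <- cand$lattice$a * 1.05
      cand$lattice$b <- cand$lattice$b * 1.05
      cand$lattice$c <- cand$lattice$c * 1.05
      total <- total * 1.05
      if (total > 4) { ok <- FALSE; break }
    }
    if (!ok) next
    res <- tryCatch(minimize_structure(cand, ff, settings, maxit = maxit,
                                       trust = Inf),
                    error = function(e) NULL)
    if (is.null(res) || !res$converged) next
    n_success <- n_success + 1L
    # deduplicate
    pat <- simulate_powder_pattern(res$structure)
    matched <- FALSE
    for (ei in seq_along(entries)) {
      e <- entries[[ei]]
      if (abs(e$energy - res$energy) > criteria$energy_window) next
      if (pattern_similarity(pat, e$pattern) < criteria$pattern_threshold) next
      if (cluster_match(res$structure, e$structure, criteria)$match) {
        entries[[ei]]$hits <- e$hits + 1L
        if (res$energy < e$energy) {
          entries[[ei]]$energy <- res$energy
          entries[[ei]]$structure <- res$structure
          entries[[ei]]$pattern <- pat
        }
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      entries[[length(entries) + 1]] <- list(
        structure = res$structure, energy = res$energy, pattern = pat,
        hits = 1L)
    }
    if (verbose) {
      message(sprintf("CSP: %d/%d successes, %d unique (attempt %d)",
                      n_success, target, length(entries), attempts))
    }
  }
  minima <- data.frame(
    id = seq_along(entries),
    energy = vapply(entries, `[[`, 0, "energy"),
    density = vapply(entries, function(e) structure_density(e$structure), 0),
    hits = vapply(entries, `[[`, 0L, "hits"))
  minima <- minima[order(minima$energy), , drop = FALSE]
  rownames(minima) <- NULL
  structure(list(minima = minima,
                 structures = lapply(entries, `[[`, "structure"),
                 n_attempts = attempts, n_success = n_success),
            class = "csp_landscape")
}

#' Energy-density table of a CSP landscape
#' @param x a `csp_landscape`
#' @param ... unused
#' @return data.frame(id, energy, density, hits)
#' @export
as.data.frame.csp_landscape <- function(x, ...) x$minima

#' @export
print.csp_landscape <- function(x, ...) {
  cat(sprintf("CSP landscape: %d unique minima from %d successful minimizations (%d attempts)\n",
              nrow(x$minima), x$n_success, x$n_attempts))
  if (nrow(x$minima)) {
    cat(sprintf("  lowest energy %.4f kJ/mol at density %.3f g/cm^3\n",
                x$minima$energy[1], x$minima$density[1]))
  }
  invisible(x)
}

#' Plot a CSP energy-density landscape
#' @param x a `csp_landscape`
#' @param ... passed to plot
#' @export
plot.csp_landscape <- function(x, ...) {
  graphics::plot(x$minima$density, x$minima$energy, pch = 19,
                 xlab = "density [g cm^-3]", ylab = "lattice energy [kJ/mol]",
                 ...)
}
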