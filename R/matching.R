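# Duplicate-structure detection: the two-step strategy used when registering
# minima. Step 1 is a fast screen comparing simulated powder X-ray
# diffraction patterns; only candidates passing the screen go to step 2, a
# molecular-cluster comparison in the spirit of COMPACK: a reference cluster
# of N molecules (central molecule plus nearest neighbours by centre of mass)
# is extracted from each structure and the clusters are compared through
# their complete set of intermolecular centre-of-mass distances (relative
# tolerance) and per-molecule orientations (angle tolerance), hydrogen atoms
# excluded. Matching is invariant under lattice translation, molecule
# permutation, supercell description and cell re-setting by construction,
# because only internal cluster geometry is compared.

#' Matching criteria
#'
#' @param pattern_threshold powder-similarity screen threshold in [0, 1]
#' @param cluster_size molecules per comparison cluster (30)
#' @param distance_tol relative tolerance on intermolecular centre-of-mass
#'   distances (0.2 = 20 percent)
#' @param angle_tol molecular orientation tolerance [degrees]
#' @param ignore_hydrogens exclude H atoms from cluster comparison
#' @param energy_window minimized energies differing by more than this
#'   [kJ/mol] short-circuit to "not a duplicate"
#' @return a `match_criteria`
#' @export
match_criteria <- function(pattern_threshold = 0.90, cluster_size = 30,
                           distance_tol = 0.20, angle_tol = 20,
                           ignore_hydrogens = TRUE, energy_window = 0.5) {
  if (cluster_size < 1) stop("cluster size must be >= 1")
  if (distance_tol <= 0 || angle_tol <= 0) stop("tolerances must be positive")
  structure(list(pattern_threshold = pattern_threshold,
                 cluster_size = cluster_size, distance_tol = distance_tol,
                 angle_tol = angle_tol, ignore_hydrogens = ignore_hydrogens,
                 energy_window = energy_window), class = "match_criteria")
}

atomic_form_factor <- function(element, s2) {
  cm <- CROMER_MANN[[element]]
  if (is.null(cm)) {
    z <- ATOMIC_NUMBERS[element]
    if (is.na(z)) stop("no scattering data for element ", element)
    return(rep(as.numeric(z), length(s2)))
  }
  f <- rep(cm$c, length(s2))
  for (i in 1:4) f <- f + cm$a[i] * exp(-cm$b[i] * s2)
  f
}

#' Simulate a powder X-ray diffraction pattern
#'
#' Kinematic powder intensities (atomic form factors, Lorentz-polarization,
#' Gaussian peak broadening) on a fixed 2-theta grid, max-normalized.
#' Screening-grade: Cu K-alpha, 5-50 degrees by default.
#'
#' @param s a [crystal_structure()]
#' @param wavelength X-ray wavelength [Angstrom]
#' @param two_theta_range 2-theta window [degrees]
#' @param step grid step [degrees]
#' @param fwhm Gaussian peak full width at half maximum [degrees]
#' @return a `powder_pattern`: list(two_theta, intensity, wavelength)
#' @export
simulate_powder_pattern <- function(s, wavelength = 1.5406,
                                    two_theta_range = c(5, 50), step = 0.02,
                                    fwhm = 0.3) {
  if (cell_volume(s$lattice) <= 0) stop("invalid cell: non-positive volume")
  A <- cell_matrix(s$lattice)
  Ainv <- solve(A)
  sites <- to_cartesian(s)
  frac <- wrap_frac(t(Ainv %*% t(sites$coords)))
  th_max <- two_theta_range[2] / 2 * pi / 180
  gmax <- 2 * sin(th_max) / wavelength
  # |h_i| <= |a_i| * gmax
  alen <- sqrt(colSums(A^2))
  hmax <- pmax(1, ceiling(alen * gmax))
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                               l = -hmax[3]:hmax[3]))
  hkl <- hkl[rowSums(hkl != 0) > 0, , drop = FALSE]
  g <- hkl %*% Ainv # rows: reciprocal vectors (no 2 pi)
  glen <- sqrt(rowSums(g^2))
  keep <- glen <= gmax & glen > 1e-9
  hkl <- hkl[keep, , drop = FALSE]
  glen <- glen[keep]
  theta <- asin(wavelength * glen / 2)
  two_theta <- 2 * theta * 180 / pi
  keep2 <- two_theta >= two_theta_range[1] & two_theta <= two_theta_range[2]
  hkl <- hkl[keep2, , drop = FALSE]
  glen <- glen[keep2]; theta <- theta[keep2]; two_theta <- two_theta[keep2]
  grid <- seq(two_theta_range[1], two_theta_range[2], by = step)
  inten <- numeric(length(grid))
  if (nrow(hkl)) {
    s2 <- (glen / 2)^2
    f_by_el <- lapply(split(seq_along(sites$element), sites$element),
                      function(ix) ix)
    phase <- hkl %*% t(frac) # nrefl x natoms, in cycles
    Fre <- matrix(0, nrow(hkl), 1); Fim <- matrix(0, nrow(hkl), 1)
    Fre <- numeric(nrow(hkl)); Fim <- numeric(nrow(hkl))
    for (el in names(f_by_el)) {
      ix <- f_by_el[[el]]
      f <- atomic_form_factor(el, s2)
      ph <- 2 * pi * phase[, ix, drop = FALSE]
      Fre <- Fre + f * rowSums(cos(ph))
      Fim <- Fim + f * rowSums(sin(ph))
    }
    lp <- (1 + cos(2 * theta)^2) / (sin(theta)^2 * cos(theta))
    I <- (Fre^2 + Fim^2) * lp
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    for (r in seq_along(I)) {
      if (I[r] <= 0) next
      lo <- max(1, floor((two_theta[r] - 4 * sigma - grid[1]) / step) + 1)
      hi <- min(length(grid), ceiling((two_theta[r] + 4 * sigma - grid[1]) / step) + 1)
      if (lo > hi) next
      w <- lo:hi
      inten[w] <- inten[w] + I[r] * exp(-(grid[w] - two_theta[r])^2 / (2 * sigma^2))
    }
  }
  if (max(inten) > 0) inten <- inten / max(inten)
  structure(list(two_theta = grid, intensity = inten,
                 wavelength = wavelength), class = "powder_pattern")
}

#' Powder-pattern similarity
#'
#' Weighted cross-correlation similarity (de Gelder style): overlap of the
#' two patterns' cross-correlation functions under a triangular shift weight,
#' normalized by the autocorrelation overlaps. Symmetric; 1 iff the patterns
#' are identical; 0 against an empty pattern.
#' @param p1,p2 `powder_pattern`s on a common grid
#' @param window half-width of the shift window [degrees]
#' @param ac1,ac2 optional precomputed weighted autocorrelations (from
#'   [pattern_autocorrelation()]), reused across many comparisons
#' @return similarity in [0, 1]
#' @export
pattern_similarity <- function(p1, p2, window = 1.0, ac1 = NULL, ac2 = NULL) {
  if (length(p1$two_theta) != length(p2$two_theta) ||
      max(abs(p1$two_theta - p2$two_theta)) > 1e-9) {
    stop("patterns are not on a common grid")
  }
  step <- p1$two_theta[2] - p1$two_theta[1]
  L <- round(window / step)
  f <- p1$intensity; g <- p2$intensity
  n <- length(f)
  w <- 1 - abs(-L:L) / (L + 1)
  # FFT cross-correlation: stats::convolve(a, b, type = "open") places the
  # lag-l correlation sum(a[i] b[i + l]) at index n - l, so the lag window
  # [-L, L] sits at indices (n - L):(n + L)
  wxc <- function(a, b) {
    cc <- stats::convolve(a, b, type = "open")
    sum(w * cc[(n - L):(n + L)])
  }
  cfg <- wxc(f, g)
  cff <- if (is.null(ac1)) wxc(f, f) else ac1
  cgg <- if (is.null(ac2)) wxc(g, g) else ac2
  if (cff <= 0 || cgg <= 0) return(0)
  max(0, min(1, cfg / sqrt(cff * cgg)))
}

#' Weighted autocorrelation of a powder pattern
#'
#' The self-term of [pattern_similarity()]'s normalization; precompute it for
#' patterns compared many times (registry deduplication).
#' @param p a `powder_pattern`
#' @param window half-width of the shift window [degrees]
#' @return scalar autocorrelation overlap
#' @export
pattern_autocorrelation <- function(p, window = 1.0) {
  pattern_similarity_raw_ac(p$intensity, p$two_theta[2] - p$two_theta[1],
                            window)
}

pattern_similarity_raw_ac <- function(f, step, window) {
  L <- round(window / step)
  n <- length(f)
  w <- 1 - abs(-L:L) / (L + 1)
  cc <- stats::convolve(f, f, type = "open")
  sum(w * cc[(n - L):(n + L)])
}

# molecular content normalized to the formula unit, as a canonical string
formula_key <- function(s) {
  content <- cell_content(s)
  content <- content / Reduce(gcd2, content)
  paste(sprintf("%s:%d", names(content), content), collapse = ",")
}

# cluster of n molecules around a central instance: centre-of-mass positions
# and (optionally heavy-atom) coordinates, all Cartesian relative to the
# central molecule's centre of mass
build_cluster <- function(s, n, center_instance = 1, ignore_h = TRUE) {
  A <- cell_matrix(s$lattice)
  full <- expand_asymmetric_unit(s)
  z <- length(full)
  coms_frac <- t(vapply(full, function(p) wrap_frac(p$frac), numeric(3)))
  # image range large enough to find n neighbours
  vol_per_mol <- cell_volume(s$lattice) / z
  rad <- (3 / (4 * pi) * n * vol_per_mol)^(1 / 3) * 2 + max(sqrt(colSums(A^2)))
  hn <- c(cell_volume(s$lattice) /
            sqrt(sum(pracma_cross(A[, 2], A[, 3])^2)),
          cell_volume(s$lattice) /
            sqrt(sum(pracma_cross(A[, 3], A[, 1])^2)),
          cell_volume(s$lattice) /
            sqrt(sum(pracma_cross(A[, 1], A[, 2])^2)))
  nm <- ceiling(rad / hn)
  shifts <- as.matrix(expand.grid(-nm[1]:nm[1], -nm[2]:nm[2], -nm[3]:nm[3]))
  centre <- as.numeric(A %*% coms_frac[center_instance, ])
  shift_cart <- shifts %*% t(A)
  coms_cart <- coms_frac %*% t(A)
  ns <- nrow(shifts)
  inst_idx <- rep(seq_len(z), times = ns)
  shift_idx <- rep(seq_len(ns), each = z)
  allcom <- coms_cart[inst_idx, , drop = FALSE] +
    shift_cart[shift_idx, , drop = FALSE]
  d <- sqrt(rowSums(sweep(allcom, 2, centre)^2))
  ord <- order(d, inst_idx)
  sel_ix <- ord[seq_len(min(n, length(d)))]
  mols <- lapply(sel_ix, function(ix) {
    cd <- list(inst = inst_idx[ix], com = allcom[ix, ])
    p <- full[[cd$inst]]
    m <- s$molecules[[p$mol]]
    keep <- if (ignore_h) m$elements != "H" else rep(TRUE, length(m$elements))
    R <- quat_to_matrix(p$quat)
    atoms <- (m$local[keep, , drop = FALSE] * p$inv) %*% t(R)
    atoms <- sweep(atoms, 2, cd$com - centre, "+")
    list(mol = p$mol, com = cd$com - centre, atoms = atoms,
         elements = m$elements[keep])
  })
  mols
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Molecular-cluster comparison of two crystal structures
#'
#' Builds an N-molecule reference cluster in each structure (central molecule
#' plus N-1 nearest by centre of mass, hydrogens excluded by default), finds
#' a molecule correspondence by superposing the clusters, and accepts the
#' match when every intermolecular centre-of-mass distance agrees within the
#' relative distance tolerance and every molecular orientation within the
#' angle tolerance.
#'
#' @param s1,s2 [crystal_structure()]s
#' @param criteria a [match_criteria()]
#' @return list(match, rmsd, n_matched, reason): heavy-atom RMSD [Angstrom]
#'   of the optimally superposed clusters when matched
#' @export
cluster_match <- function(s1, s2, criteria = match_criteria()) {
  if (formula_key(s1) != formula_key(s2)) {
    return(list(match = FALSE, rmsd = NA_real_, n_matched = 0L,
                reason = "different stoichiometry"))
  }
  n <- criteria$cluster_size
  c1 <- build_cluster(s1, n, 1, criteria$ignore_hydrogens)
  z2 <- length(expand_asymmetric_unit(s2))
  for (cent in seq_len(z2)) {
    c2 <- build_cluster(s2, n, cent, criteria$ignore_hydrogens)
    if (c2[[1]]$mol != c1[[1]]$mol) next
    for (improper in c(FALSE, TRUE)) {
      # pin the global rotation on the central molecule plus one neighbour
      # candidate (a lone, possibly linear, central molecule leaves the
      # rotation under-determined)
      if (length(c1) == 1) {
        res <- try_cluster_alignment(c1, c2, criteria, improper, 0L)
        if (res$match) return(res)
      } else {
        dist1 <- sqrt(sum(c1[[2]]$com^2))
        for (j in seq_along(c2)[-1]) {
          if (c2[[j]]$mol != c1[[2]]$mol) next
          dj <- sqrt(sum(c2[[j]]$com^2))
          if (abs(dj - dist1) > criteria$distance_tol * pmax(dist1, 1)) next
          res <- try_cluster_alignment(c1, c2, criteria, improper, j)
          if (res$match) return(res)
        }
      }
    }
  }
  list(match = FALSE, rmsd = NA_real_, n_matched = 0L,
       reason = "no cluster correspondence within tolerances")
}

# angle between two molecules' orientations after the global transform:
# Kabsch rotation angle for 3-D geometries, bond-vector angle for linear ones
orientation_angle <- function(at1, at2) {
  if (nrow(at1) < 2) return(0)
  at1c <- sweep(at1, 2, colMeans(at1))
  at2c <- sweep(at2, 2, colMeans(at2))
  sv <- svd(at1c)
  if (nrow(at1) == 2 || sv$d[2] < 1e-6 * sv$d[1]) {
    v1 <- at1[nrow(at1), ] - at1[1, ]
    v2 <- at2[nrow(at2), ] - at2[1, ]
    cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    return(acos(pmin(1, pmax(-1, cs))) * 180 / pi)
  }
  rotation_angle(kabsch(at2c, at1c)$R)
}

try_cluster_alignment <- function(c1, c2, criteria, improper = FALSE,
                                  anchor = 0L) {
  fail <- list(match = FALSE, rmsd = NA_real_, n_matched = 0L,
               reason = "alignment failed")
  a1 <- c1[[1]]$atoms; a2 <- c2[[1]]$atoms
  if (anchor > 0) {
    a1 <- rbind(a1, c1[[2]]$atoms)
    a2 <- rbind(a2, c2[[anchor]]$atoms)
  }
  if (improper) a2 <- -a2
  if (nrow(a1) != nrow(a2)) return(fail)
  R <- if (nrow(a1) >= 2) kabsch(a2, a1)$R else diag(3)
  tf <- function(x) {
    if (improper) x <- -x
    x %*% t(R)
  }
  com2 <- t(vapply(c2, `[[`, numeric(3), "com"))
  com2t <- tf(com2)
  com1 <- t(vapply(c1, `[[`, numeric(3), "com"))
  types1 <- vapply(c1, `[[`, "", "mol")
  types2 <- vapply(c2, `[[`, "", "mol")
  # greedy assignment by transformed centre-of-mass proximity
  used <- rep(FALSE, length(c2))
  map <- integer(length(c1))
  for (i in seq_along(c1)) {
    dists <- sqrt(rowSums(sweep(com2t, 2, com1[i, ])^2))
    dists[used | types2 != types1[i]] <- Inf
    j <- which.min(dists)
    if (!is.finite(dists[j])) return(fail)
    map[i] <- j
    used[j] <- TRUE
  }
  # relative tolerance on all intermolecular COM distances
  d1 <- as.matrix(stats::dist(com1))
  d2 <- as.matrix(stats::dist(com2))[map, map, drop = FALSE]
  rel <- abs(d1 - d2) / pmax(d1, 1)
  if (max(rel[upper.tri(rel)]) > criteria$distance_tol) {
    return(modifyList(fail, list(reason = "distance tolerance exceeded")))
  }
  # per-molecule orientation agreement (skip single-atom molecules)
  for (i in seq_along(c1)) {
    at1 <- c1[[i]]$atoms
    if (nrow(at1) < 2) next
    at2 <- tf(c2[[map[i]]]$atoms)
    if (orientation_angle(at1, at2) > criteria$angle_tol) {
      return(modifyList(fail, list(reason = "angle tolerance exceeded")))
    }
  }
  all1 <- do.call(rbind, lapply(c1, `[[`, "atoms"))
  all2 <- do.call(rbind, lapply(c2[map], `[[`, "atoms"))
  if (improper) all2 <- -all2
  fit_all <- kabsch(all2, all1)
  list(match = TRUE, rmsd = fit_all$rmsd, n_matched = length(c1),
       reason = "matched")
}

# cluster sets (one cluster per possible central molecule) for cached
# registry comparisons
cluster_set <- function(s, criteria) {
  z <- length(expand_asymmetric_unit(s))
  lapply(seq_len(z), function(cent) {
    build_cluster(s, criteria$cluster_size, cent, criteria$ignore_hydrogens)
  })
}

# alignment of a candidate cluster against a stored cluster set
clusters_align <- function(c1, cset2, criteria) {
  for (c2 in cset2) {
    if (c2[[1]]$mol != c1[[1]]$mol) next
    for (improper in c(FALSE, TRUE)) {
      if (length(c1) == 1) {
        if (try_cluster_alignment(c1, c2, criteria, improper, 0L)$match) {
          return(TRUE)
        }
      } else {
        dist1 <- sqrt(sum(c1[[2]]$com^2))
        for (j in seq_along(c2)[-1]) {
          if (c2[[j]]$mol != c1[[2]]$mol) next
          dj <- sqrt(sum(c2[[j]]$com^2))
          if (abs(dj - dist1) > criteria$distance_tol * pmax(dist1, 1)) next
          if (try_cluster_alignment(c1, c2, criteria, improper, j)$match) {
            return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

#' Two-step duplicate test
#'
#' Fast powder screen, then cluster comparison; symmetric (the cluster step
#' is attempted in both directions).
#' @param s1,s2 [crystal_structure()]s
#' @param criteria a [match_criteria()]
#' @param e1,e2 optional minimized energies; when both are given and differ
#'   by more than `criteria$energy_window` the structures are declared
#'   distinct without further work
#' @param pattern1,pattern2 optional precomputed [simulate_powder_pattern()]s
#' @return logical
#' @export
is_duplicate <- function(s1, s2, criteria = match_criteria(),
                         e1 = NULL, e2 = NULL,
                         pattern1 = NULL, pattern2 = NULL) {
  if (!is.null(e1) && !is.null(e2) && abs(e1 - e2) > criteria$energy_window) {
    return(FALSE)
  }
  if (is.null(pattern1)) pattern1 <- simulate_powder_pattern(s1)
  if (is.null(pattern2)) pattern2 <- simulate_powder_pattern(s2)
  if (pattern_similarity(pattern1, pattern2) < criteria$pattern_threshold) {
    return(FALSE)
  }
  if (cluster_match(s1, s2, criteria)$match) return(TRUE)
  cluster_match(s2, s1, criteria)$match
}

#' Export a powder pattern as two-column text
#' @param p a `powder_pattern`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pattern <- function(p, path) {
  utils::write.table(data.frame(two_theta = p$two_theta,
                                intensity = p$intensity),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.powder_pattern <- function(x, ...) {
  cat(sprintf("powder pattern: %d points, 2theta [%.2f, %.2f], lambda %.4f A\n",
              length(x$two_theta), min(x$two_theta), max(x$two_theta),
              x$wavelength))
  invisible(x)
}
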