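# Crystal structures: a lattice, the asymmetric-unit molecular placements
# (fractional centre + orientation quaternion + parity flag), and a
# space-group setting. The full unit cell is always regenerated from the
# asymmetric unit, so Monte Carlo moves on the asymmetric unit automatically
# propagate symmetry-related perturbations to the rest of the cell.

#' Create a molecular placement
#'
#' @param mol molecule name (must match a name in the structure's molecule set)
#' @param frac fractional centre-of-mass position (length 3)
#' @param quat orientation as a unit quaternion (w, x, y, z)
#' @param inv parity flag: +1 for the molecule's own geometry, -1 for its
#'   enantiomeric (inverted) copy as produced by improper symmetry operators
#' @param frozen hold this placement fixed during moves and minimization
#'   (framework molecules in fixture systems; also removes the redundant
#'   global-translation directions when everything else is frozen)
#' @return a placement list
#' @export
placement <- function(mol, frac, quat = c(1, 0, 0, 0), inv = 1,
                      frozen = FALSE) {
  list(mol = mol, frac = as.numeric(frac), quat = quat_normalize(quat),
       inv = as.integer(inv), frozen = isTRUE(frozen))
}

#' Create a crystal structure
#'
#' The Monte Carlo state of the package: lattice + asymmetric-unit placements
#' + space-group setting. `Z` (molecules per cell) is the number of asymmetric
#' placements times the number of symmetry operators.
#'
#' @param lattice an [lattice()] object
#' @param molecules named list of [rigid_molecule()] objects
#' @param placements list of [placement()]s for the asymmetric unit
#' @param setting a [spacegroup_setting()]; default P1
#' @param formula optional named integer vector declaring the stoichiometric
#'   formula unit (e.g. `c(acid = 1, base = 1)` for a co-crystal). By default
#'   the formula unit is the gcd-reduced molecular content of the unit cell.
#' @param allow_enantiomers whether improper operators may create enantiomeric
#'   copies of chiral molecules; if `FALSE`, expansion of a chiral molecule
#'   through an improper operator is an error
#' @return an object of class `crystal_structure`
#' @examples
#' co <- rigid_molecule(c("C", "O"), rbind(c(-0.6, 0, 0), c(0.6, 0, 0)))
#' s <- crystal_structure(lattice(8, 8, 8), list(CO = co),
#'                        list(placement("CO", c(0.5, 0.5, 0.5))))
#' nrow(to_cartesian(s)$coords)  # 2
#' @export
crystal_structure <- function(lattice, molecules, placements,
                              setting = builtin_setting("P1"),
                              formula = NULL, allow_enantiomers = TRUE) {
  if (is.null(names(molecules)) || any(!nzchar(names(molecules)))) {
    names(molecules) <- vapply(molecules, function(m) m$name, "")
  }
  placements <- lapply(placements, function(p) {
    if (!p$mol %in% names(molecules)) {
      stop("placement refers to unknown molecule '", p$mol, "'")
    }
    p$quat <- quat_normalize(p$quat)
    p
  })
  structure(list(
    lattice = lattice,
    molecules = molecules,
    placements = placements,
    setting = setting,
    formula = formula,
    allow_enantiomers = allow_enantiomers
  ), class = "crystal_structure")
}

#' Number of molecules in the unit cell
#' @param s a `crystal_structure`
#' @return Z = (asymmetric placements) x (symmetry operators)
#' @export
structure_z <- function(s) length(s$placements) * length(s$setting$ops)

#' Expand the asymmetric unit to the full cell
#'
#' Each symmetry operator maps every asymmetric placement to one full-cell
#' placement. Orientations are composed as (operator x orientation); improper
#' operators act through the proper part of the Cartesian operator combined
#' with an inversion of the molecular local frame (parity flag), so chiral
#' molecules acquire enantiomeric copies.
#'
#' @param s a `crystal_structure`
#' @return list of full-cell placements with fields mol, frac, quat, inv,
#'   op (operator index), asym (asymmetric placement index)
#' @export
expand_asymmetric_unit <- function(s) {
  ops <- s$setting$ops
  if (length(ops) == 1 && all(ops[[1]]$W == diag(3)) &&
      all(ops[[1]]$w == 0)) { # P1 fast path
    return(lapply(seq_along(s$placements), function(ip) {
      p <- s$placements[[ip]]
      list(mol = p$mol, frac = p$frac, quat = p$quat, inv = p$inv,
           op = 1L, asym = ip)
    }))
  }
  A <- cell_matrix(s$lattice)
  Ainv <- solve(A)
  out <- vector("list", length(s$setting$ops) * length(s$placements))
  k <- 0
  for (io in seq_along(s$setting$ops)) {
    op <- s$setting$ops[[io]]
    P <- A %*% op$W %*% Ainv
    if (max(abs(t(P) %*% P - diag(3))) > 1e-6) {
      stop("symmetry operator ", io, " is not orthogonal in this cell; ",
           "lattice incompatible with setting '", s$setting$label, "'")
    }
    dP <- det(P)
    proper <- if (dP < 0) -P else P
    qop <- quat_from_matrix(proper)
    flip <- if (dP < 0) -1L else 1L
    for (ip in seq_along(s$placements)) {
      p <- s$placements[[ip]]
      if (flip < 0 && !s$allow_enantiomers && is_chiral(s$molecules[[p$mol]])) {
        stop("improper operator applied to chiral molecule '", p$mol,
             "' with enantiomers disallowed")
      }
      k <- k + 1
      out[[k]] <- list(
        mol = p$mol,
        frac = as.numeric(op$W %*% p$frac) + op$w,
        quat = quat_normalize(quat_multiply(qop, p$quat)),
        inv = p$inv * flip,
        op = io, asym = ip
      )
    }
  }
  out
}

#' Cartesian atomic sites of the full unit cell
#'
#' Places every molecule of the expanded cell by rotating its local-frame
#' coordinates by the placement quaternion (after the parity flip, for
#' enantiomeric copies) and translating to the fractional centre.
#'
#' @param s a `crystal_structure`
#' @param wrap wrap molecular centres into [0, 1) before placing (pair
#'   distances entering lattice sums are unaffected)
#' @return list with `coords` (N x 3 Cartesian), and per-atom vectors
#'   `element`, `charge`, `type`, `molid` (molecule instance), `molname`,
#'   `atom` (atom index within its molecule)
#' @export
to_cartesian <- function(s, wrap = TRUE) {
  if (cell_volume(s$lattice) <= 0) stop("invalid cell: non-positive volume")
  A <- cell_matrix(s$lattice)
  full <- expand_asymmetric_unit(s)
  nat <- vapply(full, function(p) nrow(s$molecules[[p$mol]]$local), 0L)
  N <- sum(nat)
  coords <- matrix(0, N, 3)
  element <- character(N); charge <- numeric(N); type <- character(N)
  molid <- integer(N); molname <- character(N); atom <- integer(N)
  pos <- 0
  for (im in seq_along(full)) {
    p <- full[[im]]
    m <- s$molecules[[p$mol]]
    f <- if (wrap) wrap_frac(p$frac) else p$frac
    centre <- as.numeric(A %*% f)
    R <- quat_to_matrix(p$quat)
    xyz <- (m$local * p$inv) %*% t(R)
    xyz[, 1] <- xyz[, 1] + centre[1]
    xyz[, 2] <- xyz[, 2] + centre[2]
    xyz[, 3] <- xyz[, 3] + centre[3]
    idx <- pos + seq_len(nat[im])
    coords[idx, ] <- xyz
    element[idx] <- m$elements
    charge[idx] <- m$charges
    type[idx] <- m$types
    molid[idx] <- im
    molname[idx] <- p$mol
    atom[idx] <- seq_len(nat[im])
    pos <- pos + nat[im]
  }
  list(coords = coords, element = element, charge = charge, type = type,
       molid = molid, molname = molname, atom = atom)
}

# molecular content of the full cell as a named count vector
cell_content <- function(s) {
  full <- expand_asymmetric_unit(s)
  tab <- table(vapply(full, function(p) p$mol, ""))
  stats::setNames(as.integer(tab), names(tab))
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Number of formula units in the cell
#'
#' The formula unit is the declared stoichiometric set (see
#' [crystal_structure()]); by default the gcd-reduced cell content. Lattice
#' energies and enthalpies are reported per mole of formula units.
#' @param s a `crystal_structure`
#' @return integer count
#' @export
n_formula_units <- function(s) {
  content <- cell_content(s)
  if (is.null(s$formula)) {
    return(Reduce(gcd2, content))
  }
  f <- s$formula[names(content)]
  if (anyNA(f)) stop("declared formula does not cover the cell content")
  n <- content / f
  if (any(abs(n - round(n[1])) > 1e-9)) {
    stop("cell content is not an integer multiple of the declared formula")
  }
  as.integer(round(n[1]))
}

#' Crystal density
#' @param s a `crystal_structure`
#' @return density in g cm^-3
#' @export
structure_density <- function(s) {
  content <- cell_content(s)
  mass <- sum(vapply(names(content), function(nm) {
    content[[nm]] * molecule_mass(s$molecules[[nm]])
  }, 0))
  1.66053906660 * mass / cell_volume(s$lattice)
}

#' Expand a structure to P1
#'
#' Re-describes the structure with every molecule of the unit cell as an
#' independent placement and only the identity operator. Frozen-degree flags
#' of the original setting (fixed cell, frozen orientations) are carried
#' over.
#' @param s a `crystal_structure`
#' @return equivalent `crystal_structure` in P1
#' @export
as_p1 <- function(s) {
  full <- expand_asymmetric_unit(s)
  p1 <- builtin_setting("P1")
  # symmetry constraints are lifted: all cell parameters become free, unless
  # the source setting froze the cell entirely (fixture landscapes)
  if (!any(s$setting$cell_free)) p1$cell_free <- rep(FALSE, 6)
  p1$rotations_free <- s$setting$rotations_free
  p1$translations_free <- s$setting$translations_free
  crystal_structure(s$lattice, s$molecules,
                    lapply(full, function(p) placement(p$mol, p$frac, p$quat, p$inv)),
                    setting = p1, formula = s$formula,
                    allow_enantiomers = s$allow_enantiomers)
}

#' Re-describe a structure in a transformed cell
#'
#' Applies an integer basis transformation `M` (columns express the new
#' lattice vectors in units of the old: `A_new = A_old M`), remapping
#' fractional centres and rotating orientations into the canonical Cartesian
#' frame of the new cell. With `det(M) = 1` this is a pure re-description of
#' the same crystal (used to test matcher invariance); `det(M) > 1` builds
#' supercells, in which case the cell content is replicated over the sublattice
#' translations. The result is expressed in P1.
#'
#' @param s a `crystal_structure`
#' @param M 3x3 integer matrix with positive determinant
#' @return re-described `crystal_structure` in P1
#' @export
transform_cell <- function(s, M) {
  M <- matrix(as.numeric(M), 3, 3)
  dM <- det(M)
  if (abs(dM - round(dM)) > 1e-9 || round(dM) < 1) {
    stop("M must be an integer matrix with positive determinant")
  }
  nrep <- as.integer(round(dM))
  A <- cell_matrix(s$lattice)
  V <- A %*% M
  len <- sqrt(colSums(V^2))
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  lat_new <- lattice(len[1], len[2], len[3],
                     ang(V[, 2], V[, 3]), ang(V[, 1], V[, 3]), ang(V[, 1], V[, 2]))
  Anew <- cell_matrix(lat_new)
  Q <- Anew %*% solve(V) # rotation into the canonical frame of the new cell
  if (abs(det(Q) - 1) > 1e-6) stop("transformation does not preserve handedness")
  qQ <- quat_from_matrix(Q)
  Minv <- solve(M)
  full <- expand_asymmetric_unit(s)
  # translations of the old lattice that are interior points of the new cell
  reps <- list(c(0, 0, 0))
  if (nrep > 1) {
    rng <- -max(abs(M)):max(abs(M))
    cand <- as.matrix(expand.grid(rng, rng, rng))
    tfrac <- cand %*% t(Minv)
    inside <- apply(tfrac, 1, function(f) all(f > -1e-9 & f < 1 - 1e-9))
    reps <- lapply(which(inside), function(i) cand[i, ])
    if (length(reps) != nrep) stop("internal error enumerating sublattice translations")
  }
  placements <- list()
  for (tr in reps) for (p in full) {
    placements[[length(placements) + 1]] <- placement(
      p$mol, as.numeric(Minv %*% (p$frac + tr)),
      quat_multiply(qQ, p$quat), p$inv)
  }
  crystal_structure(lat_new, s$molecules, placements,
                    setting = builtin_setting("P1"), formula = s$formula,
                    allow_enantiomers = s$allow_enantiomers)
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure [%s]: Z=%d (%d asym x %d ops), V=%.2f A^3, rho=%.3f g/cm^3\n",
              x$setting$label, structure_z(x), length(x$placements),
              length(x$setting$ops), cell_volume(x$lattice), structure_density(x)))
  print(x$lattice)
  invisible(x)
}
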