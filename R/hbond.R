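# Hydrogen-bond motif classification. A hydrogen bond is an intermolecular
# H...A contact with separation strictly below the sum of van der Waals radii
# plus 0.1 Angstrom and a D-H...A angle strictly above 125 degrees. Bonds are
# aggregated into a molecule-level graph whose vertices are the molecules of
# the unit cell and whose edges carry the lattice translation of the acceptor
# image; a connected component that closes a cycle with nonzero net
# translation is infinite under periodicity.

#' Classify the hydrogen-bond motif of a structure
#'
#' Labels: "dimer" when every molecule belongs to a doubly-bonded pair (two
#' molecules linked by exactly two reciprocal bonds), "chain" when every
#' molecule lies on an infinite path (periodic component, all degrees <= 2),
#' otherwise "other".
#'
#' @param s a [crystal_structure()]
#' @param donors data.frame with columns `mol` (molecule name), `d` (donor
#'   heavy-atom index within the molecule), `h` (donor hydrogen index)
#' @param acceptors data.frame with columns `mol`, `a` (acceptor atom index)
#' @param vdw named van der Waals radii [Angstrom]; defaults to the built-in
#'   table
#' @param margin distance margin added to the vdW-radius sum (0.1)
#' @param angle_min D-H...A angle threshold [degrees] (125, strict)
#' @return list with `motif`, `bonds` (data.frame donor_mol, acceptor_mol,
#'   shift columns, distance, angle) and `components` (per-component size,
#'   bonds, periodic flag, label)
#' @export
classify_hbond_motif <- function(s, donors, acceptors, vdw = VDW_RADII,
                                 margin = 0.1, angle_min = 125) {
  if (is.null(donors) || nrow(donors) == 0 ||
      is.null(acceptors) || nrow(acceptors) == 0) {
    stop("donor and acceptor specifications are required")
  }
  sites <- to_cartesian(s)
  z <- max(sites$molid)
  # global indices of donor H / D and acceptor atoms per molecule instance
  hsel <- integer(0); dsel <- integer(0); asel <- integer(0)
  for (r in seq_len(nrow(donors))) {
    ix <- which(sites$molname == donors$mol[r] & sites$atom == donors$h[r])
    hsel <- c(hsel, ix)
    dsel <- c(dsel, which(sites$molname == donors$mol[r] &
                            sites$atom == donors$d[r]))
  }
  for (r in seq_len(nrow(acceptors))) {
    asel <- c(asel, which(sites$molname == acceptors$mol[r] &
                            sites$atom == acceptors$a[r]))
  }
  rH <- lookup_table(vdw, sites$element[hsel], "vdW radius")
  rA <- lookup_table(vdw, sites$element[asel], "vdW radius")
  dmax <- max(outer(rH, rA, "+")) + margin
  A <- cell_matrix(s$lattice)
  contacts <- cpp_contact_list(sites$coords, sites$molid, A, dmax)
  bonds <- list()
  if (nrow(contacts)) {
    hmatch <- match(contacts[, "i"], hsel)
    amatch <- match(contacts[, "j"], asel)
    cand <- which(!is.na(hmatch) & !is.na(amatch))
    for (k in cand) {
      i <- contacts[k, "i"]; j <- contacts[k, "j"]
      thr <- vdw[[sites$element[i]]] + vdw[[sites$element[j]]] + margin
      if (!(contacts[k, "dist"] < thr)) next # strict inequality
      shift <- contacts[k, c("sa", "sb", "sc")]
      apos <- sites$coords[j, ] + as.numeric(A %*% shift)
      dpos <- sites$coords[dsel[hmatch[k]], ]
      hpos <- sites$coords[i, ]
      v1 <- dpos - hpos; v2 <- apos - hpos
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (!(ang > angle_min)) next # strict inequality
      bonds[[length(bonds) + 1]] <- c(donor_mol = sites$molid[i],
                                      acceptor_mol = sites$molid[j],
                                      sa = shift[1], sb = shift[2], sc = shift[3],
                                      dist = contacts[k, "dist"], angle = ang)
    }
  }
  if (!length(bonds)) {
    return(list(motif = "other",
                bonds = data.frame(donor_mol = integer(0)),
                components = data.frame()))
  }
  bdf <- as.data.frame(do.call(rbind, bonds))
  names(bdf) <- c("donor_mol", "acceptor_mol", "sa", "sb", "sc", "dist", "angle")
  comp <- hbond_components(bdf, z)
  labels <- comp$label[comp$bonds > 0]
  bonded_mols <- unique(c(bdf$donor_mol, bdf$acceptor_mol))
  motif <- if (length(bonded_mols) == z && length(unique(labels)) == 1) {
    unique(labels)
  } else {
    "other"
  }
  list(motif = motif, bonds = bdf, components = comp)
}

# connected components of the molecule-level bond graph under periodicity;
# BFS assigns each molecule a net lattice offset, and an edge closing a cycle
# with inconsistent offset marks the component as periodic (infinite)
hbond_components <- function(bdf, z) {
  comp_id <- rep(NA_integer_, z)
  offset <- matrix(NA_real_, z, 3)
  periodic <- logical(0)
  sizes <- integer(0); nbonds <- integer(0)
  ncomp <- 0
  adj <- lapply(seq_len(z), function(i) {
    rows <- which(bdf$donor_mol == i | bdf$acceptor_mol == i)
    rows
  })
  for (start in seq_len(z)) {
    if (!is.na(comp_id[start])) next
    ncomp <- ncomp + 1
    comp_id[start] <- ncomp
    offset[start, ] <- c(0, 0, 0)
    per <- FALSE
    queue <- start
    members <- start
    edges_seen <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        edges_seen <- union(edges_seen, e)
        dm <- bdf$donor_mol[e]; am <- bdf$acceptor_mol[e]
        sh <- as.numeric(bdf[e, c("sa", "sb", "sc")])
        if (v == dm) { u <- am; du <- offset[v, ] + sh }
        else { u <- dm; du <- offset[v, ] - sh }
        if (is.na(comp_id[u])) {
          comp_id[u] <- ncomp
          offset[u, ] <- du
          members <- c(members, u)
          queue <- c(queue, u)
        } else if (max(abs(offset[u, ] - du)) > 1e-9) {
          per <- TRUE # cycle with nonzero net lattice translation
        }
      }
    }
    sizes[ncomp] <- length(members)
    nbonds[ncomp] <- length(edges_seen)
    periodic[ncomp] <- per
  }
  degree <- vapply(seq_len(z), function(i) length(adj[[i]]), 0L)
  label <- character(ncomp)
  for (k in seq_len(ncomp)) {
    mem <- which(comp_id == k)
    if (!periodic[k] && sizes[k] == 2 && nbonds[k] == 2) {
      label[k] <- "dimer"
    } else if (periodic[k] && all(degree[mem] <= 2)) {
      label[k] <- "chain"
    } else {
      label[k] <- "other"
    }
  }
  data.frame(component = seq_len(ncomp), size = sizes, bonds = nbonds,
             periodic = periodic, label = label)
}
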