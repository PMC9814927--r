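# Lattice energy of a rigid-molecule crystal:
#   E = 1/2 sum over molecule pairs and periodic images of
#       [ A exp(-B r) - C r^-6 + q_i q_k / r ]
# per mole of formula units. Intramolecular pairs are excluded entirely
# (rigid bodies). exp-6 terms and, for consistency of the cutoff rule, the
# real-space part of the electrostatics are summed to
# R_cutoff = max(15 Angstrom, R_intra); charge-charge electrostatics use Ewald
# summation (tinfoil boundary) with parameters chosen from a target accuracy.

#' Energy evaluation settings
#'
#' @param cutoff direct-space cutoff floor [Angstrom]; the effective cutoff is
#'   `max(cutoff, R_intra)` with `R_intra` the largest intramolecular
#'   atom-atom distance of any molecule in the cell. Must be >= 15.
#' @param ewald_accuracy target truncation accuracy of the Ewald sum
#'   (dimensionless; relative weight of discarded tails)
#' @param taper_width width of the smoothstep switching window below the
#'   cutoff over which exp-6 terms are tapered to zero [Angstrom]; keeps the
#'   energy C1-continuous as pairs cross the cutoff (0 = hard cutoff)
#' @param contact_margin close-contact margin added to the sum of covalent
#'   radii [Angstrom]
#' @param pressure external pressure [GPa] entering [enthalpy()]
#' @param pressure_step pressure applied in step 2 of the three-step
#'   minimization [GPa]
#' @param gtol convergence threshold on the maximum finite-difference gradient
#'   component [kJ/mol per coordinate unit]
#' @return an `energy_settings` object
#' @export
energy_settings <- function(cutoff = 15, ewald_accuracy = 1e-7,
                            taper_width = 2, contact_margin = 0.3,
                            pressure = 0, pressure_step = 0.1, gtol = 1e-4) {
  if (cutoff < 15) stop("cutoff must be at least 15 Angstrom")
  if (contact_margin < 0) stop("contact margin must be >= 0")
  if (taper_width < 0 || taper_width > cutoff / 2) {
    stop("taper width must lie in [0, cutoff/2]")
  }
  structure(list(cutoff = cutoff, ewald_accuracy = ewald_accuracy,
                 taper_width = taper_width, contact_margin = contact_margin,
                 pressure = pressure, pressure_step = pressure_step,
                 gtol = gtol),
            class = "energy_settings")
}

effective_cutoff <- function(s, settings) {
  rintra <- max(vapply(s$molecules, intramolecular_radius, 0))
  max(settings$cutoff, rintra)
}

# Per-molecule-type intramolecular charge pairs (qq products and rigid
# distances), needed for the Ewald intramolecular correction.
intra_charge_pairs <- function(mol) {
  n <- nrow(mol$local)
  if (n < 2) return(list(qq = numeric(0), r = numeric(0)))
  idx <- utils::combn(n, 2)
  r <- sqrt(rowSums((mol$local[idx[1, ], , drop = FALSE] -
                     mol$local[idx[2, ], , drop = FALSE])^2))
  list(qq = mol$charges[idx[1, ]] * mol$charges[idx[2, ]], r = r)
}

#' Lattice energy
#'
#' @param s a [crystal_structure()]
#' @param ff a [force_field()]
#' @param settings an [energy_settings()]
#' @param components return the individual energy components as an attribute
#' @param nfu formula-unit count, when already known by the caller (skips
#'   recomputing it from the cell content)
#' @return energy in kJ per mole of formula units
#' @export
lattice_energy <- function(s, ff, settings = energy_settings(),
                           components = FALSE, nfu = NULL) {
  sites <- to_cartesian(s)
  type_id <- match(sites$type, ff$types)
  if (anyNA(type_id)) {
    stop("atom type(s) not present in force field: ",
         paste(unique(sites$type[is.na(type_id)]), collapse = ", "))
  }
  A <- cell_matrix(s$lattice)
  cutoff <- effective_cutoff(s, settings)
  q <- sites$charge
  has_charges <- any(abs(q) > 1e-12)
  alpha <- 0; elec_mode <- 0L
  if (has_charges) {
    if (abs(sum(q)) > 1e-8) {
      stop("non-neutral unit cell (net charge ", signif(sum(q), 4),
           " e) with charge-only electrostatics")
    }
    eps <- settings$ewald_accuracy
    alpha <- sqrt(-log(eps)) / cutoff
    elec_mode <- 1L
  }
  direct <- cpp_direct_sum(sites$coords, sites$molid, type_id, q, A, cutoff,
                           ff$A, ff$B, ff$C, ff$rcat, ff$fcat, ff$clamp_slope,
                           alpha, elec_mode, settings$taper_width, ff$rexp)
  e_elec <- 0
  content_names <- sites$molname[!duplicated(sites$molid)]
  if (has_charges) {
    eps <- settings$ewald_accuracy
    kcut <- 2 * alpha * sqrt(-log(eps))
    recip <- cpp_ewald_recip(sites$coords, q, A, alpha, kcut)
    self <- alpha / sqrt(pi) * sum(q^2)
    # subtract the reciprocal-space contribution of rigid intramolecular pairs
    content <- table(content_names)
    intra <- 0
    for (nm in names(content)) {
      ip <- intra_charge_pairs(s$molecules[[nm]])
      if (length(ip$r)) {
        intra <- intra + content[[nm]] * sum(ip$qq * erf(alpha * ip$r) / ip$r)
      }
    }
    e_elec <- KE_COULOMB * (direct$elec_real + recip - self - intra)
  }
  # formula units from the already-expanded sites (avoids a second expansion)
  if (is.null(nfu)) {
    nfu <- if (is.null(s$formula)) {
      Reduce(gcd2, as.integer(table(content_names)))
    } else {
      n_formula_units(s)
    }
  }
  e <- (direct$exp6 + e_elec) / nfu
  if (components) {
    attr(e, "components") <- c(exp6 = direct$exp6 / nfu, elec = e_elec / nfu)
  }
  e
}

#' Close-contact check
#'
#' A structure fails when any intermolecular atom-atom distance (including
#' periodic images) is strictly shorter than the sum of the two covalent radii
#' plus the margin. Monte Carlo moves producing such contacts are rejected
#' before any energy evaluation.
#'
#' @param s a [crystal_structure()]
#' @param ff a [force_field()] (source of covalent radii)
#' @param margin margin added to the covalent-radius sum [Angstrom]
#' @return list with `ok` (logical), `distance` and `threshold` of the worst
#'   pair, `pair` (atom indices) and `elements`
#' @export
check_close_contacts <- function(s, ff, margin = 0.3) {
  sites <- to_cartesian(s)
  elems <- sort(unique(sites$element))
  rc <- lookup_table(ff$cov_radii, elems, "covalent radius")
  thr <- outer(rc, rc, "+") + margin
  eid <- match(sites$element, elems)
  res <- cpp_min_contact(sites$coords, sites$molid, eid, thr,
                         cell_matrix(s$lattice), max(thr) + 1)
  i <- res[2]; j <- res[3]
  if (i == 0) {
    return(list(ok = TRUE, distance = NA_real_, threshold = NA_real_,
                pair = NULL, elements = NULL))
  }
  list(ok = res[1] >= 0, distance = res[4],
       threshold = thr[eid[i], eid[j]],
       pair = c(i, j), elements = sites$element[c(i, j)])
}

#' Enthalpy at an applied pressure
#'
#' `E_lattice + P V / n_fu`, with the pressure-volume term converted through
#' 1 GPa Angstrom^3 = 0.6022140857 kJ/mol. This is the objective of step 2 of
#' the three-step minimization.
#' @param s a [crystal_structure()]
#' @param ff a [force_field()]
#' @param settings an [energy_settings()]
#' @param pressure pressure in GPa
#' @return enthalpy in kJ per mole of formula units
#' @export
enthalpy <- function(s, ff, settings = energy_settings(), pressure = 0) {
  v <- cell_volume(s$lattice)
  if (v <= 0) stop("invalid cell: non-positive volume")
  lattice_energy(s, ff, settings) +
    pressure * v * GPA_A3_TO_KJMOL / n_formula_units(s)
}
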