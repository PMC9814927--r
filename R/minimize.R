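# Three-step local minimization of the lattice energy over the free rigid-body
# and cell degrees of freedom:
#   (1) minimize E at zero pressure (strictly downhill from the input, so no
#       barrier is crossed during minimization),
#   (2) minimize the enthalpy E + P V at a small pressure (default 0.1 GPa) to
#       collapse artificial voids left by lid-limited sampling,
#   (3) re-minimize at zero pressure to report an energy on the original
#       landscape.
# Quasi-Newton (L-BFGS-B) on a reduced coordinate vector with finite-difference
# gradients; orientation steps are rotation vectors composed onto the current
# quaternion, so quaternions stay unit by construction.

# reduced coordinate packing ------------------------------------------------

pack_state <- function(s) {
  free <- s$setting$cell_free
  pvec <- unlist(s$lattice[c("a", "b", "c", "alpha", "beta", "gamma")])
  x <- as.numeric(pvec[free])
  # box bounds follow the free-parameter order: lengths in [2, 500] Angstrom,
  # angles in [45, angle_upper] degrees (flat-cell guard); `scale` holds the
  # Angstrom-equivalent of one unit of each coordinate so trust radii and
  # difference steps can be expressed in physical units
  lower <- ifelse(which(free) <= 3, 2, 45)
  upper <- ifelse(which(free) <= 3, 500, s$setting$angle_upper)
  scale <- ifelse(which(free) <= 3, 1, 0.2) # 1 deg of cell angle ~ 0.2 A
  lens <- unname(c(s$lattice$a, s$lattice$b, s$lattice$c))
  q0 <- list()
  for (ip in seq_along(s$placements)) {
    p <- s$placements[[ip]]
    if (isTRUE(p$frozen)) { q0[[ip]] <- p$quat; next }
    if (s$setting$translations_free) {
      x <- c(x, p$frac)
      lower <- c(lower, rep(-Inf, 3)); upper <- c(upper, rep(Inf, 3))
      scale <- c(scale, lens) # 1 fractional unit ~ one cell length
    }
    if (s$setting$rotations_free) {
      x <- c(x, c(0, 0, 0))
      lower <- c(lower, rep(-pi, 3)); upper <- c(upper, rep(pi, 3))
      scale <- c(scale, rep(1.5, 3)) # 1 rad rotation ~ 1.5 A at the periphery
    }
    q0[[ip]] <- p$quat
  }
  list(x = x, q0 = q0, free = free, lower = lower, upper = upper,
       scale = scale)
}

unpack_state <- function(x, meta, s) {
  free <- meta$free
  nfree <- sum(free)
  pvec <- unlist(s$lattice[c("a", "b", "c", "alpha", "beta", "gamma")])
  pvec[free] <- x[seq_len(nfree)]
  s$lattice <- lattice(pvec[1], pvec[2], pvec[3], pvec[4], pvec[5], pvec[6])
  k <- nfree
  for (ip in seq_along(s$placements)) {
    if (isTRUE(s$placements[[ip]]$frozen)) next
    if (s$setting$translations_free) {
      s$placements[[ip]]$frac <- x[k + 1:3]
      k <- k + 3
    }
    if (s$setting$rotations_free) {
      s$placements[[ip]]$quat <- quat_normalize(
        quat_multiply(quat_from_rotvec(x[k + 1:3]), meta$q0[[ip]]))
      k <- k + 3
    }
  }
  s
}

min_objective <- function(s0, meta, ff, settings, pressure) {
  nfu_cache <- n_formula_units(s0)
  function(x) {
    val <- tryCatch({
      s <- unpack_state(x, meta, s0)
      e <- lattice_energy(s, ff, settings, nfu = nfu_cache)
      if (pressure != 0) {
        e <- e + pressure * cell_volume(s$lattice) * GPA_A3_TO_KJMOL / nfu_cache
      }
      e
    }, error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }
}

fd_gradient <- function(fn, x, h = 1e-5) {
  h <- rep_len(h, length(x))
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h[i]; xm[i] <- xm[i] - h[i]
    (fn(xp) - fn(xm)) / (2 * h[i])
  }, 0)
}

# One minimization stage. The optimizer runs in trust-region segments: each
# L-BFGS-B call is box-constrained to +/- `trust` around the current point
# (in the reduced coordinates), so a single segment can never jump across a
# repulsive ridge wider than the trust radius — the descent path stays inside
# the starting basin, which the threshold method's correctness relies on.
minimize_stage <- function(s, ff, settings, pressure, maxit, restarts = 2,
                           trust = 0.4) {
  nseg <- if (is.finite(trust)) 60L else 1L
  meta0 <- pack_state(s)
  if (length(meta0$x) == 0) { # everything frozen
    return(list(structure = s, value = min_objective(s, meta0, ff, settings,
                                                     pressure)(numeric(0)),
                grad_norm = 0, converged = TRUE))
  }
  res <- NULL; gmax <- Inf
  for (attempt in 0:restarts) {
    for (seg in seq_len(nseg)) {
      meta <- pack_state(s)
      fn <- min_objective(s, meta, ff, settings, pressure)
      if (is.finite(trust)) {
        tr <- trust / meta$scale # physical trust radius per coordinate
        lo <- pmax(meta$lower, meta$x - tr)
        hi <- pmin(meta$upper, meta$x + tr)
      } else {
        lo <- meta$lower; hi <- meta$upper
      }
      # forward differences inside the optimizer (half the evaluations);
      # the convergence check below still uses central differences
      hfd <- 1e-5 / meta$scale
      gr <- function(x) {
        f0 <- fn(x)
        vapply(seq_along(x), function(i) {
          xp <- x; xp[i] <- xp[i] + hfd[i]
          (fn(xp) - f0) / hfd[i]
        }, 0)
      }
      res <- stats::optim(meta$x, fn, gr, method = "L-BFGS-B",
                          lower = lo, upper = hi,
                          control = list(maxit = maxit, factr = 10,
                                         pgtol = settings$gtol / 10))
      moved <- max(abs((res$par - meta$x) * meta$scale))
      s <- unpack_state(res$par, meta, s)
      # finished when the segment did not run into its trust boundary
      if (moved < trust - 1e-9) break
    }
    meta <- pack_state(s)
    fn <- min_objective(s, meta, ff, settings, pressure)
    g <- fd_gradient(fn, meta$x, h = 1e-5 / meta$scale) / meta$scale
    # ignore gradient components pressing against an active outer bound
    at_lo <- meta$x <= meta$lower + 1e-9 & g > 0
    at_hi <- meta$x >= meta$upper - 1e-9 & g < 0
    g[at_lo | at_hi] <- 0
    gmax <- max(abs(g)) # kJ/mol per Angstrom-equivalent coordinate
    if (gmax < settings$gtol) {
      return(list(structure = s, value = res$value, grad_norm = gmax,
                  converged = TRUE))
    }
  }
  list(structure = s, value = res$value, grad_norm = gmax, converged = FALSE)
}

#' Three-step local minimization
#'
#' @param s a [crystal_structure()]; must pass [check_close_contacts()]
#' @param ff a [force_field()]
#' @param settings an [energy_settings()]; `pressure_step` sets the step-2
#'   pressure and `gtol` the convergence threshold
#' @param maxit maximum iterations per stage
#' @param trust trust radius [Angstrom-equivalent per coordinate]: each
#'   optimizer segment is box-constrained to this radius around its starting
#'   point, so descent cannot jump across repulsive ridges wider than the
#'   radius (required for the threshold method, whose registry must only
#'   receive the minimum of the basin the walker actually sits in). Use
#'   `Inf` for unconstrained descent when any minimum is acceptable (e.g.
#'   during structure prediction).
#' @return a `lattice_energy_result`: list with `energy` (step-3 zero-pressure
#'   energy, kJ per mole of formula units), `converged`, `grad_norm`,
#'   `structure` (minimized), `input_energy`, and `steps` (energies after each
#'   stage). If the pressure excursion of steps 2-3 ends above the step-1
#'   energy, the step-1 result is returned (the excursion is discarded).
#' @export
minimize_structure <- function(s, ff, settings = energy_settings(), maxit = 300,
                               trust = 0.4) {
  cc <- check_close_contacts(s, ff, settings$contact_margin)
  if (!cc$ok) {
    stop(sprintf("close contact %s-%s at %.3f A (threshold %.3f A): minimization precondition violated",
                 cc$elements[1], cc$elements[2], cc$distance, cc$threshold))
  }
  e_in <- lattice_energy(s, ff, settings)
  st1 <- minimize_stage(s, ff, settings, 0, maxit, trust = trust)
  if (!any(s$setting$cell_free)) {
    # frozen cell: pressure acts on the volume only, so steps 2-3 would
    # reproduce step 1 exactly
    st2 <- st1
    st3 <- st1
  } else {
    st2 <- minimize_stage(st1$structure, ff, settings, settings$pressure_step,
                          maxit, trust = trust)
    st3 <- minimize_stage(st2$structure, ff, settings, 0, maxit, trust = trust)
  }
  if (st3$value <= st1$value + 1e-9) {
    final <- st3
  } else {
    final <- st1 # pressure excursion went uphill on the true landscape
  }
  structure(list(
    energy = final$value,
    converged = final$converged,
    grad_norm = final$grad_norm,
    structure = final$structure,
    input_energy = e_in,
    steps = c(step1 = st1$value, step2 = st2$value, step3 = st3$value)
  ), class = "lattice_energy_result")
}

#' @export
print.lattice_energy_result <- function(x, ...) {
  cat(sprintf("minimized lattice energy: %.6f kJ/mol per formula unit (%s, |grad|max %.2e)\n",
              x$energy, if (x$converged) "converged" else "NOT converged",
              x$grad_norm))
  invisible(x)
}
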