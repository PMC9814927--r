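# The five perturbation types of the threshold simulations: molecular
# translation, molecular rotation, unit-cell length, unit-cell angle, and
# unit-cell volume changes. Step sizes are uniform within a per-type cutoff
# except cell angles, which follow a symmetric triangular distribution whose
# centre is pulled towards 90 degrees (flat-cell avoidance; this intentionally
# breaks detailed balance — the goal is structure exploration, not ensemble
# sampling). Moves perturb the asymmetric unit only; symmetry-related
# molecules follow through the expansion machinery.

#' Move specification
#'
#' Default cutoffs: 0.50 Angstrom (translation), 0.05 rad (rotation),
#' 0.50 Angstrom (cell length), 0.50 degree (cell angle) and 25 Angstrom^3
#' per molecule in the cell (volume; the actual maximum change is Z x 25).
#'
#' @param translation,rotation,cell_length,cell_angle,volume move cutoffs
#' @param probabilities optional named probabilities per move type; by default
#'   proportional to the number of degrees of freedom of each type
#' @param max_angle_retries bounded resampling attempts for out-of-range angle
#'   proposals before the move is skipped
#' @return a `move_spec`
#' @export
move_spec <- function(translation = 0.50, rotation = 0.05, cell_length = 0.50,
                      cell_angle = 0.50, volume = 25,
                      probabilities = NULL, max_angle_retries = 20) {
  cut <- c(translation = translation, rotation = rotation,
           cell_length = cell_length, cell_angle = cell_angle, volume = volume)
  if (any(cut <= 0)) stop("all move cutoffs must be positive")
  if (!is.null(probabilities)) {
    probabilities <- probabilities / sum(probabilities)
  }
  structure(list(cutoffs = cut, probabilities = probabilities,
                 max_angle_retries = max_angle_retries), class = "move_spec")
}

#' Degrees of freedom per move type
#'
#' 3 translational and 3 rotational degrees of freedom per asymmetric
#' molecule, one per free cell length/angle, and one for the volume; frozen
#' subsets (see [constrain_setting()]) contribute zero.
#' @param s a [crystal_structure()]
#' @return named integer vector over the five move types
#' @export
move_dof <- function(s) {
  nasym <- sum(!vapply(s$placements, function(p) isTRUE(p$frozen), TRUE))
  st <- s$setting
  c(translation = if (st$translations_free) 3L * nasym else 0L,
    rotation = if (st$rotations_free) 3L * nasym else 0L,
    cell_length = sum(st$cell_free[1:3]),
    cell_angle = sum(st$cell_free[4:6]),
    volume = if (any(st$cell_free[1:3])) 1L else 0L)
}

#' Select a move type
#'
#' Samples a move type with probability proportional to its share of the
#' total degrees of freedom (or the explicit per-type probabilities of the
#' move specification).
#' @param spec a [move_spec()]
#' @param s a [crystal_structure()]
#' @return move type name
#' @export
select_move_type <- function(spec, s) {
  if (!is.null(spec$probabilities)) {
    p <- spec$probabilities
  } else {
    dof <- move_dof(s)
    if (sum(dof) == 0) stop("no degrees of freedom: all move types frozen")
    p <- dof / sum(dof)
  }
  p <- p[p > 0]
  sample(names(p), 1, prob = p)
}

#' Triangular-biased cell-angle proposal
#'
#' The proposal centre is pulled linearly towards 90 degrees
#' (centre = current + kappa (90 - current), kappa = cutoff/45) and triangular
#' noise of half-width `cutoff` is added, giving a symmetric triangular
#' density peaked at the shifted centre.
#' @param current current angle [degrees]
#' @param cutoff angle move cutoff [degrees]
#' @return proposed new angle [degrees]
#' @export
angle_bias_distribution <- function(current, cutoff = 0.5) {
  centre <- current + (cutoff / 45) * (90 - current)
  centre + (stats::runif(1) + stats::runif(1) - 1) * cutoff
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Propose a Monte Carlo move
#'
#' @param s a [crystal_structure()]
#' @param spec a [move_spec()]
#' @param type optional move type (sampled by [select_move_type()] if missing)
#' @return a `move_proposal`: list with `structure` (perturbed), `type`,
#'   `target` (molecule index or cell-parameter name), `payload` (the raw
#'   perturbation) and `skipped` (TRUE when an angle move exhausted its
#'   retries)
#' @export
propose_move <- function(s, spec = move_spec(), type = NULL) {
  if (is.null(type)) type <- select_move_type(spec, s)
  cut <- spec$cutoffs
  out <- list(structure = s, type = type, target = NA, payload = NULL,
              skipped = FALSE)
  pnames <- c("a", "b", "c", "alpha", "beta", "gamma")
  movable <- which(!vapply(s$placements, function(p) isTRUE(p$frozen), TRUE))
  if (type == "translation") {
    i <- if (length(movable) == 1) movable else sample(movable, 1)
    dirn <- random_unit_vector()
    mag <- stats::runif(1) * cut["translation"]
    dcart <- dirn * mag
    dfrac <- as.numeric(solve(cell_matrix(s$lattice)) %*% dcart)
    s$placements[[i]]$frac <- s$placements[[i]]$frac + dfrac
    out$target <- i; out$payload <- dcart
  } else if (type == "rotation") {
    i <- if (length(movable) == 1) movable else sample(movable, 1)
    axis <- random_unit_vector()
    ang <- stats::runif(1) * cut["rotation"]
    s$placements[[i]]$quat <- quat_normalize(
      quat_multiply(quat_from_axis_angle(axis, ang), s$placements[[i]]$quat))
    out$target <- i; out$payload <- axis * ang
  } else if (type == "cell_length") {
    free <- which(s$setting$cell_free[1:3])
    j <- if (length(free) == 1) free else sample(free, 1)
    d <- sign(stats::runif(1) - 0.5) * stats::runif(1) * cut["cell_length"]
    p <- s$lattice[[pnames[j]]] + d
    if (p <= 0.5) return(modifyList(out, list(skipped = TRUE)))
    s$lattice[[pnames[j]]] <- p
    out$target <- pnames[j]; out$payload <- d
  } else if (type == "cell_angle") {
    free <- which(s$setting$cell_free[4:6])
    if (length(free) == 0) stop("no free cell angles in this setting")
    j <- if (length(free) == 1) free else sample(free, 1)
    nm <- pnames[3 + j]
    ok <- FALSE
    for (k in seq_len(spec$max_angle_retries)) {
      newa <- angle_bias_distribution(s$lattice[[nm]], cut["cell_angle"])
      if (newa >= 45 && newa <= s$setting$angle_upper) { ok <- TRUE; break }
    }
    if (!ok) return(modifyList(out, list(skipped = TRUE)))
    out$payload <- newa - s$lattice[[nm]]
    s$lattice[[nm]] <- newa
    out$target <- nm
  } else if (type == "volume") {
    v0 <- cell_volume(s$lattice)
    z <- structure_z(s)
    dv <- sign(stats::runif(1) - 0.5) * stats::runif(1) * z * cut["volume"]
    v1 <- v0 + dv
    if (v1 <= 0.1 * v0) return(modifyList(out, list(skipped = TRUE)))
    f <- (v1 / v0)^(1 / 3)
    # isotropic scaling: lengths scale, angles and fractional centres fixed,
    # so Cartesian molecular centres scale by f and geometries are untouched
    s$lattice$a <- s$lattice$a * f
    s$lattice$b <- s$lattice$b * f
    s$lattice$c <- s$lattice$c * f
    out$target <- "volume"; out$payload <- dv
  } else {
    stop("unknown move type: ", type)
  }
  out$structure <- s
  out
}
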