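# Space-group settings: a closed set of symmetry operators (fractional
# rotation part W plus translation w), the cell-parameter constraint pattern of
# the crystal system, and bookkeeping flags used by the move generator. The
# package does no space-group determination; settings are operator bookkeeping
# for the sampling and expansion machinery.

#' Create a space-group setting
#'
#' @param label setting label (e.g. "P1", "P21/c")
#' @param ops list of operators, each `list(W = 3x3 integer matrix, w = length-3
#'   fractional translation)`. The identity must be present and the set closed
#'   under composition modulo lattice translations.
#' @param cell_free logical length-6 vector over (a, b, c, alpha, beta, gamma):
#'   which parameters a cell move may change
#' @param cell_fixed named numeric vector of fixed parameter values (e.g.
#'   `c(alpha = 90, gamma = 90)` for monoclinic)
#' @param angle_upper upper validity bound for cell angles in degrees (135;
#'   120 for trigonal settings)
#' @param translations_free,rotations_free whether molecular translation /
#'   rotation moves are allowed (fixture landscapes freeze subsets of the
#'   degrees of freedom to keep their oracles low-dimensional)
#' @return an object of class `spacegroup_setting`
#' @export
spacegroup_setting <- function(label, ops,
                               cell_free = rep(TRUE, 6),
                               cell_fixed = numeric(0),
                               angle_upper = 135,
                               translations_free = TRUE,
                               rotations_free = TRUE) {
  stopifnot(length(cell_free) == 6)
  ops <- lapply(ops, function(o) {
    W <- matrix(as.numeric(o$W), 3, 3)
    list(W = W, w = as.numeric(o$w) %% 1)
  })
  st <- structure(list(
    label = label, ops = ops,
    cell_free = cell_free,
    cell_fixed = cell_fixed,
    angle_upper = angle_upper,
    translations_free = translations_free,
    rotations_free = rotations_free
  ), class = "spacegroup_setting")
  check_operator_closure(st)
  st
}

op_key <- function(W, w) {
  paste(c(round(W), round(w %% 1, 6)), collapse = ",")
}

# operators must contain the identity and be closed under composition modulo
# lattice translations
check_operator_closure <- function(setting) {
  ops <- setting$ops
  keys <- vapply(ops, function(o) op_key(o$W, o$w), "")
  if (anyDuplicated(keys)) stop("duplicate symmetry operators in setting")
  id <- op_key(diag(3), c(0, 0, 0))
  if (!id %in% keys) stop("identity operator missing from setting")
  for (o1 in ops) for (o2 in ops) {
    W <- o1$W %*% o2$W
    w <- as.numeric(o1$W %*% o2$w) + o1$w
    if (!op_key(W, w) %in% keys) {
      stop("operator set not closed under composition in setting '",
           setting$label, "'")
    }
  }
  invisible(TRUE)
}

#' Built-in space-group settings
#'
#' Provides the settings used throughout the package: triclinic P1 and P-1
#' (all six cell parameters free) and monoclinic P21 and P21/c (b-unique;
#' alpha = gamma = 90 fixed).
#' @param label one of "P1", "P-1", "P21", "P21/c"
#' @return a `spacegroup_setting`
#' @examples
#' sg <- builtin_setting("P21/c")
#' length(sg$ops)  # 4
#' @export
builtin_setting <- function(label = c("P1", "P-1", "P21", "P21/c")) {
  label <- match.arg(label)
  I3 <- diag(3)
  inv <- -diag(3)
  screw_b <- diag(c(-1, 1, -1))
  triclinic <- rep(TRUE, 6)
  monoclinic_free <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  monoclinic_fixed <- c(alpha = 90, gamma = 90)
  switch(label,
    "P1" = spacegroup_setting("P1", list(list(W = I3, w = c(0, 0, 0))),
                              cell_free = triclinic),
    "P-1" = spacegroup_setting("P-1", list(
      list(W = I3, w = c(0, 0, 0)),
      list(W = inv, w = c(0, 0, 0))
    ), cell_free = triclinic),
    "P21" = spacegroup_setting("P21", list(
      list(W = I3, w = c(0, 0, 0)),
      list(W = screw_b, w = c(0, 0.5, 0))
    ), cell_free = monoclinic_free, cell_fixed = monoclinic_fixed),
    "P21/c" = spacegroup_setting("P21/c", list(
      list(W = I3, w = c(0, 0, 0)),
      list(W = screw_b, w = c(0, 0.5, 0.5)),
      list(W = inv, w = c(0, 0, 0)),
      list(W = diag(c(1, -1, 1)), w = c(0, 0.5, 0.5))
    ), cell_free = monoclinic_free, cell_fixed = monoclinic_fixed)
  )
}

#' Freeze degrees of freedom of a setting
#'
#' Returns a copy of `setting` with the cell and/or molecular orientations
#' held fixed. Used by fixture systems whose barrier oracles are exhaustive
#' low-dimensional grid scans.
#' @param setting a `spacegroup_setting`
#' @param fix_cell freeze all six cell parameters
#' @param fix_orientation freeze molecular orientations
#' @return modified `spacegroup_setting`
#' @export
constrain_setting <- function(setting, fix_cell = FALSE, fix_orientation = FALSE) {
  if (fix_cell) setting$cell_free <- rep(FALSE, 6)
  if (fix_orientation) setting$rotations_free <- FALSE
  setting
}

#' @export
print.spacegroup_setting <- function(x, ...) {
  cat(sprintf("space-group setting '%s': %d operator(s), free cell params: %s\n",
              x$label, length(x$ops),
              paste(c("a", "b", "c", "al", "be", "ga")[x$cell_free], collapse = " ")))
  invisible(x)
}
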