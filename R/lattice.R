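# Periodic cell: lengths a, b, c [Angstrom] and angles alpha, beta, gamma
# [degrees]. The Cartesian frame follows the usual crystallographic choice:
# a along x, b in the xy plane.

#' Create a lattice
#'
#' @param a,b,c cell lengths in Angstrom (> 0)
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180)
#' @return an object of class `xtal_lattice`
#' @examples
#' lat <- lattice(10, 10, 10)
#' cell_volume(lat)
#' @export
lattice <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = unname(a), b = unname(b), c = unname(c),
         alpha = unname(alpha), beta = unname(beta), gamma = unname(gamma))
  if (any(!is.finite(p))) stop("lattice parameters must be finite")
  if (any(p[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(p[4:6] <= 0) || any(p[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  lat <- structure(as.list(p), class = "xtal_lattice")
  if (cell_volume(lat) <= 0) stop("degenerate lattice: non-positive volume")
  lat
}

#' Cell matrix (columns are the lattice vectors)
#'
#' @param lat an `xtal_lattice`
#' @return 3x3 matrix whose columns are a, b, c in Cartesian coordinates, so
#'   that `x_cart = cell_matrix(lat) %*% x_frac`
#' @export
cell_matrix <- function(lat) {
  d2r <- pi / 180
  ca <- cos(lat$alpha * d2r); cb <- cos(lat$beta * d2r); cg <- cos(lat$gamma * d2r)
  sg <- sin(lat$gamma * d2r)
  cz <- (ca - cb * cg) / sg
  arg <- 1 - cb^2 - cz^2
  if (arg <= 0) stop("degenerate lattice: angles incompatible with a 3-D cell")
  matrix(c(
    lat$a, lat$b * cg, lat$c * cb,
    0,     lat$b * sg, lat$c * cz,
    0,     0,          lat$c * sqrt(arg)
  ), nrow = 3, byrow = TRUE)
}

#' Cell volume from the scalar triple product
#' @param lat an `xtal_lattice`
#' @return volume in Angstrom^3
#' @export
cell_volume <- function(lat) {
  d2r <- pi / 180
  ca <- cos(lat$alpha * d2r); cb <- cos(lat$beta * d2r); cg <- cos(lat$gamma * d2r)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(0)
  lat$a * lat$b * lat$c * sqrt(arg)
}

#' Fractional to Cartesian coordinates
#' @param frac n x 3 matrix (or length-3 vector) of fractional coordinates
#' @param lat an `xtal_lattice` or a 3x3 cell matrix
#' @return n x 3 matrix of Cartesian coordinates [Angstrom]
#' @export
frac_to_cart <- function(frac, lat) {
  A <- if (is.matrix(lat)) lat else cell_matrix(lat)
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = 1)
  t(A %*% t(frac))
}

#' Cartesian to fractional coordinates
#' @param cart n x 3 matrix (or length-3 vector) of Cartesian coordinates
#' @param lat an `xtal_lattice` or a 3x3 cell matrix
#' @return n x 3 matrix of fractional coordinates
#' @export
cart_to_frac <- function(cart, lat) {
  A <- if (is.matrix(lat)) lat else cell_matrix(lat)
  if (is.null(dim(cart))) cart <- matrix(cart, nrow = 1)
  t(solve(A) %*% t(cart))
}

#' Wrap fractional coordinates into [0, 1)
#'
#' Reporting helper only: Monte Carlo state keeps unwrapped coordinates so
#' trajectories stay continuous.
#' @param frac fractional coordinates (vector or matrix)
#' @return wrapped coordinates
#' @export
wrap_frac <- function(frac) frac - floor(frac)

#' @export
print.xtal_lattice <- function(x, ...) {
  cat(sprintf("lattice: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}
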