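# Unit-quaternion utilities. Quaternions are length-4 numeric vectors
# (w, x, y, z), Hamilton convention. Molecular orientations are stored as unit
# quaternions and composed as (operator %q% orientation): the left factor acts
# last, i.e. rotate the molecule first by its own orientation, then by the
# symmetry operator.

#' Normalize a quaternion to unit length
#' @param q length-4 numeric (w, x, y, z)
#' @return unit quaternion
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < 1e-12) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion product
#'
#' Hamilton product `a` times `b`; as a rotation, `b` is applied first.
#' @param a,b unit quaternions (w, x, y, z)
#' @return quaternion product
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion
#' @return 3x3 rotation matrix R such that x' = R x
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from axis and angle
#' @param axis length-3 direction (need not be unit)
#' @param angle rotation angle in radians
#' @return unit quaternion
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be nonzero")
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Quaternion from a rotation vector
#'
#' The rotation vector's direction is the axis and its norm the angle [rad];
#' the zero vector maps to the identity.
#' @param v length-3 rotation vector
#' @return unit quaternion
#' @export
quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * v / th)
}

#' Quaternion from a proper rotation matrix
#' @param R 3x3 rotation matrix with det(R) = +1
#' @return unit quaternion (w >= 0)
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

#' Uniform random rotation as a quaternion
#'
#' Shoemake's subgroup algorithm mapping three uniform variates to a rotation
#' uniform on SO(3). With explicit `u`, the mapping is deterministic (used by
#' the quasi-random structure generator).
#' @param u optional length-3 vector in [0, 1); drawn from the session RNG if
#'   missing
#' @return unit quaternion
#' @export
quat_random <- function(u = NULL) {
  if (is.null(u)) u <- stats::runif(3)
  s1 <- sqrt(1 - u[1]); s2 <- sqrt(u[1])
  t1 <- 2 * pi * u[2]; t2 <- 2 * pi * u[3]
  quat_normalize(c(s1 * sin(t1), s1 * cos(t1), s2 * sin(t2), s2 * cos(t2)))
}
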