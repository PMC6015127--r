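# Quaternion helpers. Scalar-first (w, x, y, z), Hamilton product;
# rotation of a vector v is q * (0, v) * conj(q).

#' Quaternion product
#'
#' Hamilton product of two scalar-first quaternions.
#'
#' @param a,b numeric length-4 vectors `(w, x, y, z)`.
#' @return numeric length-4 vector `a * b`.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate
#' @param q numeric length-4 quaternion.
#' @return the conjugate `(w, -x, -y, -z)`.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Normalize a quaternion to unit length
#' @param q numeric length-4 quaternion.
#' @return unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Rotate a vector by a unit quaternion
#' @param q unit quaternion (scalar-first).
#' @param v numeric length-3 vector.
#' @return the rotated vector `R(q) v`.
#' @export
quat_rotate <- function(q, v) {
  r <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  r[2:4]
}

#' Axis-angle quaternion
#' @param axis rotation axis (any nonzero length-3 vector; normalized).
#' @param angle rotation angle in radians.
#' @return unit quaternion rotating by `angle` about `axis`.
#' @export
quat_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be nonzero")
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' Shortest-arc quaternion between two directions
#'
#' The minimal (twist-free) rotation taking unit vector `from` onto unit
#' vector `to`. The antiparallel case is resolved by a 180-degree rotation
#' about the first axis orthogonal to `from`.
#'
#' @param from,to numeric length-3 vectors (normalized internally).
#' @return unit quaternion `q` with `quat_rotate(q, from) == to`.
#' @export
quat_from_vectors <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t <- to / sqrt(sum(to^2))
  d <- sum(f * t)
  if (d < -1 + 1e-12) {
    # antiparallel: rotate 180 degrees about an axis orthogonal to `from`
    ax <- c(1, 0, 0)
    if (abs(f[1]) > 0.9) ax <- c(0, 1, 0)
    ax <- ax - sum(ax * f) * f
    return(quat_axis_angle(ax, pi))
  }
  v <- c(f[2] * t[3] - f[3] * t[2],
         f[3] * t[1] - f[1] * t[3],
         f[1] * t[2] - f[2] * t[1])
  quat_normalize(c(1 + d, v))
}
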