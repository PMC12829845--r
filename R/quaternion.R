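# Quaternions are length-4 numeric vectors (w, x, y, z), Hamilton convention,
# scalar-first, right-handed. Rotations act as v' = q v q^-1.

#' Quaternion constructor
#'
#' Builds a scalar-first quaternion `(w, x, y, z)` in the Hamilton convention.
#'
#' @param w,x,y,z Real components; `w` is the scalar part.
#' @return A numeric vector of length 4.
#' @examples
#' quaternion(1, 0, 0, 0)  # identity rotation
#' @export
quaternion <- function(w, x, y, z) {
  q <- c(w, x, y, z)
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  q
}

.checkQuat <- function(q, arg = "q") {
  if (!is.numeric(q) || length(q) != 4L)
    stop(sprintf("'%s' must be a numeric vector of length 4", arg))
  if (!all(is.finite(q)))
    stop(sprintf("'%s' has non-finite components", arg))
  invisible(q)
}

#' Quaternion norm and normalization
#'
#' @param q Quaternion (length-4 numeric, scalar-first).
#' @return `quatNorm` returns the Euclidean norm; `quatNormalize` returns the
#'   unit quaternion `q / ||q||`.
#' @export
quatNorm <- function(q) {
  .checkQuat(q)
  sqrt(sum(q * q))
}

#' @rdname quatNorm
#' @export
quatNormalize <- function(q) {
  n <- quatNorm(q)
  if (n == 0) stop("cannot normalize the zero quaternion")
  q / n
}

#' Quaternion conjugate and inverse
#'
#' For a unit quaternion the inverse equals the conjugate.
#'
#' @param q Quaternion.
#' @return Length-4 numeric vector.
#' @export
quatConjugate <- function(q) {
  .checkQuat(q)
  c(q[1L], -q[2L:4L])
}

#' @rdname quatConjugate
#' @export
quatInverse <- function(q) {
  .checkQuat(q)
  n2 <- sum(q * q)
  if (n2 == 0) stop("cannot invert the zero quaternion")
  quatConjugate(q) / n2
}

#' Hamilton product of two quaternions
#'
#' Computes `a %*% b` in the quaternion algebra (scalar-first Hamilton
#' product). The norm of the product equals the product of the norms.
#'
#' @param a,b Quaternions (length-4 numeric, scalar-first).
#' @return The product quaternion.
#' @examples
#' quatMultiply(quaternion(0, 1, 0, 0), quaternion(0, 1, 0, 0))  # i * i = -1
#' @export
quatMultiply <- function(a, b) {
  .checkQuat(a, "a"); .checkQuat(b, "b")
  c(a[1L] * b[1L] - a[2L] * b[2L] - a[3L] * b[3L] - a[4L] * b[4L],
    a[1L] * b[2L] + a[2L] * b[1L] + a[3L] * b[4L] - a[4L] * b[3L],
    a[1L] * b[3L] - a[2L] * b[4L] + a[3L] * b[1L] + a[4L] * b[2L],
    a[1L] * b[4L] + a[2L] * b[3L] - a[3L] * b[2L] + a[4L] * b[1L])
}

#' Axis-angle to quaternion
#'
#' @param axis 3-vector rotation axis (need not be unit length).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion encoding the rotation.
#' @export
quatFromAxisAngle <- function(axis, angle) {
  if (length(axis) != 3L || !all(is.finite(axis)) || !is.finite(angle))
    stop("axis must be a finite 3-vector and angle a finite scalar")
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' Quaternion to rotation matrix
#'
#' Returns the 3x3 direction-cosine matrix of a unit quaternion
#' (body-to-reference for a body orientation quaternion).
#'
#' @param q Unit quaternion.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
quatToRotmat <- function(q) {
  .checkQuat(q)
  q <- quatNormalize(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Rotate a 3-vector by a unit quaternion
#'
#' @param q Unit quaternion.
#' @param v 3-vector.
#' @return The rotated 3-vector `q v q^-1`.
#' @export
quatRotate <- function(q, v) {
  if (length(v) != 3L) stop("'v' must be a 3-vector")
  p <- quatMultiply(quatMultiply(q, c(0, v)), quatConjugate(quatNormalize(q)))
  p[2L:4L]
}

#' Flexion/extension angle between parent and child joint orientations
#'
#' The joint angle is recovered from the scalar part of the relative rotation
#' `q_rel = q_parent (x) q_child^-1`:
#' `theta = arccos(2 * (q_rel)_w^2 - 1)`,
#' the total rotation angle between the two segment frames, clamped to
#' `[0, pi]`. It is symmetric in its arguments and invariant under a common
#' left rotation of both frames.
#'
#' @param qParent,qChild Unit quaternions of the parent and child segments.
#' @param tol Unit-norm tolerance for the inputs.
#' @return Angle in radians in `[0, pi]`.
#' @examples
#' jointAngle(quaternion(1, 0, 0, 0), quatFromAxisAngle(c(0, 1, 0), pi / 3))
#' @export
jointAngle <- function(qParent, qChild, tol = 1e-6) {
  .checkQuat(qParent, "qParent"); .checkQuat(qChild, "qChild")
  if (abs(quatNorm(qParent) - 1) > tol || abs(quatNorm(qChild) - 1) > tol)
    stop("jointAngle requires unit quaternions")
  qRel <- quatMultiply(qParent, quatInverse(qChild))
  # clamp absorbs rounding at the arccos boundary
  arg <- 2 * qRel[1L]^2 - 1
  acos(min(1, max(-1, arg)))
}
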