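# SO(3) machinery: 6D representation, Gram-Schmidt reconstruction, Euler
# conversions, geodesic distance, constrained random rotations.

#' Euler angle convention used throughout the package
#'
#' All Euler-angle labels are intrinsic Z-X-Y (a rotation about z, then about
#' the new x, then about the new y), right-handed, stored in degrees as
#' `(ax, ay, az)` where the matrix is `Rz(az) %*% Rx(ax) %*% Ry(ay)`. The
#' constant is embedded in every dataset manifest so files are
#' self-describing.
#'
#' @format A character scalar, `"ZXY"`.
#' @export
EULER_CONVENTION <- "ZXY"

# degeneracy threshold for Gram-Schmidt input vectors
GS_EPS <- 1e-8

check_rotation_matrix <- function(R, tol = 1e-6, arg = "R") {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R)))
    stopf("'%s' must be a finite 3x3 matrix", arg)
  ortho <- norm(crossprod(R) - diag(3), type = "F")
  d <- det(R)
  if (ortho >= tol || abs(d - 1) >= tol)
    stopf("'%s' is not a rotation matrix (|R'R - I|_F = %.3g, det = %.8f)",
          arg, ortho, d)
  invisible(R)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Reconstruct a rotation matrix from two vectors by Gram-Schmidt
#'
#' Builds an orthonormal right-handed basis from two (not necessarily unit,
#' not necessarily orthogonal) 3-vectors: `e1 = v1/|v1|`,
#' `u2 = v2 - (e1.v2) e1`, `e2 = u2/|u2|`, `e3 = e1 x e2`, returning the
#' matrix with columns `(e1, e2, e3)`. This is the map through which a network
#' head emitting six numbers (`v1`, `v2`) is projected onto SO(3); it is
#' scale-invariant in `v1` and invariant to the component of `v2` along `v1`.
#'
#' @param v1,v2 numeric 3-vectors.
#' @return A 3x3 rotation matrix (orthonormal, determinant +1).
#' @examples
#' gram_schmidt_to_rotation(c(1, 0, 0), c(0, 1, 0))  # identity
#' @export
gram_schmidt_to_rotation <- function(v1, v2) {
  if (length(v1) != 3L || length(v2) != 3L || !all(is.finite(c(v1, v2))))
    stopf("'v1' and 'v2' must be finite 3-vectors")
  n1 <- sqrt(sum(v1^2))
  if (n1 < GS_EPS)
    stopf("degenerate Gram-Schmidt input: |v1| = %.3g < %.0e", n1, GS_EPS)
  e1 <- v1 / n1
  u2 <- v2 - sum(e1 * v2) * e1
  n2 <- sqrt(sum(u2^2))
  if (n2 < GS_EPS)
    stopf("degenerate Gram-Schmidt input: v2 is (near-)parallel to v1 (|u2| = %.3g)", n2)
  e2 <- u2 / n2
  cbind(e1, e2, cross3(e1, e2), deparse.level = 0)
}

#' Convert a rotation matrix to its 6D representation
#'
#' Returns the first two columns of `R`, column-major — the continuous 6D
#' rotation representation. [gram_schmidt_to_rotation()] applied to the two
#' halves of the result reproduces `R`.
#'
#' @param R a 3x3 rotation matrix.
#' @return A numeric 6-vector `(r1..r6)`.
#' @export
rotation_to_sixd <- function(R) {
  check_rotation_matrix(R)
  c(R[, 1L], R[, 2L])
}

#' Reconstruct a rotation from a 6D representation vector
#'
#' Convenience wrapper splitting a 6-vector into `v1 = r[1:3]`, `v2 = r[4:6]`
#' and applying [gram_schmidt_to_rotation()].
#'
#' @param r numeric 6-vector.
#' @return A 3x3 rotation matrix.
#' @export
sixd_to_rotation <- function(r) {
  if (length(r) != 6L) stopf("'r' must have length 6")
  gram_schmidt_to_rotation(r[1:3], r[4:6])
}

rot_x <- function(rad) {
  c_ <- cos(rad); s_ <- sin(rad)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3L, 3L)
}
rot_y <- function(rad) {
  c_ <- cos(rad); s_ <- sin(rad)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3L, 3L)
}
rot_z <- function(rad) {
  c_ <- cos(rad); s_ <- sin(rad)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3L, 3L)
}

#' Convert Euler angles (degrees) to a rotation matrix
#'
#' @param euler_deg numeric 3-vector `(ax, ay, az)` of angles in degrees about
#'   the x, y and z axes.
#' @param convention Euler convention identifier; only `"ZXY"` (intrinsic
#'   z-x'-y'', see [EULER_CONVENTION]) is supported.
#' @return A 3x3 rotation matrix `Rz(az) %*% Rx(ax) %*% Ry(ay)`.
#' @export
euler_to_rotation <- function(euler_deg, convention = EULER_CONVENTION) {
  if (!identical(convention, "ZXY"))
    stopf("unknown Euler convention '%s' (supported: \"ZXY\")", as.character(convention)[1L])
  if (length(euler_deg) != 3L || !all(is.finite(euler_deg)))
    stopf("'euler_deg' must be a finite 3-vector (ax, ay, az) in degrees")
  a <- deg2rad(euler_deg)
  rot_z(a[3L]) %*% rot_x(a[1L]) %*% rot_y(a[2L])
}

#' Convert a rotation matrix to Euler angles (degrees)
#'
#' Inverts [euler_to_rotation()] on the principal branch: `ax` in
#' `[-90, 90]`, `ay` and `az` in `[-180, 180)`. At gimbal lock
#' (`ax = +/-90` degrees, where only `az -/+ ay` is observable) the tie-break
#' sets `ay = 0` and folds the whole in-plane angle into `az`, so the output
#' is deterministic.
#'
#' @inheritParams euler_to_rotation
#' @param R a 3x3 rotation matrix.
#' @return Numeric 3-vector `(ax, ay, az)` in degrees.
#' @export
rotation_to_euler <- function(R, convention = EULER_CONVENTION) {
  if (!identical(convention, "ZXY"))
    stopf("unknown Euler convention '%s' (supported: \"ZXY\")", as.character(convention)[1L])
  check_rotation_matrix(R)
  # R = Rz(az) Rx(ax) Ry(ay):
  #   R[3,2] = sin(ax); R[3,1] = -cos(ax) sin(ay); R[3,3] = cos(ax) cos(ay)
  #   R[1,2] = -sin(az) cos(ax); R[2,2] = cos(az) cos(ax)
  sx <- clamp(R[3L, 2L], -1, 1)
  if (abs(sx) > 1 - 1e-9) {
    ax <- if (sx > 0) 90 else -90
    ay <- 0
    # with ay = 0: R[1,1] = cos(az), R[1,3] = sign(sx) * sin(az)
    az <- rad2deg(atan2(sign(sx) * R[1L, 3L], R[1L, 1L]))
  } else {
    ax <- rad2deg(asin(sx))
    ay <- rad2deg(atan2(-R[3L, 1L], R[3L, 3L]))
    az <- rad2deg(atan2(-R[1L, 2L], R[2L, 2L]))
  }
  e <- c(ax, ay, az)
  ((e + 180) %% 360) - 180
}

#' Geodesic distance between two rotations, in degrees
#'
#' The angle of the relative rotation `Rrel = t(R1) %*% R2`, computed as
#' `acos((trace(Rrel) - 1) / 2)` with the argument clamped to `[-1, 1]` to
#' absorb rounding. Symmetric, zero iff `R1 == R2`, bounded by 180 degrees.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return Angle in degrees in `[0, 180]`.
#' @export
geodesic_distance_deg <- function(R1, R2) {
  check_rotation_matrix(R1, arg = "R1")
  check_rotation_matrix(R2, arg = "R2")
  rel <- crossprod(R1, R2)
  rad2deg(acos(clamp((sum(diag(rel)) - 1) / 2, -1, 1)))
}

#' Draw a random rotation with bounded per-axis Euler angles
#'
#' Samples three angles independently and uniformly in
#' `[-max_angle_per_axis, +max_angle_per_axis]` degrees and composes them
#' under the package Euler convention ([EULER_CONVENTION]). Uses the current
#' R random stream; wrap in `set.seed()` (or [with_seed()]) for
#' reproducibility.
#'
#' @param max_angle_per_axis maximum magnitude of each Euler angle, degrees,
#'   in `[0, 180]`.
#' @return A 3x3 rotation matrix (identity when `max_angle_per_axis = 0`).
#' @export
random_rotation_in_range <- function(max_angle_per_axis) {
  if (!is_number(max_angle_per_axis) || max_angle_per_axis < 0 || max_angle_per_axis > 180)
    stopf("'max_angle_per_axis' must be a single value in [0, 180] degrees")
  euler_to_rotation(runif(3L, -max_angle_per_axis, max_angle_per_axis))
}
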