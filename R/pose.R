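# Pose: rotation + normalized translation relative to the volume centre.

#' Construct a plane pose
#'
#' A pose is a rigid placement of the slicing plane relative to the volume
#' centre: a 3x3 rotation matrix and a translation in normalized coordinates
#' (each axis scaled so that the volume spans `[-1, 1]`; in-volume poses have
#' components in that range, but values outside it are representable).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric 3-vector, normalized units.
#' @return An object of class `"pose"` with elements `rotation` and
#'   `translation`.
#' @examples
#' pose()  # identity pose at the volume centre
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  check_rotation_matrix(rotation, arg = "rotation")
  if (length(translation) != 3L || !all(is.finite(translation)))
    stopf("'translation' must be a finite 3-vector")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "pose")
}

#' Construct a pose from Euler angles
#'
#' @param euler_deg `(ax, ay, az)` in degrees, package convention.
#' @param translation normalized 3-vector.
#' @return A `"pose"` object.
#' @export
pose_from_euler <- function(euler_deg, translation = c(0, 0, 0)) {
  pose(euler_to_rotation(euler_deg), translation)
}

#' @export
print.pose <- function(x, ...) {
  e <- rotation_to_euler(x$rotation)
  cat("<pose>\n")
  cat(sprintf("  translation (normalized): %8.4f %8.4f %8.4f\n",
              x$translation[1], x$translation[2], x$translation[3]))
  cat(sprintf("  euler %s (deg):          %8.3f %8.3f %8.3f\n",
              EULER_CONVENTION, e[1], e[2], e[3]))
  invisible(x)
}

is_pose <- function(x) inherits(x, "pose")
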