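# Oblique-plane extraction: pixel grid -> plane-local mm -> pose transform ->
# trilinear sampling of the volume.

#' Specify a slicing plane
#'
#' The slice is a square patch of physical side `field_of_view` mm sampled at
#' `resolution` x `resolution` pixels. In plane-local coordinates the patch
#' lies in the x-y plane with the image centre at the origin and the plane
#' normal along local z; pixel `(row i, col j)` (1-based) sits at local
#' `x = (j - 0.5 - res/2) * fov/res`, `y = (i - 0.5 - res/2) * fov/res`.
#' A point `p` on the plane maps into the volume as
#' `p_volume = R %*% p + t_mm`, where `t_mm` is the pose translation
#' denormalized to mm — rotation about the volume centre, then offset.
#'
#' @param pose a [pose()] (translation in normalized units).
#' @param field_of_view physical side length of the square slice, mm.
#' @param resolution pixels per side (>= 2).
#' @return An object of class `"slice_spec"`.
#' @export
slice_spec <- function(pose, field_of_view, resolution) {
  stopifnot(is_pose(pose))
  if (!is_number(field_of_view) || field_of_view <= 0)
    stopf("'field_of_view' must be a positive length in mm")
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 2L)
    stopf("'resolution' must be an integer >= 2")
  structure(list(pose = pose, field_of_view = field_of_view,
                 resolution = resolution),
            class = "slice_spec")
}

#' Extract a 2D slice from a volume at a 6D pose
#'
#' Samples the volume by trilinear interpolation at the pixel grid of the
#' plane described by `spec` (see [slice_spec()] for the geometry). Sample
#' points outside the volume's physical bounds receive the fill value 0
#' (ultrasound background); `overlap` is the fraction of sample points that
#' fall inside the bounds.
#'
#' @param vol a [volume()].
#' @param spec a [slice_spec()].
#' @return A list of class `"slice_image"` with `pixels` (resolution x
#'   resolution matrix in `[0, 1]`), `label` (the pose), `overlap`, and the
#'   `field_of_view` / `resolution` used.
#' @export
extract_slice <- function(vol, spec) {
  stopifnot(inherits(vol, "us_volume"), inherits(spec, "slice_spec"))
  t_mm <- denormalize_translation(spec$pose$translation, vol$extent)
  out <- slice_sample_cpp(vol$grid, vol$spacing, spec$pose$rotation, t_mm,
                          spec$field_of_view, spec$resolution)
  structure(list(pixels = out$pixels, label = spec$pose,
                 overlap = out$overlap,
                 field_of_view = spec$field_of_view,
                 resolution = spec$resolution),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %dx%d px, fov %.1f mm, overlap %.3f\n",
              x$resolution, x$resolution, x$field_of_view, x$overlap))
  invisible(x)
}

#' Fraction of a slicing plane's sample points inside the volume
#'
#' Same sample-point grid and inside test as [extract_slice()], without
#' interpolating intensities. Used to reject poorly overlapping poses during
#' dataset generation.
#'
#' @inheritParams extract_slice
#' @return A fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(vol, spec) {
  stopifnot(inherits(vol, "us_volume"), inherits(spec, "slice_spec"))
  t_mm <- denormalize_translation(spec$pose$translation, vol$extent)
  overlap_fraction_cpp(dim(vol$grid), vol$spacing, spec$pose$rotation, t_mm,
                       spec$field_of_view, spec$resolution)
}

#' Default slice field of view for a volume
#'
#' The smallest volume extent, so an unrotated centred slice never leaves the
#' volume.
#'
#' @param vol a [volume()].
#' @return Field of view in mm.
#' @export
default_field_of_view <- function(vol) {
  stopifnot(inherits(vol, "us_volume"))
  min(vol$extent)
}
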