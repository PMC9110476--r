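# Volume container + NIfTI I/O + normalized-coordinate helpers.

#' Construct a volume object
#'
#' A 3D grayscale intensity grid with voxel spacing. Physical coordinates are
#' in mm with the origin at the volume centre; voxel index `k` (0-based) on an
#' axis sits at `(k + 0.5) * spacing - extent/2` mm, and `extent = dim(grid)
#' * spacing`.
#'
#' @param grid 3D numeric array; intensities are expected in `[0, 1]`.
#' @param spacing voxel size in mm, scalar (isotropic) or per-axis 3-vector.
#'   A warning is raised for non-isotropic spacing, which the geometry
#'   supports but typical ultrasound volumes do not use.
#' @return An object of class `"us_volume"` with fields `grid`, `spacing`
#'   (3-vector, mm) and `extent` (3-vector, mm).
#' @export
volume <- function(grid, spacing = c(1, 1, 1)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stopf("'grid' must be a 3D array, got %d dimension(s)",
          length(dim(grid) %||% dim(as.array(grid))))
  if (!all(is.finite(grid))) stopf("'grid' contains non-finite values")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stopf("'spacing' must be positive (scalar or 3-vector), in mm")
  spacing <- as.numeric(spacing)
  if (diff(range(spacing)) > 1e-9)
    warning("non-isotropic voxel spacing (", paste(signif(spacing, 6), collapse = " x "),
            " mm); geometry remains correct but this is unusual for US volumes")
  structure(list(grid = grid, spacing = spacing,
                 extent = dim(grid) * spacing),
            class = "us_volume")
}

#' @export
print.us_volume <- function(x, ...) {
  cat(sprintf("<us_volume> %s voxels, spacing %s mm, extent %s mm, intensity [%.3f, %.3f]\n",
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$extent, 4), collapse = "x"),
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Load a volume from a NIfTI file
#'
#' Reads a 3D scalar NIfTI image, takes the voxel spacing from the header
#' `pixdim`, and rescales intensities linearly to `[0, 1]` (a constant image
#' maps to 0).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume()] object.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stopf("expected a 3D volume, but '%s' has %d dimensions", path, length(dim(arr)))
  sp <- RNifti::pixdim(img)[1:3]
  if (!all(is.finite(sp)) || any(sp <= 0))
    stopf("non-positive voxel spacing in NIfTI header of '%s'", path)
  arr <- array(as.vector(arr), dim(arr))  # drop NIfTI header attributes
  rng <- range(arr)
  arr <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1]) else array(0, dim(arr))
  volume(arr, sp)
}

#' Save a volume to a NIfTI file
#'
#' @param vol a [volume()] object.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "us_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("output directory does not exist: %s", dir)
  img <- RNifti::asNifti(structure(vol$grid, pixdim = vol$spacing))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize a translation from mm to the volume-relative scale
#'
#' Maps mm offsets from the volume centre to normalized coordinates in which
#' the volume spans `[-1, 1]` per axis: `t_norm = t_mm / (extent / 2)`.
#'
#' @param t_mm numeric 3-vector, mm.
#' @param extent volume physical size per axis, mm (3-vector).
#' @return Normalized 3-vector.
#' @export
normalize_translation <- function(t_mm, extent) {
  if (length(t_mm) != 3L || !all(is.finite(t_mm)))
    stopf("'t_mm' must be a finite 3-vector")
  if (length(extent) != 3L || !all(is.finite(extent)) || any(extent <= 0))
    stopf("'extent' must be a positive 3-vector (mm)")
  as.numeric(t_mm) / (as.numeric(extent) / 2)
}

#' Denormalize a translation from the volume-relative scale to mm
#'
#' Inverse of [normalize_translation()]: `t_mm = t_norm * extent / 2`.
#'
#' @param t_norm normalized 3-vector.
#' @inheritParams normalize_translation
#' @return 3-vector in mm.
#' @export
denormalize_translation <- function(t_norm, extent) {
  if (length(t_norm) != 3L || !all(is.finite(t_norm)))
    stopf("'t_norm' must be a finite 3-vector")
  if (length(extent) != 3L || !all(is.finite(extent)) || any(extent <= 0))
    stopf("'extent' must be a positive 3-vector (mm)")
  as.numeric(t_norm) * as.numeric(extent) / 2
}
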