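# Procedural fetal-brain-like speckle phantom: a bright ellipsoidal "skull"
# shell enclosing asymmetric internal structures (tilted midline echo, unequal
# ventricle pair, focal bright body, posterior lobe) under multiplicative
# speckle. Realism is deliberately minimal: the generator only needs to make
# every pose visually identifiable (no rotational or mirror symmetry) and to
# carry ultrasound-like texture.

#' Parameters of the procedural phantom volume
#'
#' @param shape voxels per axis (scalar or 3-vector); default 64.
#' @param spacing voxel size in mm; default 1 mm isotropic, giving a 64 mm
#'   cube, roughly the scale of a mid-gestation fetal brain.
#' @param skull_radii ellipsoid semi-axes of the skull shell in mm; must fit
#'   inside the volume extent.
#' @param structure_count number of internal structures beyond the skull
#'   shell and midline, between 3 and 4.
#' @param speckle_strength multiplicative speckle amplitude in `[0, 1]`;
#'   0 disables noise.
#' @param seed integer RNG seed; the phantom is a deterministic function of
#'   its parameters.
#' @return A list of class `"phantom_params"`.
#' @export
phantom_params <- function(shape = c(64, 64, 64), spacing = 1,
                           skull_radii = NULL, structure_count = 4,
                           speckle_strength = 0.3, seed = 20220430) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 8L))
    stopf("'shape' must be 3 integers >= 8")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("'spacing' must be positive (mm)")
  extent <- shape * spacing
  if (is.null(skull_radii)) skull_radii <- 0.44 * extent
  if (length(skull_radii) != 3L || any(skull_radii <= 0))
    stopf("'skull_radii' must be 3 positive semi-axes (mm)")
  if (any(skull_radii > extent / 2))
    stopf("skull radii (%s mm) exceed the half-extent (%s mm)",
          paste(signif(skull_radii, 4), collapse = ", "),
          paste(signif(extent / 2, 4), collapse = ", "))
  if (!is_number(speckle_strength) || speckle_strength < 0 || speckle_strength > 1)
    stopf("'speckle_strength' must be in [0, 1]")
  structure_count <- as.integer(structure_count)
  if (is.na(structure_count) || structure_count < 3L || structure_count > 4L)
    stopf("'structure_count' must be 3 or 4 (>= 3 keeps the phantom asymmetric)")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 skull_radii = as.numeric(skull_radii),
                 structure_count = structure_count,
                 speckle_strength = speckle_strength,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# smooth seeded low-frequency 3D texture in [-1, 1]: a coarse random grid
# trilinearly upsampled to the full resolution (value noise). Gives every
# brain region locally identifiable structure, the way real parenchyma has
# texture everywhere.
.value_noise <- function(d, coarse = 7L, seed = 0L) {
  g <- with_seed(seed, array(runif(coarse^3, -1, 1), rep(coarse, 3L)))
  idx <- lapply(1:3, function(k) {
    u <- (seq_len(d[k]) - 0.5) / d[k] * (coarse - 1) + 1
    i0 <- pmin(floor(u), coarse - 1)
    list(i0 = i0, f = u - i0)
  })
  out <- array(0, d)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wx <- if (dx) idx[[1]]$f else 1 - idx[[1]]$f
    wy <- if (dy) idx[[2]]$f else 1 - idx[[2]]$f
    wz <- if (dz) idx[[3]]$f else 1 - idx[[3]]$f
    block <- g[idx[[1]]$i0 + dx, idx[[2]]$i0 + dy, idx[[3]]$i0 + dz]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * array(block, d)
  }
  out
}

# 3-tap (1,2,1)/4 separable smoothing along each axis (replicated edges);
# gives speckle its characteristic resolution-cell correlation length
.smooth3 <- function(a) {
  d <- dim(a)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  for (ax in 1:3) {
    idx_m <- pad(seq_len(d[ax]) - 1L, d[ax])
    idx_p <- pad(seq_len(d[ax]) + 1L, d[ax])
    a <- switch(ax,
                (a[idx_m, , ] + 2 * a + a[idx_p, , ]) / 4,
                (a[, idx_m, ] + 2 * a + a[, idx_p, ]) / 4,
                (a[, , idx_m] + 2 * a + a[, , idx_p]) / 4)
  }
  a
}

# add an ellipsoid of intensity `value` (blended over the existing field)
.add_ellipsoid <- function(field, X, Y, Z, centre, radii, value) {
  r2 <- ((X - centre[1]) / radii[1])^2 + ((Y - centre[2]) / radii[2])^2 +
    ((Z - centre[3]) / radii[3])^2
  field[r2 <= 1] <- value
  field
}

#' Generate a procedural brain-like phantom volume
#'
#' Builds the deterministic anatomy field — skull shell, smooth seeded
#' parenchyma texture (so every region carries pose information, as real
#' tissue does), tilted midline echo, two unequal dark ventricles, one
#' bright focal body, one posterior lobe, placed so no rotation or mirror of
#' the volume maps it onto itself — and, if `speckle_strength > 0`,
#' multiplies it by gamma-distributed multiplicative speckle with a
#' one-resolution-cell correlation length, baked into the volume (texture is
#' a fixed landmark field, consistent across slices).
#'
#' @param params a [phantom_params()] object.
#' @return A [volume()] with intensities in `[0, 1]`.
#' @export
generate_phantom_volume <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  d <- params$shape; sp <- params$spacing
  ext <- d * sp
  ax <- lapply(1:3, function(k) ((seq_len(d[k]) - 0.5) * sp[k]) - ext[k] / 2)
  X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  rad <- params$skull_radii

  # normalized ellipsoidal radius for the skull
  re <- sqrt((X / rad[1])^2 + (Y / rad[2])^2 + (Z / rad[3])^2)
  field <- array(0.05, d)                       # exterior: dark fluid
  field[re <= 1] <- 0.30                        # brain parenchyma
  # smooth parenchyma texture so every region carries pose information
  # (real brain tissue is textured everywhere, never flat)
  tex <- 0.40 * .value_noise(d, coarse = 7L, seed = params$seed + 1L) +
    0.20 * .value_noise(d, coarse = 13L, seed = params$seed + 2L)
  field[re <= 1] <- clamp(field[re <= 1] + tex[re <= 1], 0.08, 0.75)
  field[re <= 1 & re >= 0.90] <- 0.95           # bright skull shell

  inside <- re < 0.88
  # tilted midline echo: bright slab, tilted 8 deg about z so it is not a
  # symmetry plane of the ellipsoid
  md <- abs(X * cos(deg2rad(8)) + Y * sin(deg2rad(8)))
  field[inside & md < 0.02 * ext[1]] <- 0.85

  # unequal ventricle pair (dark), asymmetric offsets
  field <- .add_ellipsoid(field, X, Y, Z, centre = c(0.18, 0.22, 0.10) * ext,
                          radii = c(0.16, 0.09, 0.07) * ext, value = 0.08)
  field <- .add_ellipsoid(field, X, Y, Z, centre = c(-0.16, 0.12, -0.06) * ext,
                          radii = c(0.10, 0.06, 0.05) * ext, value = 0.10)
  # bright focal body (choroid-plexus-like), one octant only
  field <- .add_ellipsoid(field, X, Y, Z, centre = c(0.10, -0.20, 0.16) * ext,
                          radii = c(0.07, 0.05, 0.06) * ext, value = 0.90)
  if (params$structure_count >= 4L) {
    # posterior lobe (cerebellum-like), intermediate intensity
    field <- .add_ellipsoid(field, X, Y, Z, centre = c(-0.05, -0.26, -0.14) * ext,
                            radii = c(0.14, 0.08, 0.06) * ext, value = 0.55)
  }

  s <- params$speckle_strength
  if (s > 0) {
    noise <- with_seed(params$seed,
                       array(rgamma(prod(d), shape = 4, rate = 4), d))
    # correlated speckle: fully developed speckle has a correlation length
    # of about one resolution cell, not white voxel noise
    noise <- .smooth3(noise)
    field <- field * (1 - s + s * noise)
  }
  volume(clamp(field, 0, 1), sp)
}

#' Canonical standard-plane pose of the procedural phantom
#'
#' A fixed, documented oblique plane near the volume centre that intersects
#' the midline echo, the larger ventricle and the focal bright body — the
#' phantom's stand-in for a sonographer-annotated transventricular standard
#' plane.
#'
#' @return A [pose()].
#' @export
phantom_standard_plane <- function() {
  pose_from_euler(c(8, -5, 12), c(0.04, 0.06, 0.10))
}
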