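# Independent oracles and shared fixtures, implemented without using the
# package's own code paths where they serve as cross-checks.

# --- quaternion oracle for rotation distances ------------------------------
# Shepperd-style rotation-matrix -> unit quaternion conversion.
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# geodesic angle between two rotations via the quaternion dot product
quat_angle_deg <- function(R1, R2) {
  q1 <- rotmat_to_quat(R1)
  q2 <- rotmat_to_quat(R2)
  2 * acos(pmin(abs(sum(q1 * q2)), 1)) * 180 / pi
}

# random rotation uniform on SO(3) (QR of a Gaussian matrix, det-corrected) —
# deliberately not the package's Euler-based sampler
random_so3 <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q %*% diag(c(1, 1, det(Q)))
}

# --- per-pixel trilinear slice oracle --------------------------------------
# Mirrors the documented slicing conventions with explicit R loops.
slice_oracle <- function(vol, sp_pose, fov, res) {
  d <- dim(vol$grid)
  sp <- vol$spacing
  ext2 <- d * sp / 2
  t_mm <- sp_pose$translation * ext2
  R <- sp_pose$rotation
  pix <- fov / res
  out <- matrix(0, res, res)
  inside_n <- 0L
  for (j in seq_len(res)) {
    x <- (j - 1 + 0.5 - res / 2) * pix
    for (i in seq_len(res)) {
      y <- (i - 1 + 0.5 - res / 2) * pix
      p <- R[, 1] * x + R[, 2] * y + t_mm
      if (any(abs(p) > ext2)) next
      inside_n <- inside_n + 1L
      u <- p / sp + d / 2 - 0.5
      i0 <- pmax(pmin(floor(u), d - 2), 0)
      f <- u - i0
      acc <- 0
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
          (if (dz) f[3] else 1 - f[3])
        acc <- acc + w * vol$grid[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
      }
      out[i, j] <- acc
    }
  }
  list(pixels = out, overlap = inside_n / res^2)
}

# manifest rows as a bare data.frame (drops bookkeeping attributes such as
# the directory, which legitimately differs between copies)
manifest_table <- function(m) {
  df <- as.data.frame(m)
  attr(df, "euler_convention") <- NULL
  attr(df, "field_of_view") <- NULL
  attr(df, "resolution") <- NULL
  attr(df, "seed") <- NULL
  attr(df, "extent") <- NULL
  attr(df, "dir") <- NULL
  df
}

# --- shared small fixtures --------------------------------------------------
# memoized across test files (building the phantom dataset is the slow part)
.fixture_env <- new.env(parent = emptyenv())

fixture_phantom <- function() {
  if (is.null(.fixture_env$vol))
    .fixture_env$vol <- generate_phantom_volume(phantom_params())
  .fixture_env$vol
}

# a tiny labelled dataset on disk: 40 RP + 10 SP slices at 32 px
fixture_dataset <- function() {
  if (is.null(.fixture_env$manifest)) {
    dir <- file.path(tempdir(), "planepose-fixture-ds")
    vol <- fixture_phantom()
    man <- build_dataset(vol, sampler_config(n_random = 40, n_near_sp = 10, seed = 303),
                         dir, sp = phantom_standard_plane(),
                         resolution = 32)
    .fixture_env$manifest <- man
    .fixture_env$manifest_dir <- dir
  }
  .fixture_env$manifest
}
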