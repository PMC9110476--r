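# Pose sampling (random planes + dense near-standard-plane planes) and
# dataset construction with CSV manifests + PNG slices.

#' Pose sampler configuration
#'
#' Controls the two training subsets: `RP` planes drawn uniformly at random
#' within fixed per-axis ranges, and `SP` planes perturbing an annotated
#' standard plane with intervals that ramp linearly from coarse to fine
#' across the sequence (translation 0.1 down to 0.001 normalized units,
#' rotation 7.9 down to 1.9 degrees by default). Poses whose slice overlaps
#' the volume by less than `min_overlap` are rejected and redrawn
#' (`min_overlap = 0` disables rejection).
#'
#' @param n_random number of random-pose (`RP`) planes.
#' @param n_near_sp number of near-standard-plane (`SP`) planes.
#' @param trans_range per-axis translation range, normalized units (uniform
#'   in `[-trans_range, trans_range]`).
#' @param rot_range per-axis rotation range, degrees.
#' @param sp_trans_interval_max,sp_trans_interval_min near-SP translation
#'   perturbation interval at the start/end of the ramp, normalized units.
#' @param sp_rot_interval_max,sp_rot_interval_min near-SP rotation
#'   perturbation interval at the start/end of the ramp, degrees.
#' @param min_overlap minimum slice/volume overlap fraction in `[0, 1]`.
#' @param seed integer RNG seed for dataset construction.
#' @return A list of class `"sampler_config"`.
#' @export
sampler_config <- function(n_random = 1000, n_near_sp = 100,
                           trans_range = 0.5, rot_range = 45,
                           sp_trans_interval_max = 0.1,
                           sp_trans_interval_min = 0.001,
                           sp_rot_interval_max = 7.9,
                           sp_rot_interval_min = 1.9,
                           min_overlap = 0.75, seed = 1L) {
  n_random <- as.integer(n_random); n_near_sp <- as.integer(n_near_sp)
  if (is.na(n_random) || n_random < 0L || is.na(n_near_sp) || n_near_sp < 0L)
    stopf("'n_random' and 'n_near_sp' must be counts >= 0")
  if (!is_number(trans_range) || trans_range < 0 ||
      !is_number(rot_range) || rot_range < 0 || rot_range > 180)
    stopf("'trans_range' must be >= 0 and 'rot_range' in [0, 180] degrees")
  if (sp_trans_interval_max < sp_trans_interval_min ||
      sp_rot_interval_max < sp_rot_interval_min)
    stopf("near-SP interval maxima must be >= their minima")
  if (!is_number(min_overlap) || min_overlap < 0 || min_overlap > 1)
    stopf("'min_overlap' must be in [0, 1]")
  structure(list(n_random = n_random, n_near_sp = n_near_sp,
                 trans_range = trans_range, rot_range = rot_range,
                 sp_trans_interval_max = sp_trans_interval_max,
                 sp_trans_interval_min = sp_trans_interval_min,
                 sp_rot_interval_max = sp_rot_interval_max,
                 sp_rot_interval_min = sp_rot_interval_min,
                 min_overlap = min_overlap, seed = as.integer(seed)),
            class = "sampler_config")
}

# draw once from `draw_fun` repeatedly until the overlap constraint holds
.rejection_sample <- function(draw_fun, vol, fov, resolution, min_overlap,
                              max_reject = 1000L) {
  for (k in seq_len(max_reject + 1L)) {
    p <- draw_fun()
    if (min_overlap <= 0) return(p)
    ov <- overlap_fraction(vol, slice_spec(p, fov, resolution))
    if (ov >= min_overlap) return(p)
  }
  stopf(paste0("pose sampling rejected %d consecutive candidates; ",
               "lower 'min_overlap' or narrow the sampling ranges"), max_reject)
}

#' Draw one random in-volume pose
#'
#' Translation uniform per axis in `[-trans_range, trans_range]` (normalized
#' units); rotation via [random_rotation_in_range()] with `rot_range`;
#' rejection-resampled until the slice overlap reaches
#' `config$min_overlap`. Uses the current R random stream.
#'
#' @param config a [sampler_config()].
#' @param vol a [volume()].
#' @param field_of_view,resolution slice geometry used for the overlap test;
#'   defaults to [default_field_of_view()] at 64 px.
#' @return A [pose()].
#' @export
sample_random_pose <- function(config, vol,
                               field_of_view = default_field_of_view(vol),
                               resolution = 64L) {
  stopifnot(inherits(config, "sampler_config"), inherits(vol, "us_volume"))
  draw <- function() {
    pose(random_rotation_in_range(config$rot_range),
         runif(3L, -config$trans_range, config$trans_range))
  }
  .rejection_sample(draw, vol, field_of_view, resolution, config$min_overlap)
}

#' Draw poses densely around a standard plane
#'
#' Generates `config$n_near_sp` poses perturbing `sp_pose`: the i-th pose
#' adds per-axis uniform translation within `±trans_i` and composes a
#' per-axis-bounded random rotation within `±rot_i`, where both intervals
#' ramp linearly from their `max` to their `min` across the sequence.
#' Overlap-filtered like [sample_random_pose()].
#'
#' @param sp_pose the annotated standard-plane [pose()].
#' @inheritParams sample_random_pose
#' @return A list of [pose()] objects of length `config$n_near_sp`.
#' @export
sample_near_sp_poses <- function(config, sp_pose, vol,
                                 field_of_view = default_field_of_view(vol),
                                 resolution = 64L) {
  stopifnot(inherits(config, "sampler_config"), is_pose(sp_pose),
            inherits(vol, "us_volume"))
  n <- config$n_near_sp
  if (n == 0L) return(list())
  frac <- if (n == 1L) 1 else (seq_len(n) - 1) / (n - 1)
  t_int <- config$sp_trans_interval_max +
    frac * (config$sp_trans_interval_min - config$sp_trans_interval_max)
  r_int <- config$sp_rot_interval_max +
    frac * (config$sp_rot_interval_min - config$sp_rot_interval_max)
  lapply(seq_len(n), function(i) {
    draw <- function() {
      pose(sp_pose$rotation %*% random_rotation_in_range(r_int[i]),
           sp_pose$translation + runif(3L, -t_int[i], t_int[i]))
    }
    .rejection_sample(draw, vol, field_of_view, resolution, config$min_overlap)
  })
}

#' Read/write a standard-plane annotation (JSON)
#'
#' The annotation stores the pose of a manually identified standard plane:
#' `{volume_id, t, euler_deg, convention, annotator}`.
#'
#' @param path JSON file path.
#' @return For `read_sp_annotation`, a list with `pose` ([pose()]),
#'   `volume_id` and `annotator`.
#' @export
read_sp_annotation <- function(path) {
  if (!file.exists(path)) stopf("SP annotation not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("volume_id", "t", "euler_deg", "convention")
  miss <- setdiff(need, names(j))
  if (length(miss)) stopf("SP annotation missing field(s): %s", paste(miss, collapse = ", "))
  if (!identical(j$convention, EULER_CONVENTION))
    stopf("SP annotation uses Euler convention '%s'; this package uses '%s'",
          j$convention, EULER_CONVENTION)
  list(pose = pose_from_euler(as.numeric(j$euler_deg), as.numeric(j$t)),
       volume_id = j$volume_id, annotator = j$annotator %||% NA_character_)
}

#' @rdname read_sp_annotation
#' @param sp_pose the standard-plane [pose()].
#' @param volume_id identifier of the annotated volume.
#' @param annotator free-text annotator name.
#' @export
write_sp_annotation <- function(sp_pose, path, volume_id = "phantom",
                                annotator = "synthetic") {
  stopifnot(is_pose(sp_pose))
  jsonlite::write_json(
    list(volume_id = volume_id,
         t = sp_pose$translation,
         euler_deg = rotation_to_euler(sp_pose$rotation),
         convention = EULER_CONVENTION,
         annotator = annotator),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

MANIFEST_COLUMNS <- c("image_path", "volume_id", "subset",
                      "t_x", "t_y", "t_z", "a_x", "a_y", "a_z", "overlap")
MANIFEST_HEADER_KEYS <- c("euler_convention", "field_of_view", "resolution", "seed")

#' Build a labelled slice dataset from a volume
#'
#' Samples `config$n_random` random-pose planes (subset `RP`) and
#' `config$n_near_sp` near-standard-plane planes (subset `SP`), extracts each
#' slice, writes it as an 8-bit grayscale PNG under `out_dir/images/`, and
#' writes the manifest CSV (`manifest.csv`) with normalized translations,
#' Euler angles in degrees, and the achieved overlap per row. Deterministic
#' given `config$seed`.
#'
#' @param vol a [volume()].
#' @param config a [sampler_config()].
#' @param out_dir output directory (created if missing).
#' @param sp standard-plane annotation: a [pose()], a list with a `pose`
#'   element (as from [read_sp_annotation()]), or `NULL`. Required when
#'   `config$n_near_sp > 0`.
#' @param field_of_view slice side in mm; default [default_field_of_view()].
#' @param resolution slice resolution in pixels per side; default 128.
#' @param volume_id identifier recorded in every row.
#' @return The manifest, invisibly (see [read_manifest()] for its class).
#' @export
build_dataset <- function(vol, config, out_dir, sp = NULL,
                          field_of_view = default_field_of_view(vol),
                          resolution = 128L, volume_id = "phantom") {
  stopifnot(inherits(vol, "us_volume"), inherits(config, "sampler_config"))
  if (is.list(sp) && !is_pose(sp) && !is.null(sp$pose)) sp <- sp$pose
  if (config$n_near_sp > 0L && !is_pose(sp))
    stopf("'sp' (standard-plane pose) is required when n_near_sp > 0")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  resolution <- as.integer(resolution)

  rows <- with_seed(config$seed, {
    rp <- lapply(seq_len(config$n_random), function(i)
      sample_random_pose(config, vol, field_of_view, resolution))
    sps <- if (config$n_near_sp > 0L)
      sample_near_sp_poses(config, sp, vol, field_of_view, resolution)
    else list()
    list(rp = rp, sp = sps)
  })

  poses <- c(rows$rp, rows$sp)
  subset <- c(rep("RP", length(rows$rp)), rep("SP", length(rows$sp)))
  n <- length(poses)
  df <- data.frame(image_path = sprintf("images/%s_%05d.png", tolower(subset), seq_len(n)),
                   volume_id = volume_id, subset = subset,
                   t_x = NA_real_, t_y = NA_real_, t_z = NA_real_,
                   a_x = NA_real_, a_y = NA_real_, a_z = NA_real_,
                   overlap = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- poses[[i]]
    sl <- extract_slice(vol, slice_spec(p, field_of_view, resolution))
    png::writePNG(round(sl$pixels * 255) / 255, file.path(out_dir, df$image_path[i]))
    e <- rotation_to_euler(p$rotation)
    df[i, c("t_x", "t_y", "t_z")] <- p$translation
    df[i, c("a_x", "a_y", "a_z")] <- e
    df$overlap[i] <- sl$overlap
  }
  man <- new_manifest(df, field_of_view = field_of_view, resolution = resolution,
                      seed = config$seed, extent = vol$extent, dir = out_dir)
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  invisible(man)
}

new_manifest <- function(df, field_of_view, resolution, seed, extent = NULL,
                         dir = NULL) {
  structure(df, class = c("pose_manifest", "data.frame"),
            euler_convention = EULER_CONVENTION,
            field_of_view = field_of_view, resolution = as.integer(resolution),
            seed = as.integer(seed), extent = extent, dir = dir)
}

#' Write a dataset manifest to CSV
#'
#' The file carries a self-describing header block of `# key: value` lines
#' (Euler convention, field of view, resolution, seed, and the volume extent
#' when known) followed by the CSV table. Numeric fields are written at full
#' double precision.
#'
#' @param manifest a `pose_manifest` (from [build_dataset()] or
#'   [read_manifest()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "pose_manifest"))
  hdr <- c(sprintf("# euler_convention: %s", attr(manifest, "euler_convention")),
           sprintf("# field_of_view: %.17g", attr(manifest, "field_of_view")),
           sprintf("# resolution: %d", attr(manifest, "resolution")),
           sprintf("# seed: %d", attr(manifest, "seed")))
  ext <- attr(manifest, "extent")
  if (!is.null(ext))
    hdr <- c(hdr, sprintf("# extent_mm: %.17g %.17g %.17g", ext[1], ext[2], ext[3]))
  df <- as.data.frame(manifest)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset manifest from CSV
#'
#' Validates the header block (the Euler convention line is mandatory), the
#' column set, subset tags (`RP`/`SP` only) and finiteness of all numeric
#' fields.
#'
#' @param path manifest CSV path.
#' @return A `pose_manifest`: a data.frame with columns
#'   `image_path, volume_id, subset, t_x, t_y, t_z, a_x, a_y, a_z, overlap`
#'   and attributes `euler_convention`, `field_of_view`, `resolution`,
#'   `seed`, `extent` and `dir` (the manifest's directory, against which
#'   image paths are resolved).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  miss <- setdiff(MANIFEST_HEADER_KEYS, names(kv))
  if (length(miss))
    stopf("manifest header missing key(s): %s", paste(miss, collapse = ", "))
  if (!identical(kv$euler_convention, EULER_CONVENTION))
    stopf("manifest Euler convention '%s' differs from the package convention '%s'",
          kv$euler_convention, EULER_CONVENTION)
  df <- read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  miss <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(miss))
    stopf("manifest missing column(s): %s", paste(miss, collapse = ", "))
  bad <- which(!df$subset %in% c("RP", "SP"))
  if (length(bad))
    stopf("unknown subset tag '%s' in manifest row %d", df$subset[bad[1]], bad[1])
  numcols <- c("t_x", "t_y", "t_z", "a_x", "a_y", "a_z", "overlap")
  for (cc in numcols) {
    if (!is.numeric(df[[cc]]) || any(!is.finite(df[[cc]])))
      stopf("manifest column '%s' contains non-finite values", cc)
  }
  ext <- if (!is.null(kv$extent_mm)) as.numeric(strsplit(kv$extent_mm, "\\s+")[[1]])
  new_manifest(df[MANIFEST_COLUMNS],
               field_of_view = as.numeric(kv$field_of_view),
               resolution = as.integer(kv$resolution),
               seed = as.integer(kv$seed), extent = ext,
               dir = dirname(normalizePath(path)))
}

#' Load the slice images of a manifest into an array
#'
#' @param manifest a `pose_manifest`.
#' @param dir directory against which `image_path` is resolved; defaults to
#'   the manifest's own directory.
#' @return A numeric array `resolution x resolution x nrow(manifest)` in
#'   `[0, 1]`.
#' @export
load_manifest_images <- function(manifest, dir = attr(manifest, "dir")) {
  stopifnot(inherits(manifest, "pose_manifest"))
  if (is.null(dir)) stopf("manifest has no directory; pass 'dir'")
  res <- attr(manifest, "resolution")
  n <- nrow(manifest)
  arr <- array(0, c(res, res, n))
  for (i in seq_len(n)) {
    f <- file.path(dir, manifest$image_path[i])
    if (!file.exists(f)) stopf("manifest image not found: %s", f)
    px <- png::readPNG(f)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    arr[, , i] <- px
  }
  arr
}

#' Ground-truth poses of a manifest
#'
#' @param manifest a `pose_manifest`.
#' @return A list of [pose()] objects, one per row.
#' @export
manifest_poses <- function(manifest) {
  stopifnot(inherits(manifest, "pose_manifest"))
  lapply(seq_len(nrow(manifest)), function(i)
    pose_from_euler(as.numeric(manifest[i, c("a_x", "a_y", "a_z")]),
                    as.numeric(manifest[i, c("t_x", "t_y", "t_z")])))
}
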