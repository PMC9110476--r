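# Error metrics and per-subset (RP vs SP) median/min/max reporting.

#' Translation error between two poses, in mm
#'
#' Euclidean distance between the two plane centres after denormalizing both
#' translations to mm with the evaluated volume's own extent (normalized
#' units are volume-relative, so the conversion scale is per volume).
#'
#' @param pred,gt [pose()] objects.
#' @param extent volume physical size per axis, mm.
#' @return Distance in mm (symmetric in its pose arguments).
#' @export
translation_error_mm <- function(pred, gt, extent) {
  stopifnot(is_pose(pred), is_pose(gt))
  d <- denormalize_translation(pred$translation, extent) -
    denormalize_translation(gt$translation, extent)
  sqrt(sum(d^2))
}

#' Rotation error between two poses, in degrees
#'
#' Geodesic distance between the two orientations
#' (see [geodesic_distance_deg()]).
#'
#' @param pred,gt [pose()] objects.
#' @return Angle in degrees in `[0, 180]`.
#' @export
rotation_error_deg <- function(pred, gt) {
  stopifnot(is_pose(pred), is_pose(gt))
  geodesic_distance_deg(pred$rotation, gt$rotation)
}

#' Median / min / max of a numeric vector
#'
#' Standard order statistics; the median of an even-length vector is the
#' midpoint of the central pair.
#'
#' @param values non-empty numeric vector.
#' @return Named list with `median`, `min`, `max`.
#' @export
aggregate_stats <- function(values) {
  if (!length(values) || !is.numeric(values) || any(!is.finite(values)))
    stopf("'values' must be a non-empty finite numeric vector")
  list(median = median(values), min = min(values), max = max(values))
}

#' Evaluate a model (or oracle predictions) on a manifest
#'
#' Predicts a pose for every manifest row, computes the per-plane
#' translation error in mm and geodesic rotation error in degrees against
#' the stored labels, and aggregates median/min/max per subset (`Test RP` /
#' `Test SP`). Empty subsets are omitted with a warning.
#'
#' @param model a fitted `"pose_model"`, or a list of [pose()] predictions
#'   of length `nrow(manifest)` (e.g. the labels themselves, as an oracle
#'   check).
#' @param manifest a `pose_manifest`.
#' @param dir directory resolving image paths (unused when `model` is a
#'   pose list).
#' @param extent volume extent in mm used for denormalization; defaults to
#'   the extent recorded in the manifest.
#' @param records_csv optional path: when given, the full per-record table
#'   is written there as CSV.
#' @return An object of class `"pose_eval"`: `records` (data.frame with
#'   `image_path, subset, trans_err_mm, rot_err_deg`), `stats` (data.frame
#'   with one row per subset x metric), `extent` and `counts`.
#' @export
evaluate_model <- function(model, manifest, dir = attr(manifest, "dir"),
                           extent = attr(manifest, "extent"),
                           records_csv = NULL) {
  stopifnot(inherits(manifest, "pose_manifest"))
  if (is.null(extent))
    stopf("volume extent unknown: pass 'extent' (mm per axis)")
  n <- nrow(manifest)
  gt <- manifest_poses(manifest)
  preds <- if (inherits(model, "pose_model")) {
    images <- load_manifest_images(manifest, dir)
    out <- network_forward(model$network, images)
    lapply(seq_len(n), function(i) output_to_pose(out[, i]))
  } else if (is.list(model) && all(vapply(model, is_pose, logical(1)))) {
    if (length(model) != n)
      stopf("prediction list has %d elements for %d manifest rows", length(model), n)
    model
  } else stopf("'model' must be a pose_model or a list of poses")

  records <- data.frame(
    image_path = manifest$image_path, subset = manifest$subset,
    trans_err_mm = vapply(seq_len(n), function(i)
      translation_error_mm(preds[[i]], gt[[i]], extent), numeric(1)),
    rot_err_deg = vapply(seq_len(n), function(i)
      rotation_error_deg(preds[[i]], gt[[i]]), numeric(1)),
    stringsAsFactors = FALSE)

  stats <- do.call(rbind, lapply(c("RP", "SP"), function(sub) {
    r <- records[records$subset == sub, ]
    if (!nrow(r)) {
      warning(sprintf("subset %s is empty; omitted from the report", sub))
      return(NULL)
    }
    tr <- aggregate_stats(r$trans_err_mm)
    ro <- aggregate_stats(r$rot_err_deg)
    data.frame(subset = paste("Test", sub),
               trans_median_mm = tr$median, trans_min_mm = tr$min,
               trans_max_mm = tr$max, rot_median_deg = ro$median,
               rot_min_deg = ro$min, rot_max_deg = ro$max,
               n = nrow(r), stringsAsFactors = FALSE)
  }))
  if (!is.null(records_csv)) write.csv(records, records_csv, row.names = FALSE)
  structure(list(records = records, stats = stats, extent = extent,
                 counts = table(manifest$subset)),
            class = "pose_eval")
}

#' @export
print.pose_eval <- function(x, ...) {
  cat("Plane pose regression errors (per subset)\n")
  cat(sprintf("  volume extent used for mm conversion: %s mm\n\n",
              paste(signif(x$extent, 5), collapse = " x ")))
  s <- x$stats
  cat(sprintf("  %-8s %28s   %28s\n", "", "Translation Norm [mm]", "Rotation GE [deg]"))
  cat(sprintf("  %-8s %9s %9s %9s   %9s %9s %9s\n", "",
              "Median", "Min", "Max", "Median", "Min", "Max"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %9.3f %9.3f %9.3f   %9.3f %9.3f %9.3f\n",
                s$subset[i], s$trans_median_mm[i], s$trans_min_mm[i],
                s$trans_max_mm[i], s$rot_median_deg[i], s$rot_min_deg[i],
                s$rot_max_deg[i]))
  invisible(x)
}

#' Summary as a JSON-ready list
#'
#' @param object a `"pose_eval"`.
#' @param ... unused.
#' @return A plain list mirroring the stats table, suitable for
#'   `jsonlite::write_json()`.
#' @export
summary.pose_eval <- function(object, ...) {
  s <- object$stats
  out <- lapply(seq_len(nrow(s)), function(i) as.list(s[i, -1]))
  names(out) <- s$subset
  out$extent_mm <- object$extent
  out
}

#' Constant mean-pose baseline predictor
#'
#' The strongest constant predictor: the per-axis mean of the training
#' translations and the chordal mean of the training rotations (the SVD
#' projection of the averaged rotation matrices back onto SO(3)). Used as
#' the reference the trained network must beat.
#'
#' @param manifest a `pose_manifest` of training labels.
#' @return A [pose()].
#' @export
baseline_mean_pose <- function(manifest) {
  stopifnot(inherits(manifest, "pose_manifest"))
  gt <- manifest_poses(manifest)
  t_mean <- rowMeans(vapply(gt, function(p) p$translation, numeric(3)))
  M <- Reduce(`+`, lapply(gt, function(p) p$rotation)) / length(gt)
  sv <- svd(M)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  pose(R, t_mean)
}
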