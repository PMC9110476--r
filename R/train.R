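# Training loop: seeded split/shuffle/init, Adam on the flat parameter
# vector, per-epoch train/val loss history, best-epoch checkpointing.

# labels for a manifest: list(t = 3 x N, R = 3 x 3 x N)
.manifest_labels <- function(manifest) {
  n <- nrow(manifest)
  t_gt <- t(as.matrix(manifest[, c("t_x", "t_y", "t_z")]))
  R_gt <- array(0, c(3, 3, n))
  for (i in seq_len(n))
    R_gt[, , i] <- euler_to_rotation(as.numeric(manifest[i, c("a_x", "a_y", "a_z")]))
  list(t = t_gt, R = R_gt)
}

.batch_loss <- function(ptr, images, labels, idx, lambda, squared, want_grad) {
  nn_loss_grad_cpp(ptr, images[, , idx, drop = FALSE],
                   labels$t[, idx, drop = FALSE],
                   labels$R[, , idx, drop = FALSE],
                   lambda, squared, want_grad)
}

# mean loss over a set, computed in batches without gradients
.set_loss <- function(ptr, images, labels, idx, lambda, squared, batch_size) {
  tot <- rot <- trans <- 0
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    l <- .batch_loss(ptr, images, labels, b, lambda, squared, want_grad = FALSE)
    w <- length(b) / length(idx)
    tot <- tot + w * l$loss_total
    rot <- rot + w * l$loss_rot
    trans <- trans + w * l$loss_trans
  }
  c(total = tot, rot = rot, trans = trans)
}

#' Train a plane-pose regression model
#'
#' Fits the CNN of `config$backbone` to the labelled slices of a dataset
#' manifest. The run is deterministic given `config$seed` (which covers the
#' validation split, epoch shuffling and weight initialization): a seeded
#' `val_fraction` share of the rows is held out for validation, the rest is
#' shuffled each epoch into minibatches optimized by Adam on the total loss
#' `L_rot + lambda * L_trans`, and the returned weights are those of the
#' epoch with the lowest validation total loss. With `epochs = 0` the model
#' keeps its random initialization and the history is empty.
#'
#' @param manifest a `pose_manifest` (see [build_dataset()] /
#'   [read_manifest()]).
#' @param config a [train_config()]; `config$image_size` must match the
#'   manifest resolution.
#' @param dir directory resolving the manifest's image paths.
#' @param verbose emit one machine-parseable progress line per epoch to
#'   stderr.
#' @return An object of class `"pose_model"`: fields `network`
#'   (`pose_network` with the best weights), `config`, `history` (data.frame
#'   with per-epoch train/val total, rotation and translation losses),
#'   `best_epoch` and `manifest_fingerprint`.
#' @seealso [predict.pose_model()], [evaluate_model()], [save_pose_model()]
#' @export
train_pose_model <- function(manifest, config = train_config(),
                             dir = attr(manifest, "dir"), verbose = FALSE) {
  stopifnot(inherits(manifest, "pose_manifest"), inherits(config, "train_config"))
  if (nrow(manifest) == 0L) stopf("manifest is empty")
  res <- attr(manifest, "resolution")
  if (!is.null(res) && res != config$image_size)
    stopf("manifest resolution (%d px) does not match config image_size (%d px)",
          res, config$image_size)
  images <- load_manifest_images(manifest, dir)
  labels <- .manifest_labels(manifest)
  n <- nrow(manifest)

  fit <- with_seed(config$seed, {
    net <- build_network(config)
    ptr <- net$ptr
    n_val <- max(1L, round(config$val_fraction * n))
    if (n_val >= n) stopf("dataset too small for a %.0f%% validation split",
                          100 * config$val_fraction)
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)

    npar <- length(net$params)
    theta <- net$params
    m <- numeric(npar); v <- numeric(npar)
    step <- 0L
    total_steps <- config$epochs * ceiling(length(train_idx) / config$batch_size)
    lr_at <- function(s) {
      if (identical(config$lr_schedule, "cosine")) {
        lr_min <- config$learning_rate / 25
        lr_min + 0.5 * (config$learning_rate - lr_min) *
          (1 + cos(pi * (s - 1) / max(total_steps - 1, 1)))
      } else config$learning_rate
    }
    lam <- config$lambda_weight
    hist <- vector("list", config$epochs)
    best <- list(val = Inf, params = theta, buffers = net$buffers, epoch = 0L)

    for (ep in seq_len(config$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tr_tot <- tr_rot <- tr_trans <- 0
      for (b in batches) {
        l <- .batch_loss(ptr, images, labels, b, lam, config$squared, TRUE)
        step <- step + 1L
        g <- l$grad
        m <- config$beta1 * m + (1 - config$beta1) * g
        v <- config$beta2 * v + (1 - config$beta2) * g^2
        mhat <- m / (1 - config$beta1^step)
        vhat <- v / (1 - config$beta2^step)
        theta <- theta - lr_at(step) * mhat / (sqrt(vhat) + 1e-8)
        nn_set_params(ptr, theta)
        w <- length(b) / length(ord)
        tr_tot <- tr_tot + w * l$loss_total
        tr_rot <- tr_rot + w * l$loss_rot
        tr_trans <- tr_trans + w * l$loss_trans
      }
      vl <- .set_loss(ptr, images, labels, val_idx, lam, config$squared,
                      config$batch_size)
      hist[[ep]] <- data.frame(epoch = ep, train_total = tr_tot,
                               train_rot = tr_rot, train_trans = tr_trans,
                               val_total = vl["total"], val_rot = vl["rot"],
                               val_trans = vl["trans"], row.names = NULL)
      if (vl["total"] < best$val)
        best <- list(val = vl["total"], params = theta,
                     buffers = nn_get_buffers(ptr), epoch = ep)
      if (verbose)
        message(sprintf(
          "epoch=%d train_total=%.6f train_rot=%.6f train_trans=%.6f val_total=%.6f",
          ep, tr_tot, tr_rot, tr_trans, vl["total"]))
    }
    history <- if (config$epochs > 0) do.call(rbind, hist) else
      data.frame(epoch = integer(), train_total = numeric(),
                 train_rot = numeric(), train_trans = numeric(),
                 val_total = numeric(), val_rot = numeric(),
                 val_trans = numeric())
    net$params <- best$params
    net$buffers <- best$buffers
    nn_set_params(ptr, net$params)
    nn_set_buffers(ptr, net$buffers)
    list(net = net, history = history, best_epoch = best$epoch)
  })

  structure(list(network = fit$net, config = config, history = fit$history,
                 best_epoch = fit$best_epoch,
                 manifest_fingerprint = manifest_fingerprint(manifest)),
            class = "pose_model")
}

#' Fingerprint of a manifest's labels
#'
#' A cheap content signature (row count, subset counts and label column
#' sums) recorded in every checkpoint so a model can be matched to its
#' training data.
#'
#' @param manifest a `pose_manifest`.
#' @return A character scalar.
#' @export
manifest_fingerprint <- function(manifest) {
  stopifnot(inherits(manifest, "pose_manifest"))
  num <- as.matrix(manifest[, c("t_x", "t_y", "t_z", "a_x", "a_y", "a_z")])
  sprintf("n=%d;rp=%d;sp=%d;sum=%.10e", nrow(manifest),
          sum(manifest$subset == "RP"), sum(manifest$subset == "SP"),
          sum(num))
}

#' @export
print.pose_model <- function(x, ...) {
  cat(sprintf("<pose_model> backbone=%s image_size=%d, %d parameters\n",
              x$config$backbone, x$config$image_size,
              length(x$network$params)))
  if (nrow(x$history)) {
    cat(sprintf("  trained %d epoch(s); best epoch %d (val total loss %.5f)\n",
                nrow(x$history), x$best_epoch,
                x$history$val_total[x$best_epoch]))
  } else cat("  untrained (random initialization)\n")
  invisible(x)
}

#' @export
summary.pose_model <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("\nLoss history (first/last epochs):\n")
    h <- object$history
    print(rbind(head(h, 2), tail(h, 2)), row.names = FALSE, digits = 5)
  }
  invisible(object)
}

#' Plot training and validation loss curves
#'
#' @param x a fitted `"pose_model"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pose_model <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("model has no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$epoch, cbind(h$train_total, h$val_total), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "total loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict the pose of one or more images
#'
#' Images are preprocessed to the model's input size (resized preserving the
#' aspect ratio, then centre-cropped; see [preprocess_image()]) and pushed
#' through the network; the head output is projected onto a valid pose by
#' Gram-Schmidt.
#'
#' @param object a fitted `"pose_model"`.
#' @param images a single 2D grayscale matrix in `[0, 1]`, or an
#'   `H x W x N` array.
#' @param ... unused.
#' @return For a single image, a [pose()] (with the Euler-angle reading of
#'   its rotation attached as attribute `"euler_deg"` for display); for a
#'   batch, a list of poses.
#' @export
predict.pose_model <- function(object, images, ...) {
  single <- is.matrix(images)
  if (single) images <- array(images, c(dim(images), 1L))
  if (length(dim(images)) != 3L)
    stopf("'images' must be a 2D matrix or an H x W x N array")
  size <- object$config$image_size
  prep <- array(0, c(size, size, dim(images)[3]))
  for (i in seq_len(dim(images)[3]))
    prep[, , i] <- preprocess_image(images[, , i], size)
  out <- network_forward(object$network, prep)
  poses <- lapply(seq_len(ncol(out)), function(i) {
    p <- output_to_pose(out[, i])
    attr(p, "euler_deg") <- rotation_to_euler(p$rotation)
    p
  })
  if (single) poses[[1]] else poses
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single RDS archive holding the weights, buffers,
#' config, loss history, best epoch and training-data fingerprint. The
#' native network handle is rebuilt transparently on load.
#'
#' @param model a `"pose_model"`.
#' @param path checkpoint file path.
#' @return `save_pose_model` returns `path` invisibly; `load_pose_model`
#'   returns the restored `"pose_model"`.
#' @export
save_pose_model <- function(model, path) {
  stopifnot(inherits(model, "pose_model"))
  model$network$ptr <- NULL
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pose_model
#' @export
load_pose_model <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  model <- readRDS(path)
  stopifnot(inherits(model, "pose_model"))
  model$network$ptr <- .network_handle(model$network)
  model
}
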