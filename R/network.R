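# Network contract: backbone + 9-parameter head, Gram-Schmidt forward
# reconstruction, and the weighted rotation/translation loss.

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam with learning rate
#' 1e-4 (`beta1 = 0.9`, `beta2 = 0.999`), batch size 100, 50 epochs,
#' `lambda = 0.01` weighting the translation loss against the rotation loss,
#' a seeded 20% validation split, and 128 px input images. The `smallconv`
#' backbone (4 strided conv blocks + 2 fully connected layers) is a compact
#' CPU-trainable variant of the `resnet18` backbone.
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam exponential decay rates.
#' @param lambda_weight weight of the translation loss in the total loss.
#' @param val_fraction fraction of the training set held out for validation,
#'   in `(0, 1)`.
#' @param image_size input image side in pixels (>= 32; `smallconv` requires
#'   a multiple of 16).
#' @param backbone `"resnet18"` or `"smallconv"`.
#' @param lr_schedule `"constant"`, or `"cosine"` for a cosine decay of the
#'   learning rate from `learning_rate` to `learning_rate / 25` across the
#'   run (helpful for short schedules, where late high-variance updates
#'   otherwise undo earlier progress).
#' @param pretrained logical; request externally pretrained backbone
#'   weights. No weight files ship with this package, so `TRUE` errors at
#'   network construction — train from random initialization instead.
#' @param squared use squared norms in the losses instead of the default
#'   plain norms (see [translation_loss()]).
#' @param seed integer seed covering split, shuffling and initialization.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 50, batch_size = 100, learning_rate = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, lambda_weight = 0.01,
                         val_fraction = 0.2, image_size = 128,
                         backbone = c("resnet18", "smallconv"),
                         lr_schedule = c("constant", "cosine"),
                         pretrained = FALSE, squared = FALSE, seed = 1L) {
  backbone <- match.arg(backbone)
  lr_schedule <- match.arg(lr_schedule)
  if (!is_number(val_fraction) || val_fraction <= 0 || val_fraction >= 1)
    stopf("'val_fraction' must be in (0, 1)")
  if (!is_number(lambda_weight) || lambda_weight <= 0)
    stopf("'lambda_weight' must be > 0")
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L)
    stopf("'image_size' must be an integer >= 32")
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (is.na(epochs) || epochs < 0L) stopf("'epochs' must be >= 0")
  if (is.na(batch_size) || batch_size < 1L) stopf("'batch_size' must be >= 1")
  if (!is_number(learning_rate) || learning_rate <= 0)
    stopf("'learning_rate' must be > 0")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 lambda_weight = lambda_weight, val_fraction = val_fraction,
                 image_size = image_size, backbone = backbone,
                 lr_schedule = lr_schedule,
                 pretrained = isTRUE(pretrained), squared = isTRUE(squared),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a pose-regression network
#'
#' Constructs the backbone + 9-output regression head and draws He-normal
#' initial weights from the current R random stream (wrap in `set.seed()`
#' for reproducible initialization). The network maps a single-channel
#' `image_size` x `image_size` image to the 9-vector
#' `theta = (t1, t2, t3, r1, ..., r6)`.
#'
#' @param config a [train_config()].
#' @return A list of class `"pose_network"` holding the native network
#'   handle, its parameter vector and the config.
#' @export
build_network <- function(config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (config$pretrained)
    stopf(paste0("pretrained backbone weights are not bundled with this ",
                 "package; set pretrained = FALSE to train from random ",
                 "initialization"))
  ptr <- nn_create(config$backbone, config$image_size, 1L)
  info <- nn_param_info(ptr)
  params <- numeric(sum(info$size))
  off <- 0L
  for (i in seq_along(info$size)) {
    n <- info$size[i]
    params[off + seq_len(n)] <- switch(info$kind[i],
      weight = rnorm(n) * sqrt(2 / info$fan_in[i]),
      bias = 0,
      bn_gamma = 1,
      bn_beta = 0,
      stopf("unknown parameter kind '%s'", info$kind[i]))
    off <- off + n
  }
  nn_set_params(ptr, params)
  structure(list(ptr = ptr, params = params, buffers = nn_get_buffers(ptr),
                 config = config),
            class = "pose_network")
}

# rebuild the native handle when absent or stale (e.g. after a checkpoint
# was deserialized from disk, which cannot preserve external pointers)
.network_handle <- function(net) {
  if (!is.null(net$ptr) && nn_ptr_valid(net$ptr)) return(net$ptr)
  ptr <- nn_create(net$config$backbone, net$config$image_size, 1L)
  nn_set_params(ptr, net$params)
  nn_set_buffers(ptr, net$buffers)
  ptr
}

#' Raw network forward pass
#'
#' @param net a `"pose_network"` (or fitted [train_pose_model()] object).
#' @param images array `H x W x N` (or a single `H x W` matrix) in `[0, 1]`.
#' @return A 9 x N matrix of head outputs `(t1, t2, t3, r1..r6)` per column.
#' @export
network_forward <- function(net, images) {
  if (inherits(net, "pose_model")) net <- net$network
  stopifnot(inherits(net, "pose_network"))
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  stopifnot(length(dim(images)) == 3L)
  ptr <- .network_handle(net)
  nn_set_params(ptr, net$params)
  nn_set_buffers(ptr, net$buffers)
  nn_forward_cpp(ptr, images, train = FALSE)
}

#' Convert a raw network output to a pose
#'
#' Splits the 9-vector into translation `t = theta[1:3]` and the 6D rotation
#' representation `r = theta[4:9]`, reconstructing the rotation by
#' [gram_schmidt_to_rotation()]. Degenerate rotation heads (zero or parallel
#' half-vectors) raise an error rather than returning NaNs.
#'
#' @param theta numeric 9-vector `(t1, t2, t3, r1..r6)`.
#' @return A [pose()].
#' @export
output_to_pose <- function(theta) {
  if (length(theta) != 9L || !all(is.finite(theta)))
    stopf("'theta' must be a finite 9-vector (t1..t3, r1..r6)")
  pose(sixd_to_rotation(theta[4:9]), theta[1:3])
}

#' Translation loss: batch mean of Euclidean distances
#'
#' `mean(||t_pred - t_gt||_2)` over the batch; with `squared = TRUE` the
#' squared norms are averaged instead.
#'
#' @param t_pred,t_gt numeric 3-vectors or 3 x N matrices.
#' @param squared average squared norms instead of norms.
#' @return A scalar loss.
#' @export
translation_loss <- function(t_pred, t_gt, squared = FALSE) {
  if (is.vector(t_pred)) t_pred <- matrix(t_pred, nrow = 3L)
  if (is.vector(t_gt)) t_gt <- matrix(t_gt, nrow = 3L)
  if (!all(dim(t_pred) == dim(t_gt)) || nrow(t_pred) != 3L)
    stopf("'t_pred' and 't_gt' must both be 3 x N")
  d <- sqrt(colSums((t_pred - t_gt)^2))
  if (squared) mean(d^2) else mean(d)
}

#' Rotation loss: batch mean of Frobenius-norm differences
#'
#' `mean(||R_pred - R_gt||_F)` over the batch (squared with
#' `squared = TRUE`). For rotation matrices the value is bounded by
#' `2 * sqrt(2)` (attained for 180-degree-apart rotations).
#'
#' @param R_pred,R_gt 3x3 matrices or 3 x 3 x N arrays.
#' @inheritParams translation_loss
#' @return A scalar loss.
#' @export
rotation_loss <- function(R_pred, R_gt, squared = FALSE) {
  if (is.matrix(R_pred)) R_pred <- array(R_pred, c(3, 3, 1))
  if (is.matrix(R_gt)) R_gt <- array(R_gt, c(3, 3, 1))
  if (!all(dim(R_pred) == dim(R_gt)) || !all(dim(R_pred)[1:2] == c(3, 3)))
    stopf("'R_pred' and 'R_gt' must both be 3 x 3 x N")
  d <- sqrt(apply((R_pred - R_gt)^2, 3, sum))
  if (squared) mean(d^2) else mean(d)
}

#' Total loss: rotation + lambda * translation
#'
#' @param l_rot,l_trans scalar rotation and translation losses.
#' @param lambda positive weighting hyperparameter (reference value 0.01).
#' @return `l_rot + lambda * l_trans`.
#' @export
total_loss <- function(l_rot, l_trans, lambda = 0.01) {
  if (!is_number(lambda) || lambda <= 0) stopf("'lambda' must be > 0")
  l_rot + lambda * l_trans
}
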