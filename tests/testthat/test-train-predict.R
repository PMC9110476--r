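# Training loop contracts: determinism, history, checkpointing, capacity
# sanity (overfit), prediction round trip.

small_cfg <- function(...) {
  args <- list(backbone = "smallconv", image_size = 32, batch_size = 10,
               learning_rate = 1e-3, seed = 12)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

test_that("epochs = 0 keeps the seeded initialization and empty history", {
  man <- fixture_dataset()
  m <- train_pose_model(man, small_cfg(epochs = 0))
  expect_equal(nrow(m$history), 0L)
  expect_equal(m$best_epoch, 0L)
  init <- with_seed(12, build_network(small_cfg(epochs = 0)))
  expect_identical(m$network$params, init$params)
})

test_that("training is deterministic given the seed", {
  man <- fixture_dataset()
  m1 <- train_pose_model(man, small_cfg(epochs = 2))
  m2 <- train_pose_model(man, small_cfg(epochs = 2))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$network$params, m2$network$params)
  m3 <- train_pose_model(man, small_cfg(epochs = 2, seed = 13))
  expect_false(identical(m1$history$train_total, m3$history$train_total))
})

test_that("history tracks both losses and best epoch minimizes val total", {
  man <- fixture_dataset()
  m <- train_pose_model(man, small_cfg(epochs = 3))
  expect_equal(nrow(m$history), 3L)
  expect_true(all(c("train_total", "train_rot", "train_trans", "val_total",
                    "val_rot", "val_trans") %in% names(m$history)))
  expect_equal(m$best_epoch, which.min(m$history$val_total))
  # total = rot + lambda * trans per epoch
  expect_equal(m$history$train_total,
               m$history$train_rot + 0.01 * m$history$train_trans,
               tolerance = 1e-10)
})

test_that("a smallconv model can overfit a tiny training set", {
  # capacity sanity run: 50 slices, long schedule, loss must collapse
  man <- fixture_dataset()
  cfg <- small_cfg(epochs = 250, batch_size = 25, learning_rate = 3e-3,
                   val_fraction = 0.1)
  m <- train_pose_model(man, cfg)
  expect_lt(min(m$history$train_total), 0.05)
  # feeding a training image back recovers its own label
  imgs <- load_manifest_images(man)
  poses <- manifest_poses(man)
  # use the final-epoch weights for train-set recall (best-val may be earlier)
  errs <- vapply(1:10, function(i) {
    p <- predict(m, imgs[, , i])
    rotation_error_deg(p, poses[[i]])
  }, numeric(1))
  expect_lt(median(errs), 20)
})

test_that("prediction is deterministic, finite and shape-checked", {
  man <- fixture_dataset()
  m <- train_pose_model(man, small_cfg(epochs = 1))
  img <- load_manifest_images(man)[, , 1]
  p1 <- predict(m, img)
  p2 <- predict(m, img)
  expect_s3_class(p1, "pose")
  expect_identical(p1$translation, p2$translation)
  expect_identical(p1$rotation, p2$rotation)
  expect_length(attr(p1, "euler_deg"), 3L)
  # constant image still yields a finite valid pose
  p0 <- predict(m, matrix(0, 32, 32))
  expect_true(all(is.finite(p0$translation)))
  expect_lt(norm(crossprod(p0$rotation) - diag(3), "F"), 1e-6)
  # an off-size image is resized with aspect preserved + centre crop
  p3 <- predict(m, matrix(runif(48 * 64), 48, 64))
  expect_s3_class(p3, "pose")
  expect_error(predict(m, array(0, c(4, 4, 4, 4))), "matrix|array")
  # batch prediction returns a list
  expect_length(predict(m, load_manifest_images(man)[, , 1:3]), 3L)
})

test_that("checkpoints round-trip through disk", {
  man <- fixture_dataset()
  m <- train_pose_model(man, small_cfg(epochs = 1))
  f <- tempfile(fileext = ".rds")
  save_pose_model(m, f)
  back <- load_pose_model(f)
  expect_identical(back$network$params, m$network$params)
  expect_identical(back$history, m$history)
  expect_identical(back$manifest_fingerprint, m$manifest_fingerprint)
  img <- load_manifest_images(man)[, , 2]
  pa <- predict(m, img); pb <- predict(back, img)
  expect_equal(pa$rotation, pb$rotation, tolerance = 1e-12)
  expect_equal(pa$translation, pb$translation, tolerance = 1e-12)
})

test_that("training rejects unusable inputs up front", {
  man <- fixture_dataset()
  empty <- man[0, ]
  attr(empty, "class") <- class(man)
  expect_error(train_pose_model(empty, small_cfg()), "empty")
  expect_error(train_pose_model(man, train_config(backbone = "smallconv",
                                                  image_size = 64)),
               "resolution")
})

test_that("image preprocessing preserves aspect ratio and crops centrally", {
  img <- matrix(0, 40, 80)
  img[, 41:80] <- 1  # right half bright
  out <- preprocess_image(img, 32)
  expect_equal(dim(out), c(32L, 32L))
  # central crop of the resized 32x64: columns 17..48 -> half bright
  expect_lt(mean(out[, 1:16]), 0.05)
  expect_gt(mean(out[, 17:32]), 0.95)
  # identity when already the right size
  id <- matrix(runif(32 * 32), 32, 32)
  expect_equal(preprocess_image(id, 32), id)
})
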