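# Network contract, pose head reconstruction and the training losses.

test_that("network outputs have the 9-parameter contract shape", {
  set.seed(20)
  cfg <- train_config(backbone = "smallconv", image_size = 64)
  net <- build_network(cfg)
  x <- array(runif(64 * 64 * 4), c(64, 64, 4))
  out <- network_forward(net, x)
  expect_equal(dim(out), c(9L, 4L))
  expect_true(all(is.finite(out)))
  # resnet18 variant builds and runs forward too
  cfg2 <- train_config(backbone = "resnet18", image_size = 64)
  net2 <- with_seed(3, build_network(cfg2))
  out2 <- network_forward(net2, x[, , 1:2])
  expect_equal(dim(out2), c(9L, 2L))
  expect_true(all(is.finite(out2)))
  expect_error(build_network(train_config(backbone = "smallconv",
                                          image_size = 40)), "divisible")
})

test_that("unsupported construction requests error out", {
  expect_error(train_config(backbone = "vgg"), "arg")
  expect_error(build_network(train_config(pretrained = TRUE)), "pretrained")
  expect_error(train_config(lambda_weight = 0), "lambda")
  expect_error(train_config(val_fraction = 1), "val_fraction")
})

test_that("initialization is deterministic under a fixed seed", {
  cfg <- train_config(backbone = "smallconv", image_size = 64)
  n1 <- with_seed(9, build_network(cfg))
  n2 <- with_seed(9, build_network(cfg))
  expect_identical(n1$params, n2$params)
  x <- array(0.5, c(64, 64, 2))
  expect_identical(network_forward(n1, x), network_forward(n2, x))
})

test_that("output_to_pose applies Gram-Schmidt and its invariances", {
  p <- output_to_pose(c(0, 0, 0, 1, 0, 0, 0, 1, 0))
  expect_equal(p$rotation, diag(3))
  expect_equal(p$translation, c(0, 0, 0))
  set.seed(21)
  for (k in 1:50) {
    R <- random_so3()
    theta <- c(runif(3, -1, 1), rotation_to_sixd(R))
    p <- output_to_pose(theta)
    expect_equal(p$rotation, R, tolerance = 1e-9)
    # scale invariance of the reconstruction
    p5 <- output_to_pose(c(theta[1:3], 5 * theta[4:9]))
    expect_equal(p5$rotation, R, tolerance = 1e-9)
  }
  expect_error(output_to_pose(c(0, 0, 0, 0, 0, 0, 1, 0, 0)), "degenerate")
  expect_error(output_to_pose(rep(1, 8)), "9-vector")
})

test_that("forward reconstruction is always a valid rotation", {
  # whatever the raw head emits, Gram-Schmidt projects onto SO(3)
  set.seed(22)
  for (k in 1:200) {
    theta <- rnorm(9, sd = 3)
    R <- sixd_to_rotation(theta[4:9])
    expect_lt(norm(crossprod(R) - diag(3), "F"), 1e-6)
    expect_lt(abs(det(R) - 1), 1e-6)
  }
})

test_that("losses reproduce hand-computed values", {
  expect_equal(translation_loss(c(1, 0, 0), c(0, 0, 0)), 1.0)
  expect_equal(translation_loss(cbind(c(1, 0, 0), c(0, 0, 0)),
                                matrix(0, 3, 2)), 0.5)
  expect_equal(translation_loss(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(translation_loss(c(2, 0, 0), c(0, 0, 0), squared = TRUE), 4)
  # identity vs Rz(180): difference diag(-2,-2,0) -> Frobenius sqrt(8)
  expect_equal(rotation_loss(diag(3), euler_to_rotation(c(0, 0, 180))), sqrt(8))
  expect_equal(rotation_loss(diag(3), diag(3)), 0)
  expect_equal(total_loss(0.2, 3.0, lambda = 0.01), 0.23, tolerance = 1e-9)
  expect_equal(total_loss(0, 0, lambda = 0.5), 0)
  # lambda scales only the translation term
  expect_equal(total_loss(0.2, 3.0, 0.1) - 0.2, 10 * (total_loss(0.2, 3.0, 0.01) - 0.2))
  expect_error(translation_loss(matrix(0, 3, 2), matrix(0, 3, 3)), "3 x N")
  expect_error(total_loss(1, 1, lambda = -1), "lambda")
})

test_that("rotation loss is bounded by 2*sqrt(2) on SO(3)", {
  set.seed(23)
  worst <- 0
  for (k in 1:2000) {
    worst <- max(worst, rotation_loss(random_so3(), random_so3()))
    }
  expect_lte(worst, 2 * sqrt(2))
  expect_gt(worst, 2 * sqrt(2) - 0.1)  # the bound is approached
})

test_that("batch loss kernel agrees with the R reference implementation", {
  set.seed(24)
  cfg <- train_config(backbone = "smallconv", image_size = 32,
                      lambda_weight = 0.01)
  net <- build_network(cfg)
  N <- 5
  x <- array(runif(32 * 32 * N), c(32, 32, N))
  t_gt <- matrix(runif(3 * N, -1, 1), 3, N)
  R_gt <- array(0, c(3, 3, N))
  for (i in 1:N) R_gt[, , i] <- random_so3()
  out <- network_forward(net, x)
  # R-side reference: project each head output, then the documented losses
  R_pred <- array(0, c(3, 3, N))
  for (i in 1:N) R_pred[, , i] <- sixd_to_rotation(out[4:9, i])
  l_ref_rot <- rotation_loss(R_pred, R_gt)
  l_ref_trans <- translation_loss(out[1:3, ], t_gt)
  l <- planepose:::nn_loss_grad_cpp(net$ptr, x, t_gt, R_gt, 0.01,
                                    FALSE, FALSE)
  expect_equal(l$loss_rot, l_ref_rot, tolerance = 1e-10)
  expect_equal(l$loss_trans, l_ref_trans, tolerance = 1e-10)
  expect_equal(l$loss_total, total_loss(l_ref_rot, l_ref_trans, 0.01),
               tolerance = 1e-10)
})

test_that("analytic gradients match finite differences through Gram-Schmidt", {
  set.seed(25)
  cfg <- train_config(backbone = "smallconv", image_size = 32,
                      lambda_weight = 0.01)
  net <- build_network(cfg)
  ptr <- net$ptr
  N <- 3
  x <- array(runif(32 * 32 * N), c(32, 32, N))
  t_gt <- matrix(runif(3 * N, -1, 1), 3, N)
  R_gt <- array(0, c(3, 3, N))
  for (i in 1:N) R_gt[, , i] <- random_so3()
  buf <- planepose:::nn_get_buffers(ptr)
  for (sq in c(FALSE, TRUE)) {
    planepose:::nn_set_buffers(ptr, buf)
    l <- planepose:::nn_loss_grad_cpp(ptr, x, t_gt, R_gt, 0.01, sq, TRUE)
    th <- planepose:::nn_get_params(ptr)
    idx <- sample(length(th), 20)
    h <- 1e-5
    fd <- vapply(idx, function(k) {
      tp <- th; tp[k] <- tp[k] + h
      planepose:::nn_set_params(ptr, tp)
      lp <- planepose:::nn_loss_grad_cpp(ptr, x, t_gt, R_gt, 0.01, sq, TRUE)$loss_total
      planepose:::nn_set_buffers(ptr, buf)
      tm <- th; tm[k] <- tm[k] - h
      planepose:::nn_set_params(ptr, tm)
      lm <- planepose:::nn_loss_grad_cpp(ptr, x, t_gt, R_gt, 0.01, sq, TRUE)$loss_total
      planepose:::nn_set_buffers(ptr, buf)
      (lp - lm) / (2 * h)
    }, numeric(1))
    planepose:::nn_set_params(ptr, th)
    expect_lt(max(abs(fd - l$grad[idx]) / (abs(fd) + 1e-6)), 1e-3)
  }
})
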