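# SO(3) machinery: Gram-Schmidt projection, 6D representation, Euler
# conversions, geodesic distance, bounded random rotations.

test_that("Gram-Schmidt reproduces hand-derived bases", {
  expect_equal(gram_schmidt_to_rotation(c(1, 0, 0), c(0, 1, 0)), diag(3))
  # normalization and projection are forced: scaled/oblique inputs
  expect_equal(gram_schmidt_to_rotation(c(2, 0, 0), c(1, 1, 0)), diag(3))
  # direct evaluation of e1/u2/cross formulas for swapped axes
  expect_equal(gram_schmidt_to_rotation(c(0, 1, 0), c(1, 0, 0)),
               cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1)))
})

test_that("Gram-Schmidt output is always in SO(3) and scale-invariant", {
  set.seed(41)
  worst_ortho <- worst_det <- 0
  for (k in 1:500) {
    v1 <- rnorm(3); v2 <- rnorm(3)
    R <- gram_schmidt_to_rotation(v1, v2)
    worst_ortho <- max(worst_ortho, norm(crossprod(R) - diag(3), "F"))
    worst_det <- max(worst_det, abs(det(R) - 1))
    # invariance to positive rescaling of the head outputs
    expect_equal(gram_schmidt_to_rotation(5 * v1, 3 * v2), R, tolerance = 1e-12)
  }
  expect_lt(worst_ortho, 1e-6)
  expect_lt(worst_det, 1e-6)
})

test_that("degenerate Gram-Schmidt inputs raise explicit errors", {
  expect_error(gram_schmidt_to_rotation(c(0, 0, 0), c(1, 0, 0)), "degenerate")
  expect_error(gram_schmidt_to_rotation(c(1, 0, 0), c(2, 0, 0)), "parallel")
  expect_error(gram_schmidt_to_rotation(c(1, 0, 0), 1e-10 * c(1, 1e-3, 0)),
               "parallel")
})

test_that("6D representation round-trips through Gram-Schmidt", {
  expect_equal(rotation_to_sixd(diag(3)), c(1, 0, 0, 0, 1, 0))
  # Rz(90 deg): columns (0,1,0) and (-1,0,0)
  expect_equal(rotation_to_sixd(euler_to_rotation(c(0, 0, 90))),
               c(0, 1, 0, -1, 0, 0))
  set.seed(42)
  for (k in 1:200) {
    R <- random_so3()
    expect_lt(norm(sixd_to_rotation(rotation_to_sixd(R)) - R, "F"), 1e-6)
  }
  expect_error(rotation_to_sixd(matrix(1, 3, 3)), "not a rotation")
})

test_that("Euler conversions invert each other on the principal branch", {
  expect_equal(euler_to_rotation(c(0, 0, 0)), diag(3))
  R90 <- euler_to_rotation(c(90, 0, 0))
  expect_equal(sum(diag(R90)), 1)
  expect_equal(geodesic_distance_deg(diag(3), R90), 90)
  expect_equal(rotation_to_euler(euler_to_rotation(c(10, 20, 30))), c(10, 20, 30))
  expect_equal(rotation_to_euler(diag(3)), c(0, 0, 0))
  set.seed(43)
  for (k in 1:200) {
    e <- runif(3, -179, 179) * c(0.49, 1, 1)  # keep ax off gimbal lock
    R <- euler_to_rotation(e)
    expect_equal(euler_to_rotation(rotation_to_euler(R)), R, tolerance = 1e-9)
  }
  expect_error(euler_to_rotation(c(0, 0, 0), convention = "XYZ"), "convention")
  expect_error(rotation_to_euler(diag(3), convention = "ZYX"), "convention")
})

test_that("gimbal-lock poses resolve to the documented canonical output", {
  for (sx in c(90, -90)) {
    e_in <- c(sx, 25, 40)
    R <- euler_to_rotation(e_in)
    e_out <- rotation_to_euler(R)
    expect_equal(e_out[1], sx)
    expect_equal(e_out[2], 0)            # tie-break: middle-chain survivor, ay = 0
    expect_equal(euler_to_rotation(e_out), R, tolerance = 1e-9)
  }
})

test_that("geodesic distance matches the quaternion oracle and its axioms", {
  expect_equal(geodesic_distance_deg(diag(3), diag(3)), 0)
  expect_equal(geodesic_distance_deg(diag(3), euler_to_rotation(c(90, 0, 0))), 90)
  expect_equal(geodesic_distance_deg(euler_to_rotation(c(0, 0, 30)),
                                     euler_to_rotation(c(0, 0, 75))), 45)
  # 180 degrees exactly
  expect_equal(geodesic_distance_deg(diag(3), euler_to_rotation(c(0, 0, 180))), 180)
  set.seed(44)
  for (k in 1:200) {
    R1 <- random_so3(); R2 <- random_so3(); Q <- random_so3()
    g <- geodesic_distance_deg(R1, R2)
    expect_gte(g, 0); expect_lte(g, 180)
    expect_equal(g, quat_angle_deg(R1, R2), tolerance = 1e-6)
    expect_equal(geodesic_distance_deg(R2, R1), g, tolerance = 1e-9)
    # left-invariance
    expect_equal(geodesic_distance_deg(Q %*% R1, Q %*% R2), g, tolerance = 1e-6)
  }
})

test_that("bounded random rotations are deterministic and per-axis uniform", {
  expect_equal(with_seed(1, random_rotation_in_range(0)), diag(3))
  expect_identical(with_seed(7, random_rotation_in_range(45)),
                   with_seed(7, random_rotation_in_range(45)))
  expect_error(random_rotation_in_range(-1), "\\[0, 180\\]")
  expect_error(random_rotation_in_range(200), "\\[0, 180\\]")
  # recovered per-axis angles uniform on [-45, 45]
  set.seed(45)
  ang <- t(replicate(2000, rotation_to_euler(random_rotation_in_range(45))))
  for (axis in 1:3) {
    ks <- suppressWarnings(stats::ks.test(ang[, axis], "punif", -45, 45))
    expect_gt(ks$p.value, 0.01)
  }
})
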