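# Procedural phantom, pose samplers, dataset construction and manifest I/O.

test_that("phantom generation is deterministic and parameter-validated", {
  p <- phantom_params(shape = 32, speckle_strength = 0.3, seed = 99)
  v1 <- generate_phantom_volume(p)
  v2 <- generate_phantom_volume(p)
  expect_identical(v1$grid, v2$grid)
  expect_true(all(v1$grid >= 0 & v1$grid <= 1))
  expect_error(phantom_params(shape = 32, spacing = 1, skull_radii = c(20, 10, 10)),
               "exceed")
  expect_error(phantom_params(speckle_strength = 2), "\\[0, 1\\]")
  expect_error(phantom_params(structure_count = 2), "3 or 4")
})

test_that("speckle-free phantom is smooth, speckled one carries noise", {
  base <- generate_phantom_volume(phantom_params(shape = 32, speckle_strength = 0))
  spk <- generate_phantom_volume(phantom_params(shape = 32, speckle_strength = 0.3))
  # the noise-free anatomy varies slowly; speckle adds voxel-scale variation
  # on top. Compare mean voxel-to-voxel jumps inside the brain.
  jump <- function(v) mean(abs(diff(v$grid[8:24, 10:22, 10:22])))
  expect_gt(jump(spk), jump(base))
  expect_gt(mean(abs(spk$grid - base$grid)), 0.003)  # noise is really there
  # the anatomy field underneath is the same
  expect_gt(cor(as.vector(base$grid), as.vector(spk$grid)), 0.8)
  # texture makes the interior non-constant even without speckle
  expect_gt(stats::sd(base$grid[10:22, 10:22, 16]), 0.02)
})

test_that("phantom has no symmetry under the 24 cube rotations", {
  # the best-matching cube-symmetry rotation of the volume onto itself must
  # be the identity, uniquely: exhaustive check over all 24 orientation-
  # preserving axis permutations/flips
  vol <- generate_phantom_volume(phantom_params(shape = 32, speckle_strength = 0))
  g <- vol$grid
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cors <- c()
  for (pm in perms) for (fx in 0:1) for (fy in 0:1) for (fz in 0:1) {
    h <- aperm(g, pm)
    if (fx) h <- h[dim(h)[1]:1, , ]
    if (fy) h <- h[, dim(h)[2]:1, ]
    if (fz) h <- h[, , dim(h)[3]:1]
    # keep only proper rotations: permutation parity * flip parity == +1
    parity <- sign(det(diag(3)[pm, ])) * (-1)^(fx + fy + fz)
    if (parity == 1) cors <- c(cors, cor(as.vector(g), as.vector(h)))
  }
  expect_length(cors, 24L)
  expect_equal(max(cors), 1)                        # identity is among them
  expect_lt(sort(cors, decreasing = TRUE)[2], 0.97) # and the unique maximum
})

test_that("random pose sampling respects ranges, overlap and determinism", {
  vol <- fixture_phantom()
  cfg0 <- sampler_config(trans_range = 0, rot_range = 0, min_overlap = 0)
  p0 <- with_seed(1, sample_random_pose(cfg0, vol))
  expect_equal(p0$rotation, diag(3))
  expect_equal(p0$translation, c(0, 0, 0))
  cfg <- sampler_config(trans_range = 0.5, rot_range = 45, min_overlap = 0.75)
  expect_identical(with_seed(5, sample_random_pose(cfg, vol)),
                   with_seed(5, sample_random_pose(cfg, vol)))
  set.seed(6)
  for (k in 1:50) {
    p <- sample_random_pose(cfg, vol)
    expect_true(all(abs(p$translation) <= 0.5))
    ov <- overlap_fraction(vol, slice_spec(p, default_field_of_view(vol), 64))
    expect_gte(ov, 0.75)
  }
  # impossible overlap constraint errors out with advice
  bad <- sampler_config(trans_range = 3, rot_range = 0, min_overlap = 0.999)
  expect_error(with_seed(1, sample_random_pose(bad, vol)), "min_overlap")
})

test_that("near-SP sampling ramps its intervals from coarse to fine", {
  vol <- fixture_phantom()
  sp <- phantom_standard_plane()
  degenerate <- sampler_config(n_near_sp = 5, sp_trans_interval_max = 0,
                               sp_trans_interval_min = 0,
                               sp_rot_interval_max = 0, sp_rot_interval_min = 0,
                               min_overlap = 0)
  ps <- with_seed(2, sample_near_sp_poses(degenerate, sp, vol))
  for (p in ps) {
    expect_equal(p$translation, sp$translation)
    expect_equal(p$rotation, sp$rotation)
  }
  cfg <- sampler_config(n_near_sp = 60, min_overlap = 0)
  ps <- with_seed(3, sample_near_sp_poses(cfg, sp, vol))
  expect_length(ps, 60L)
  dt <- vapply(ps, function(p) sqrt(sum((p$translation - sp$translation)^2)),
               numeric(1))
  dr <- vapply(ps, function(p) geodesic_distance_deg(p$rotation, sp$rotation),
               numeric(1))
  # bounds implied by the default 0.1 / 7.9-degree starting intervals
  expect_true(all(dt <= 0.1 * sqrt(3) + 1e-12))
  expect_true(all(dr <= 3 * 7.9))
  # the late (fine-interval) poses are much closer than the early ones
  expect_lt(mean(dt[41:60]), mean(dt[1:20]))
  expect_lt(mean(dr[41:60]), mean(dr[1:20]))
  expect_identical(with_seed(3, sample_near_sp_poses(cfg, sp, vol)), ps)
})

test_that("build_dataset writes the configured counts with valid labels", {
  man <- fixture_dataset()
  expect_equal(sum(man$subset == "RP"), 40L)
  expect_equal(sum(man$subset == "SP"), 10L)
  dir <- attr(man, "dir")
  expect_true(all(file.exists(file.path(dir, man$image_path))))
  # every stored pose is a valid rotation + finite translation
  for (p in manifest_poses(man)) expect_s3_class(p, "pose")
  # near-SP requires an SP pose
  expect_error(build_dataset(fixture_phantom(),
                             sampler_config(n_random = 1, n_near_sp = 1),
                             tempfile()),
               "standard-plane")
})

test_that("re-slicing manifest rows reproduces the stored PNGs", {
  man <- fixture_dataset()
  vol <- fixture_phantom()
  dir <- attr(man, "dir")
  poses <- manifest_poses(man)
  idx <- with_seed(8, sample(nrow(man), 15))
  for (i in idx) {
    px <- png::readPNG(file.path(dir, man$image_path[i]))
    sl <- extract_slice(vol, slice_spec(poses[[i]], attr(man, "field_of_view"),
                                        attr(man, "resolution")))
    expect_lt(max(abs(px - sl$pixels)), 1 / 255)
  }
})

test_that("manifests round-trip losslessly and reject malformed input", {
  man <- fixture_dataset()
  f <- tempfile(fileext = ".csv")
  write_manifest(man, f)
  back <- read_manifest(f)
  expect_equal(manifest_table(back), manifest_table(man))
  expect_equal(attr(back, "field_of_view"), attr(man, "field_of_view"))
  expect_equal(attr(back, "resolution"), attr(man, "resolution"))
  expect_equal(attr(back, "extent"), attr(man, "extent"))

  lines <- readLines(f)
  # missing euler_convention header
  writeLines(lines[!grepl("euler_convention", lines)], f2 <- tempfile())
  expect_error(read_manifest(f2), "euler_convention")
  # unknown subset tag, named by row
  bad <- sub("^(images/rp_00002.png,[^,]*),RP", "\\1,XX", lines)
  writeLines(bad, f3 <- tempfile())
  expect_error(read_manifest(f3), "XX")
  # missing column
  writeLines(sub(",overlap", "", sub(",0\\.[0-9]+$", "", lines)), f4 <- tempfile())
  expect_error(read_manifest(f4), "overlap")
})

test_that("identical seeds give identical datasets, and SP planes sit nearer", {
  vol <- generate_phantom_volume(phantom_params(shape = 32))
  cfg <- sampler_config(n_random = 12, n_near_sp = 8, seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- build_dataset(vol, cfg, d1, sp = phantom_standard_plane(), resolution = 32)
  m2 <- build_dataset(vol, cfg, d2, sp = phantom_standard_plane(), resolution = 32)
  expect_equal(manifest_table(m1), manifest_table(m2))
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # byte-identical slices
  for (k in c(1, 10, 15))
    expect_identical(readBin(file.path(d1, m1$image_path[k]), "raw", 1e6),
                     readBin(file.path(d2, m2$image_path[k]), "raw", 1e6))
  # the SP subset is strictly nearer to the SP pose than the RP subset
  man <- fixture_dataset()
  sp <- phantom_standard_plane()
  g <- vapply(manifest_poses(man), function(p)
    geodesic_distance_deg(p$rotation, sp$rotation), numeric(1))
  expect_lt(median(g[man$subset == "SP"]), median(g[man$subset == "RP"]))
})

test_that("SP annotations round-trip through JSON", {
  sp <- phantom_standard_plane()
  f <- tempfile(fileext = ".json")
  write_sp_annotation(sp, f, volume_id = "phantom-1", annotator = "synthetic")
  back <- read_sp_annotation(f)
  expect_equal(back$pose$translation, sp$translation)
  expect_equal(back$pose$rotation, sp$rotation, tolerance = 1e-12)
  expect_equal(back$volume_id, "phantom-1")
  j <- jsonlite::read_json(f)
  j$convention <- NULL
  jsonlite::write_json(j, f2 <- tempfile(), auto_unbox = TRUE)
  expect_error(read_sp_annotation(f2), "convention")
})
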