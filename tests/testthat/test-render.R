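test_that("pose draws stay inside the configured ranges", {
  cfg <- view_config()
  set.seed(3)
  for (i in 1:200) {
    pp <- sample_pose_pair(cfg)
    p <- pp$params
    expect_true(p$azimuth >= 0 && p$azimuth < 360)
    expect_true(p$elevation >= 90 && p$elevation <= 270)
    expect_true(p$height >= 0.5 && p$height <= 0.6)
    expect_true(p$opp_height >= -0.6 && p$opp_height <= -0.5)
    expect_true(all(abs(c(p$shift_init, p$shift_opp)) <= 0.1))
    expect_rotation(pp$initial$R)
    expect_rotation(pp$opposite$R)
    # opposite orientation is exactly the 180-degree model
    expect_lt(max(abs(pp$opposite$R -
                        rotation_about_y(180) %*% pp$initial$R)), 1e-12)
  }
})

test_that("the ground-truth translation registers the opposite view", {
  set.seed(11)
  mesh <- sphere_mesh()
  p <- sample_mesh_surface(mesh, 50)
  pp <- sample_pose_pair()
  p_init <- world_to_camera(point_cloud(p, "world"), pp$initial)$xyz
  p_opp <- world_to_camera(point_cloud(p, "world"), pp$opposite)$xyz
  # p_opp = Ry(180) p_init + t_gt, i.e. register_to_world inverts it
  back <- register_to_world(point_cloud(p_opp, "opposite_camera"),
                            rigid_pose(rotation_about_y(180), pp$t_gt))
  expect_lt(max(abs(back$xyz - p_init)), 1e-9)
  # centred object: t_gt is approximately (0, 0, height - opp_height)
  cfg0 <- view_config(shift_x = c(0, 0), shift_y = c(0, 0))
  pp0 <- sample_pose_pair(cfg0)
  expect_equal(pp0$t_gt[1:2], c(0, 0), tolerance = 1e-9)
  expect_equal(pp0$t_gt[3],
               pp0$params$height - pp0$params$opp_height, tolerance = 1e-9)
})

test_that("pose sampling is deterministic under a seed", {
  set.seed(42); a <- sample_pose_pair()
  set.seed(42); b <- sample_pose_pair()
  expect_identical(a, b)
  degenerate <- view_config(azimuth = c(10, 10), elevation = c(120, 120),
                            height = c(0.55, 0.55), shift_x = c(0, 0),
                            shift_y = c(0, 0), opp_height = c(-0.55, -0.55))
  set.seed(1); c1 <- sample_pose_pair(degenerate)
  set.seed(999); c2 <- sample_pose_pair(degenerate)
  expect_equal(c1$t_gt, c2$t_gt)
  expect_error(view_config(height = c(1, 0.5)), "min <= max")
})

test_that("rendered sphere depth matches the closed-form nearest point", {
  k <- k_test()
  mesh <- make_primitive("sphere", r = 3.65, resolution = 4)
  set.seed(5)
  pp <- sample_pose_pair()
  d <- render_depth(mesh, pp$initial, k, quantize_mm = FALSE)
  expect_gt(sum(d > 0), 50)
  # the minimum camera-Z depth of a sphere is the centre's Z minus r (the
  # surface point whose normal faces straight down the optical axis)
  z_centre <- pp$initial$t[3]
  expect_equal(min(d[d > 0]), z_centre - 0.0365, tolerance = 0.002)
  # on-axis case: camera straight above, no shift -- the nearest depth is
  # exactly distance minus radius
  R <- depthvol:::camera_rotation(c(0, 1, 0))
  pose0 <- rigid_pose(R, -as.numeric(R %*% c(0, 0.55, 0)))
  d0 <- render_depth(mesh, pose0, k, quantize_mm = FALSE)
  expect_equal(min(d0[d0 > 0]), 0.55 - 0.0365, tolerance = 5e-4)
  # empty mesh renders an all-zero image
  empty <- list(vertices = matrix(numeric(0), 0, 3),
                faces = matrix(integer(0), 0, 3))
  expect_true(all(render_depth(empty, pp$initial, k) == 0))
})

test_that("a face-on cube renders its face at the modal depth", {
  k <- k_test()
  mesh <- make_primitive("cube", edge = 5.7)
  # camera straight above at 0.55 m looking down
  R <- depthvol:::camera_rotation(c(0, 1, 0))
  pose <- rigid_pose(R, -as.numeric(R %*% c(0, 0.55, 0)))
  d <- render_depth(mesh, pose, k, quantize_mm = FALSE)
  face_depth <- 0.55 - 0.057 / 2
  modal <- as.numeric(names(sort(table(round(d[d > 0], 4)),
                                 decreasing = TRUE))[1])
  expect_equal(modal, face_depth, tolerance = 1e-3)
})

test_that("datasets round-trip losslessly modulo millimetre quantisation", {
  out <- tempfile("ds")
  meshes <- list(ball = make_primitive("sphere", r = 3, resolution = 2),
                 box = make_primitive("cube", edge = 5))
  idx <- build_dataset(meshes, n_pairs_per_object = 3, seed = 21,
                       out_dir = out, k = k_test())
  expect_equal(nrow(idx), 6L)
  expect_length(list.files(out, pattern = "\\.png$", recursive = TRUE), 12L)
  expect_true(file.exists(file.path(out, "index.jsonl")))
  # reread one sample: depth values equal to the mm-quantised render
  d <- read_depth_png(idx$init[1])
  meta <- jsonlite::read_json(idx$meta[1], simplifyVector = TRUE)
  set.seed(idx$seed[1])
  s <- render_pair(meshes$ball, k_test())
  expect_equal(matrix(d, nrow(d)), matrix(s$initial, nrow(d)),
               tolerance = 1e-12)
  expect_equal(meta$t_gt, s$t_gt, tolerance = 1e-12)
  pose <- attr(d, "pose")
  expect_lt(max(abs(pose$R - s$poses$initial$R)), 1e-12)
  # rebuilding with the same seed reproduces the metadata byte for byte
  out2 <- tempfile("ds2")
  build_dataset(meshes, 3, seed = 21, out_dir = out2, k = k_test())
  expect_identical(readLines(idx$meta[4]),
                   readLines(file.path(out2, "box", "00001.json")))
})

test_that("holdout split partitions exactly with remainder to train", {
  idx <- data.frame(i = 1:10)
  sp <- holdout_split(idx, c(0.7, 0.1, 0.2), seed = 2)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 7L, validation = 1L, test = 2L))
  all_i <- sort(unname(unlist(lapply(sp, function(s) s$i))))
  expect_identical(all_i, 1:10)
  expect_error(holdout_split(idx[0, , drop = FALSE]), "empty")
  expect_error(holdout_split(idx, c(0.5, 0.2, 0.2)), "sum to 1")
})
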