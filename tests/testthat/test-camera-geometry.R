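test_that("rotation about y matches the closed form at key angles", {
  expect_identical(rotation_about_y(180),
                   matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3))
  expect_identical(rotation_about_y(0), diag(c(1, 1, 1)))
  expect_equal(rotation_about_y(90),
               matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3))
  # self-inverse at 180 degrees, exactly
  r180 <- rotation_about_y(180)
  expect_identical(r180 %*% r180, diag(c(1, 1, 1)))
})

test_that("rotation about y is orthonormal with inverse at -theta", {
  for (theta in c(-270, -33.3, 12.7, 45, 91, 200, 359)) {
    R <- rotation_about_y(theta)
    expect_rotation(R, tol = 1e-12)
    expect_lt(max(abs(R %*% rotation_about_y(-theta) - diag(3))), 1e-12)
    p <- c(0.3, -1.2, 2.5)
    expect_equal(sqrt(sum((R %*% p)^2)), sqrt(sum(p^2)), tolerance = 1e-9)
  }
})

test_that("back-projection inverts the pinhole model pixel by pixel", {
  k <- intrinsics(500, 500, 320, 240, 640, 480)
  d <- matrix(0, 480, 640)
  d[241, 321] <- 1.0    # principal point, v = 240, u = 320 (0-based)
  d[241, 421] <- 2.0    # u = 420
  pc <- back_project(depth_image(d), k)
  expect_equal(nrow(pc$xyz), 2L)
  expect_equal(pc$xyz[pc$xyz[, 3] == 1, ], c(0, 0, 1))
  expect_equal(pc$xyz[pc$xyz[, 3] == 2, ], c(0.4, 0, 2.0))
})

test_that("back-projection yields one point per valid pixel, Z preserved", {
  k <- k_test()
  set.seed(4)
  d <- matrix(0, k$height, k$width)
  idx <- sample(length(d), 500)
  d[idx] <- runif(500, 0.2, 2)
  pc <- back_project(depth_image(d), k)
  expect_equal(nrow(pc$xyz), 500L)
  expect_setequal(round(pc$xyz[, 3], 12), round(d[idx], 12))
  # empty image -> empty cloud, not an error
  empty <- back_project(depth_image(matrix(0, k$height, k$width)), k)
  expect_equal(nrow(empty$xyz), 0L)
  # dimension mismatch is an error
  expect_error(back_project(depth_image(matrix(1, 5, 5)), k), "intrinsics")
})

test_that("projection z-buffers and round-trips back-projection", {
  k <- k_test()
  # two points on one ray keep the nearer depth
  pc <- point_cloud(rbind(c(0, 0, 1), c(0, 0, 2)), "initial_camera")
  d <- project(pc, k)
  # (cx, cy) = (79.5, 59.5) rounds half away from zero to pixel (80, 60),
  # i.e. row 61, column 81 in 1-based indexing
  expect_equal(d[61, 81], 1)
  expect_equal(sum(d > 0), 1)
  # project . back_project is the identity on valid pixels
  mesh <- sphere_mesh()
  pair <- render_test_pair(mesh, seed = 2)
  cloud <- back_project(pair$initial, k)
  d2 <- project(cloud, k)
  expect_equal(unclass(d2), unclass(pair$initial), tolerance = 1e-12)
  # behind-camera points are dropped
  behind <- project(point_cloud(rbind(c(0, 0, -1)), "initial_camera"), k)
  expect_true(all(behind == 0))
})

test_that("world registration inverts the rigid transform", {
  # hand-evaluated: p_c = (0,0,1), R = Ry(180), T = (0,0,2) -> p_w = (0,0,1)
  pose <- rigid_pose(rotation_about_y(180), c(0, 0, 2))
  pw <- register_to_world(point_cloud(rbind(c(0, 0, 1)), "opposite_camera"),
                          pose)
  expect_equal(pw$xyz[1, ], c(0, 0, 1))
  # identity pose is the identity map
  id <- rigid_pose(diag(3), c(0, 0, 0))
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(register_to_world(point_cloud(p, "initial_camera"), id)$xyz, p)
  # random-pose round trips within 1e-9
  set.seed(7)
  for (i in 1:5) {
    pp <- sample_pose_pair()
    for (pose in list(pp$initial, pp$opposite)) {
      cam <- world_to_camera(point_cloud(p, "world"), pose)
      back <- register_to_world(cam, pose)
      expect_lt(max(abs(back$xyz - p)), 1e-9)
    }
  }
  expect_error(rigid_pose(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
})

test_that("depth images reject invalid values", {
  expect_error(depth_image(matrix(-1, 2, 2)), "negative")
  expect_error(depth_image(matrix(NaN, 2, 2)), "finite")
  expect_error(intrinsics(500, 500, 700, 240, 640, 480), "principal point")
})
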