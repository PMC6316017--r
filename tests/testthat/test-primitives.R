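test_that("analytic volumes match closed forms", {
  expect_equal(make_primitive("cube", edge = 5.7)$analytic_volume_cm3,
               5.7^3)                                   # 185.193
  expect_equal(make_primitive("sphere", r = 1)$analytic_volume_cm3,
               4 / 3 * pi, tolerance = 1e-12)           # 4.18879
  expect_equal(make_primitive("cylinder", r = 3, h = 5)$analytic_volume_cm3,
               pi * 9 * 5, tolerance = 1e-12)           # 141.372
  expect_equal(make_primitive("capsule", r = 2, h = 8)$analytic_volume_cm3,
               pi * 4 * 8 + 4 / 3 * pi * 8, tolerance = 1e-12)
  expect_equal(make_primitive("ellipsoid", a = 1, b = 2,
                              c = 3)$analytic_volume_cm3,
               4 / 3 * pi * 6, tolerance = 1e-12)
  expect_error(make_primitive("cube", edge = -1), "positive")
  expect_error(make_primitive("sphere"), "needs size parameter")
})

test_that("primitive meshes are closed and consistently outward-oriented", {
  for (spec in list(list("cube", edge = 5.7), list("sphere", r = 3.65),
                    list("cylinder", r = 3, h = 5),
                    list("capsule", r = 2, h = 8),
                    list("bent_capsule", r = 1.9, arc_radius = 5))) {
    mesh <- do.call(make_primitive, spec)
    f <- mesh$faces
    # closed and orientable: every directed edge appears exactly once
    dir_edges <- paste(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
    expect_false(any(duplicated(dir_edges)), info = spec[[1]])
    rev_edges <- paste(c(f[, 2], f[, 3], f[, 1]), c(f[, 1], f[, 2], f[, 3]))
    expect_true(all(rev_edges %in% dir_edges), info = spec[[1]])
    # outward: signed volume positive and near the analytic value
    sv <- depthvol:::signed_mesh_volume(mesh)
    expect_gt(sv, 0)
    expect_equal(sv * 1e6, mesh$analytic_volume_cm3, tolerance = 0.02)
  }
})

test_that("mesh volume converges to the analytic value with resolution", {
  errs <- vapply(2:4, function(lvl) {
    m <- make_primitive("sphere", r = 3.65, resolution = lvl)
    abs(mesh_volume(m) * 1e6 - m$analytic_volume_cm3) / m$analytic_volume_cm3
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.005)   # icosphere level 4 within 0.5%
})

test_that("signed-tetrahedron volume is exact and orientation independent", {
  cube <- depthvol:::mesh_cube(1)
  expect_identical(mesh_volume(cube), 1)
  flipped <- cube
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_identical(mesh_volume(flipped), 1)
  expect_warning(mesh_volume(list(vertices = cube$vertices,
                                  faces = cube$faces[-1, ])), "not closed")
})

test_that("bent-capsule analytic volume agrees with a voxel oracle", {
  r <- 1.9; ar <- 5; ad <- 120
  mesh <- make_primitive("bent_capsule", r = r, arc_radius = ar,
                         arc_degrees = ad)
  # independent oracle: dense voxel count of the analytic solid (tube of
  # radius r around a circular arc, spherical caps)
  rm <- r / 100; arm <- ar / 100
  half <- ad / 2 * pi / 180
  step <- 0.0015
  bb <- apply(mesh$vertices, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], by = step)
  gy <- seq(bb[1, 2], bb[2, 2], by = step)
  gz <- seq(bb[1, 3], bb[2, 3], by = step)
  g <- as.matrix(expand.grid(gx, gy, gz))
  # distance from each grid point to the arc segment
  cx <- g[, 1]; cy <- g[, 2] + arm
  ang <- atan2(cx, cy)
  ang_cl <- pmin(pmax(ang, -half), half)
  nearest <- cbind(arm * sin(ang_cl), arm * cos(ang_cl) - arm, 0)
  dist <- sqrt(rowSums((g - nearest)^2))
  vox_vol <- sum(dist <= rm) * step^3 * 1e6
  expect_equal(mesh$analytic_volume_cm3, vox_vol, tolerance = 0.02)
  expect_equal(mesh_volume(mesh) * 1e6, mesh$analytic_volume_cm3,
               tolerance = 0.02)
})

test_that("surface sampling is area-uniform on a cube", {
  mesh <- make_primitive("cube", edge = 2)
  set.seed(1)
  pts <- sample_mesh_surface(mesh, 6000)
  # every point on the surface, faces hit in proportion to area
  p <- pts * 100
  onface <- rowSums(abs(abs(p) - 1) < 1e-9)
  expect_true(all(onface >= 1))
  axis <- apply(abs(p), 1, which.max)
  side <- sign(p[cbind(seq_len(nrow(p)), axis)])
  perface <- table(paste(axis, side))
  expect_length(perface, 6L)
  expect_true(all(abs(perface / 1000 - 1) < 0.2))
})
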