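test_that("alpha selection follows the sampling density", {
  grid <- point_cloud(as.matrix(expand.grid(0:5, 0:5, 0:5)), "world")
  expect_equal(choose_alpha(grid, 3), 3)            # unit grid spacing
  scaled <- point_cloud(grid$xyz * 0.01, "world")
  expect_equal(choose_alpha(scaled, 3), 0.03)       # scale equivariance
  expect_error(choose_alpha(grid, 0), "positive")
  expect_error(choose_alpha(point_cloud(matrix(0, 20, 3), "world")),
               "degenerate")
})

test_that("alpha shapes of dense surface samples recover volumes", {
  mesh <- make_primitive("cube", edge = 100)    # 1 m cube in metres
  cl <- surface_cloud(mesh, 5000, seed = 1)
  # Poisson sampling leaves occasional gaps wider than a few median
  # spacings; estimate_volume's escalation seals them
  est <- estimate_volume(cl)
  expect_true(est$watertight)
  expect_equal(est$volume_cm3 / 1e6, 1, tolerance = 0.02)
  # direct alpha-shape call on an evenly sampled surface (no Poisson gaps)
  g <- seq(-0.5, 0.5, length.out = 25)
  gg <- as.matrix(expand.grid(g, g))
  faces <- rbind(cbind(gg, -0.5), cbind(gg, 0.5),
                 cbind(gg[, 1], -0.5, gg[, 2]), cbind(gg[, 1], 0.5, gg[, 2]),
                 cbind(-0.5, gg), cbind(0.5, gg))
  set.seed(99)
  cg <- point_cloud(unique(faces) + 1e-9 * matrix(stats::rnorm(3 *
    nrow(unique(faces))), ncol = 3), "world")
  m <- alpha_shape(cg, choose_alpha(cg, 3))
  expect_true(attr(m, "watertight"))
  expect_equal(attr(m, "enclosed_volume"), 1, tolerance = 0.02)
  # the boundary mesh's signed volume agrees with the tetrahedral count
  expect_equal(mesh_volume(m, warn_open = FALSE),
               attr(m, "enclosed_volume"), tolerance = 1e-9)
  # four non-coplanar points at large alpha give the single tetrahedron
  tet <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                     "world")
  mt <- alpha_shape(tet, 100)
  expect_equal(nrow(mt$faces), 4L)
  expect_equal(attr(mt, "enclosed_volume"), 1 / 6, tolerance = 1e-12)
})

test_that("the convex hull is the large-alpha limit (vs a Qhull oracle)", {
  mesh <- sphere_mesh(r = 3)
  cl <- surface_cloud(mesh, 1500, seed = 2)
  m <- alpha_shape(cl, 1e9)
  # independent oracle: Qhull's own hull volume
  sp <- reticulate::import("scipy.spatial")
  hull <- sp$ConvexHull(cl$xyz)
  expect_equal(attr(m, "enclosed_volume"), hull$volume, tolerance = 1e-9)
  expect_equal(convex_hull_volume(cl), hull$volume, tolerance = 1e-9)
})

test_that("enclosed volume grows monotonically in alpha up to the hull", {
  mesh <- make_primitive("bent_capsule", r = 1.9, arc_radius = 5)
  cl <- surface_cloud(mesh, 3000, seed = 3)
  alphas <- choose_alpha(cl, 3) * 2^(0:7)
  vols <- vapply(alphas, function(a)
    attr(alpha_shape(cl, a), "enclosed_volume"), numeric(1))
  expect_true(all(diff(vols) >= -1e-12))
  hull <- convex_hull_volume(cl)
  expect_true(all(vols <= hull + 1e-12))
  expect_equal(vols[length(vols)], hull, tolerance = 1e-6)
  # the bent capsule is concave: a mid-ladder alpha keeps the bend open
  expect_lt(attr(alpha_shape(cl, alphas[3]), "enclosed_volume"), 0.9 * hull)
})

test_that("volume estimates are rigid-motion invariant and deterministic", {
  mesh <- sphere_mesh(r = 3)
  cl <- surface_cloud(mesh, 2000, seed = 4)
  v1 <- estimate_volume(cl)
  v2 <- estimate_volume(cl)
  expect_identical(v1$volume_cm3, v2$volume_cm3)
  R <- rotation_about_y(37.5)
  moved <- point_cloud(sweep(cl$xyz %*% t(R), 2, c(0.3, -0.1, 0.9), "+"),
                       "world")
  v3 <- estimate_volume(moved)
  expect_equal(v3$volume_cm3, v1$volume_cm3, tolerance = 1e-6)
  expect_equal(v1$volume_cm3, mesh$analytic_volume_cm3, tolerance = 0.03)
})

test_that("estimates converge as surface sampling densifies", {
  mesh <- make_primitive("capsule", r = 2, h = 8)
  errs <- vapply(c(800, 1600, 3200), function(n) {
    cl <- surface_cloud(mesh, n, seed = 5)
    abs(estimate_volume(cl)$volume_cm3 - mesh$analytic_volume_cm3) /
      mesh$analytic_volume_cm3
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.03)
})
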