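test_that("hole filling touches only enclosed invalid pixels", {
  # hole-free image returned unchanged
  d <- depth_image(matrix(0.55, 10, 10))
  expect_identical(unclass(fill_depth_holes(d)), unclass(d))
  # a single hole surrounded by a constant is filled with that constant
  m <- matrix(0, 20, 20); m[5:15, 5:15] <- 0.55; m[10, 10] <- 0
  filled <- fill_depth_holes(depth_image(m))
  expect_equal(filled[10, 10], 0.55)
  expect_equal(unclass(filled)[m > 0], m[m > 0])    # valid pixels untouched
  # the background (border-connected zeros) is never filled
  expect_true(all(filled[1:3, ] == 0))
  # a hole inside a ramp is filled within its neighbours' range
  ramp <- matrix(rep(seq(0.5, 0.6, length.out = 20), each = 20), 20, 20)
  ramp[8:9, 11] <- 0
  fr <- fill_depth_holes(depth_image(ramp), radius = 2, sigma_range = 0.05)
  nb <- ramp[6:11, 9:13]
  expect_true(all(fr[8:9, 11] >= min(nb[nb > 0]) &
                    fr[8:9, 11] <= max(nb[nb > 0])))
  # a wide hole is filled over several passes
  wide <- matrix(0.4, 30, 30); wide[10:20, 10:20] <- 0
  wide[1, 1] <- 0.4  # keep border valid so the hole is enclosed
  fw <- fill_depth_holes(depth_image(wide))
  expect_true(all(fw[10:20, 10:20] > 0))
})

test_that("object masks keep the largest component", {
  d <- matrix(0, 30, 30)
  d[5:20, 5:20] <- 0.5          # 256 px
  d[25:26, 25:27] <- 0.6        # 6 px
  m <- extract_object_mask(depth_image(d))
  expect_equal(sum(m), 256)
  expect_true(all(m[5:20, 5:20]))
  expect_error(extract_object_mask(depth_image(matrix(0, 5, 5))),
               "no object")
  # a known background depth is carved out first
  d2 <- matrix(0.8, 30, 30); d2[10:15, 10:15] <- 0.5
  m2 <- extract_object_mask(depth_image(d2), background_depth = 0.8)
  expect_equal(sum(m2), 36)
})

test_that("statistical outlier removal drops isolated points only", {
  mesh <- sphere_mesh(r = 3)
  cl <- surface_cloud(mesh, 1000, seed = 2)
  spiked <- point_cloud(rbind(cl$xyz, c(10, 0, 0)), "world")
  out <- remove_outliers(spiked, k = 20, std_ratio = 2)
  expect_false(any(out$xyz[, 1] == 10))
  expect_gte(nrow(out$xyz), 0.99 * 1000)
  # brute-force check of the criterion on a small cloud
  small <- point_cloud(rbind(matrix(runif(90), 30, 3), c(50, 50, 50)),
                       "world")
  kept <- remove_outliers(small, k = 5, std_ratio = 2)
  d2 <- as.matrix(dist(small$xyz))
  mdist <- vapply(seq_len(31), function(i) mean(sort(d2[i, -i])[1:5]), 0)
  expect_equal(nrow(kept$xyz), sum(mdist <= mean(mdist) + 2 * sd(mdist)))
  # a perfectly uniform grid loses nothing
  grid <- point_cloud(as.matrix(expand.grid(1:5, 1:5, 1:5)), "world")
  expect_equal(nrow(remove_outliers(grid, k = 6, std_ratio = 3)$xyz), 125L)
  # degenerate inputs
  expect_equal(nrow(remove_outliers(point_cloud(matrix(0, 0, 3)))$xyz), 0L)
  expect_warning(remove_outliers(point_cloud(matrix(rnorm(9), 3, 3)),
                                 k = 20), "unchanged")
})

test_that("translation-only ICP recovers rigid shifts", {
  mesh <- sphere_mesh(r = 3)
  src <- surface_cloud(mesh, 800, seed = 3)
  # identical clouds: zero translation, zero cost
  r0 <- icp_translation(src, src)
  expect_equal(r0$t, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(r0$rms, 1e-9)
  # closed-form oracle for a pure shift: the centroid difference
  shift <- c(0.05, 0, 0.02)
  tgt <- point_cloud(sweep(src$xyz, 2, shift, "+"), "world")
  oracle <- colMeans(tgt$xyz) - colMeans(src$xyz)
  r1 <- icp_translation(src, tgt)
  expect_equal(r1$t, shift, tolerance = 1e-3)
  expect_equal(r1$t, oracle, tolerance = 1e-3)
  # starting at the optimum converges immediately
  r2 <- icp_translation(src, tgt, t_init = shift)
  expect_lte(r2$iterations, 2)
  expect_lt(r2$rms, icp_params()$tolerance)
  # cost is non-increasing at every iteration
  expect_true(all(diff(r1$rms_trace) <= 1e-12))
})

test_that("perturbed initialisations are improved in nearly all trials", {
  mesh <- sphere_mesh(r = 3)
  src <- surface_cloud(mesh, 500, seed = 4)
  shift <- c(0.02, -0.01, 0.03)
  tgt <- point_cloud(sweep(src$xyz, 2, shift, "+"), "world")
  set.seed(5)
  improved <- vapply(1:100, function(i) {
    eps <- runif(3, -1, 1)
    eps <- eps / sqrt(sum(eps^2)) * runif(1, 0, 0.05)
    r <- icp_translation(src, tgt, t_init = shift + eps)
    sqrt(sum((r$t - shift)^2)) < sqrt(sum(eps^2))
  }, logical(1))
  expect_gte(mean(improved), 0.95)
})

test_that("completion fuses both views in the world frame", {
  mesh <- sphere_mesh()
  k <- default_intrinsics()           # full res: extents need real sampling
  pair <- render_test_pair(mesh, seed = 6, k = k)
  cl <- complete_cloud(pair$initial, pair$opposite, k, pair$t_gt,
                       refine = FALSE)
  # pure union when nothing is removed
  expect_equal(nrow(cl$xyz),
               attr(cl, "n_initial") + attr(cl, "n_opposite"))
  expect_identical(cl$frame, "world")
  # the two opposite hemispherical views cover the whole sphere
  extents <- apply(cl$xyz, 2, function(x) diff(range(x)))
  expect_true(all(abs(extents - 2 * 0.0365) < 0.02 * 2 * 0.0365))
  # the rotation applied to the opposite view is exactly Ry(180): undoing
  # the registration with it recovers the opposite camera cloud
  m2 <- extract_object_mask(fill_depth_holes(pair$opposite))
  c2 <- back_project(pair$opposite, k, m2)
  n1 <- attr(cl, "n_initial")
  opp_world <- cl$xyz[(n1 + 1):nrow(cl$xyz), ]
  undone <- sweep(opp_world %*% t(rotation_about_y(180)), 2, pair$t_gt, "+")
  expect_lt(max(abs(undone - c2$xyz)), 1e-9)
})

test_that("refinement at the optimum changes nothing materially", {
  mesh <- sphere_mesh()
  k <- default_intrinsics(1 / 2)   # rim extrapolation needs real sampling
  pair <- render_test_pair(mesh, seed = 7, k = k)
  off <- complete_cloud(pair$initial, pair$opposite, k, pair$t_gt,
                        refine = FALSE, denoise_opposite = FALSE,
                        outlier_removal = FALSE)
  on <- complete_cloud(pair$initial, pair$opposite, k, pair$t_gt,
                       refine = TRUE, denoise_opposite = FALSE,
                       outlier_removal = FALSE)
  # the contour stages may nudge the translation by a few pixels' worth
  expect_lt(sqrt(sum((attr(on, "translation") - pair$t_gt)^2)), 0.006)
  expect_equal(nrow(on$xyz), nrow(off$xyz))
})
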