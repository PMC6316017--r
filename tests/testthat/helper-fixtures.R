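# Shared fixtures: small intrinsics and meshes so most tests run in seconds.

k_test <- function() intrinsics(142.5, 142.5, 79.5, 59.5, 160, 120)

# square low-res camera zoomed so a ~7 cm object spans ~35 px at 0.55 m
k_square64 <- function() intrinsics(256, 256, 31.5, 31.5, 64, 64)

sphere_mesh <- function(r = 3.65, subdiv = 3)
  make_primitive("sphere", r = r, resolution = subdiv)

# deterministic two-view pair of a mesh under the default pose model
render_test_pair <- function(mesh, seed = 1, k = k_test()) {
  set.seed(seed)
  render_pair(mesh, k, quantize_mm = FALSE)
}

# uniform surface samples of a mesh as a world-frame cloud
surface_cloud <- function(mesh, n, seed = 1) {
  set.seed(seed)
  point_cloud(sample_mesh_surface(mesh, n), "world")
}

expect_rotation <- function(R, tol = 1e-9) {
  expect_lt(max(abs(crossprod(R) - diag(3))), tol)
  expect_lt(abs(det(R) - 1), tol)
}
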