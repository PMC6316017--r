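the_py <- new.env(parent = emptyenv())

# Delaunay backend: Qhull through scipy.spatial. The python interpreter on
# PATH is bound lazily on first use.
scipy_spatial <- function() {
  if (is.null(the_py$spatial)) {
    if (!reticulate::py_available(initialize = FALSE)) {
      py <- Sys.getenv("RETICULATE_PYTHON", "")
      if (!nzchar(py)) py <- Sys.which("python3")
      if (!nzchar(py)) py <- Sys.which("python")
      if (nzchar(py)) try(reticulate::use_python(py, required = FALSE),
                          silent = TRUE)
    }
    the_py$spatial <- reticulate::import("scipy.spatial", delay_load = FALSE)
  }
  the_py$spatial
}

#' Delaunay tetrahedralisation of a 3D point cloud
#'
#' Thin wrapper over Qhull (scipy.spatial.Delaunay). Falls back to joggled
#' input (`QJ`) if the triangulation fails on degenerate (e.g. grid-quantised)
#' data.
#'
#' @param xyz n x 3 matrix.
#' @return m x 4 integer matrix of 1-based vertex indices.
#' @keywords internal
delaunay_tetrahedra <- function(xyz) {
  sp <- scipy_spatial()
  tri <- tryCatch(sp$Delaunay(xyz),
                  error = function(e) sp$Delaunay(xyz, qhull_options = "QJ"))
  simp <- tri$simplices
  storage.mode(simp) <- "integer"
  simp + 1L
}

tetra_circumradius <- function(xyz, tet) {
  a <- xyz[tet[, 1], , drop = FALSE]
  ba <- xyz[tet[, 2], , drop = FALSE] - a
  ca <- xyz[tet[, 3], , drop = FALSE] - a
  da <- xyz[tet[, 4], , drop = FALSE] - a
  cr_cd <- cbind(ca[, 2] * da[, 3] - ca[, 3] * da[, 2],
                 ca[, 3] * da[, 1] - ca[, 1] * da[, 3],
                 ca[, 1] * da[, 2] - ca[, 2] * da[, 1])
  cr_db <- cbind(da[, 2] * ba[, 3] - da[, 3] * ba[, 2],
                 da[, 3] * ba[, 1] - da[, 1] * ba[, 3],
                 da[, 1] * ba[, 2] - da[, 2] * ba[, 1])
  cr_bc <- cbind(ba[, 2] * ca[, 3] - ba[, 3] * ca[, 2],
                 ba[, 3] * ca[, 1] - ba[, 1] * ca[, 3],
                 ba[, 1] * ca[, 2] - ba[, 2] * ca[, 1])
  b2 <- rowSums(ba^2); c2 <- rowSums(ca^2); d2 <- rowSums(da^2)
  num <- b2 * cr_cd + c2 * cr_db + d2 * cr_bc
  denom <- 2 * rowSums(ba * cr_cd)           # 12 * signed volume
  r <- sqrt(rowSums(num^2)) / abs(denom)
  r[!is.finite(r)] <- Inf                     # degenerate (flat) tetrahedra
  r
}

tetra_volumes <- function(xyz, tet) {
  a <- xyz[tet[, 1], , drop = FALSE]
  ba <- xyz[tet[, 2], , drop = FALSE] - a
  ca <- xyz[tet[, 3], , drop = FALSE] - a
  da <- xyz[tet[, 4], , drop = FALSE] - a
  abs(ba[, 1] * (ca[, 2] * da[, 3] - ca[, 3] * da[, 2]) -
      ba[, 2] * (ca[, 1] * da[, 3] - ca[, 3] * da[, 1]) +
      ba[, 3] * (ca[, 1] * da[, 2] - ca[, 2] * da[, 1])) / 6
}

#' Choose an alpha radius from the sampling density
#'
#' The alpha-sphere radius is set to `multiplier` times the median
#' nearest-neighbour spacing of the cloud, scaling with both resolution and
#' object size (scaling every point by `s` scales alpha by `s`).
#'
#' @param cloud A `point_cloud` with at least 10 points.
#' @param multiplier Positive multiplier (default 3).
#' @return Alpha in metres.
#' @export
choose_alpha <- function(cloud, multiplier = 3.0) {
  if (multiplier <= 0) stop("multiplier must be positive")
  if (nrow(cloud$xyz) < 10) stop("cloud too small to estimate spacing")
  sp <- median_nn_spacing(cloud$xyz)
  if (!is.finite(sp) || sp <= 0)
    stop("degenerate cloud: nearest-neighbour spacing is zero")
  multiplier * sp
}

# Core alpha-complex machinery. A Delaunay tetrahedron is *kept* when its
# circumradius is <= alpha. Excluded tetrahedra reachable from outside the
# convex hull (flooding across shared faces never crossing a kept
# tetrahedron) are exterior; the rest are interior voids, which the solid
# encloses. The reported surface is the outer boundary: faces between
# {kept + voids} and the exterior, oriented outward.
# alpha-independent structure of a cloud's Delaunay complex: tetrahedra,
# circumradii, per-tetra volumes, the four faces of each tetrahedron and the
# matching face occurrence of the neighbouring tetrahedron (NA on the hull)
complex_structure <- function(xyz, tet = NULL) {
  if (is.null(tet)) tet <- delaunay_tetrahedra(xyz)
  nt <- nrow(tet)
  faces <- rbind(tet[, c(2, 3, 4)], tet[, c(1, 4, 3)],
                 tet[, c(1, 2, 4)], tet[, c(1, 3, 2)])
  owner <- rep(seq_len(nt), 4)
  opp <- c(tet[, 1], tet[, 2], tet[, 3], tet[, 4])
  sf1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  sf3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  sf2 <- as.numeric(faces[, 1]) + faces[, 2] + faces[, 3] - sf1 - sf3
  npts <- nrow(xyz) + 1
  key <- (sf1 * npts + sf2) * npts + sf3
  # equal keys are adjacent after sorting; each key occurs once or twice
  ord <- order(key)
  partner <- rep(NA_integer_, length(key))
  same <- key[ord[-length(ord)]] == key[ord[-1]]
  i1 <- ord[which(same)]; i2 <- ord[which(same) + 1L]
  partner[i1] <- i2; partner[i2] <- i1
  maxedge <- do.call(pmax, lapply(list(c(1, 2), c(1, 3), c(1, 4), c(2, 3),
                                       c(2, 4), c(3, 4)), function(p)
    sqrt(rowSums((xyz[tet[, p[1]], , drop = FALSE] -
                    xyz[tet[, p[2]], , drop = FALSE])^2))))
  list(xyz = xyz, tet = tet, nt = nt, faces = faces, owner = owner,
       opp = opp, partner = partner,
       circumradius = tetra_circumradius(xyz, tet),
       maxedge = maxedge,
       tet_volume = tetra_volumes(xyz, tet))
}

# the alpha complex at one alpha. A Delaunay tetrahedron is *kept* when its
# circumradius is <= alpha. Excluded tetrahedra reachable from outside the
# convex hull (flooding across shared faces, never through a kept
# tetrahedron) are exterior; the rest are interior voids, enclosed by the
# solid.
alpha_complex <- function(xyz, alpha, structure = NULL) {
  cs <- if (is.null(structure)) complex_structure(xyz) else structure
  # regularised membership: keep by circumradius, or when all four vertices
  # fit inside one alpha-ball -- near-coplanar tetrahedra along flat or
  # quantised surfaces have arbitrarily large circumspheres, yet an
  # alpha-ball cannot pass between their vertices; excluding them pinches
  # the boundary and never closes
  kept <- cs$circumradius <= alpha | cs$maxedge <= 2 * alpha
  exterior <- rep(FALSE, cs$nt)
  if (any(!kept)) {
    hull_owner <- cs$owner[is.na(cs$partner)]
    seeds <- unique(hull_owner[!kept[hull_owner]])
    if (length(seeds)) {
      has_p <- !is.na(cs$partner)
      pi_ <- cs$owner[has_p]
      pj <- cs$owner[cs$partner[has_p]]
      both_ex <- !kept[pi_] & !kept[pj]
      g <- igraph::make_empty_graph(n = cs$nt, directed = FALSE)
      if (any(both_ex))
        g <- igraph::add_edges(g, rbind(pi_[both_ex], pj[both_ex]))
      comp <- igraph::components(g)$membership
      exterior <- comp %in% unique(comp[seeds]) & !kept
    }
  }
  c(cs, list(kept = kept, solid = !exterior))
}

#' Alpha-shape surface reconstruction
#'
#' Builds the alpha complex (Delaunay tetrahedra with circumradius <= alpha)
#' of the cloud and returns the *outer* boundary surface of the solid it
#' bounds: internal cavities of the crust that are sealed off from the
#' outside are treated as part of the solid, which is what volume measurement
#' of a surface-sampled object requires (the raw alpha complex of a surface
#' sample is a thin crust). As `alpha -> Inf` the result is the convex hull;
#' the enclosed volume is monotonically non-decreasing in alpha.
#'
#' @param cloud A `point_cloud` (>= 4 non-coplanar points).
#' @param alpha Alpha-sphere radius in metres (> 0).
#' @return A `trimesh` whose vertices are the cloud points, with attributes
#'   `watertight` (every boundary edge shared by exactly two faces),
#'   `enclosed_volume` (units^3, from the kept + void tetrahedra) and
#'   `alpha`.
#' @export
alpha_shape <- function(cloud, alpha) {
  stopifnot(alpha > 0)
  xyz <- cloud$xyz
  if (nrow(xyz) < 4) stop("need at least 4 points")
  ac <- alpha_complex(xyz, alpha)
  boundary_from_complex(xyz, ac, alpha)
}

boundary_from_complex <- function(xyz, ac, alpha) {
  solid_face <- ac$solid[ac$owner]
  # boundary: faces of solid tetrahedra on the hull or facing a non-solid twin
  has_p <- !is.na(ac$partner)
  twin_solid <- rep(FALSE, length(ac$owner))
  twin_solid[has_p] <- ac$solid[ac$owner[ac$partner[has_p]]]
  boundary <- solid_face & !twin_solid
  f <- ac$faces[boundary, , drop = FALSE]
  ov <- ac$opp[boundary]
  # orient outward: normal away from the owning tetra's opposite vertex
  a <- xyz[f[, 1], , drop = FALSE]
  b <- xyz[f[, 2], , drop = FALSE]
  cc <- xyz[f[, 3], , drop = FALSE]
  n1 <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) -
                (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) -
                (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
                (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  d <- xyz[ov, , drop = FALSE] - a
  flip <- rowSums(n1 * d) > 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  vol <- sum(ac$tet_volume[ac$solid])
  mesh <- structure(list(vertices = xyz, faces = f), class = "trimesh")
  attr(mesh, "watertight") <- nrow(f) > 0 && mesh_is_closed(f)
  attr(mesh, "enclosed_volume") <- vol
  attr(mesh, "alpha") <- alpha
  mesh
}

#' Estimate object volume from a completed point cloud
#'
#' End of the pipeline: pick alpha from the sampling density
#' ([choose_alpha()]), reconstruct the alpha-shape surface, and measure the
#' enclosed volume. If the reconstruction collapses to an open or crust-only
#' shell (outer boundary not closed, or enclosed volume under a quarter of
#' the convex hull's), alpha is doubled and the reconstruction repeated --
#' two opposite views always leave a thin grazing-angle band of sparse
#' sampling near the mutual silhouette, and the escalation bridges it while
#' still preserving concavities larger than the final alpha.
#'
#' @param cloud A world-frame `point_cloud` (metres), e.g. from
#'   [complete_cloud()].
#' @param multiplier Alpha multiplier passed to [choose_alpha()].
#' @param max_doublings Escalation cap (default 8).
#' @param plateau_tol Relative volume change under which a doubling counts
#'   as converged. The default 0.01 lies below the typical volume increment
#'   of bridging a sampling seam between two fused views (a few percent), so
#'   escalation closes such seams, while genuine concavities -- whose
#'   bridging adds far more than 1% in one doubling -- are preserved.
#' @return A list of class `volume_result`: `volume_cm3`, `alpha` (m),
#'   `watertight`, `n_triangles`, `escalations`, `mesh`.
#' @export
estimate_volume <- function(cloud, multiplier = 3.0, max_doublings = 8,
                            plateau_tol = 0.01) {
  alpha0 <- choose_alpha(cloud, multiplier)
  xyz <- cloud$xyz
  cs <- complex_structure(xyz)
  cut_at <- function(alpha)
    boundary_from_complex(xyz, alpha_complex(xyz, alpha, structure = cs),
                          alpha)
  alpha <- alpha0
  mesh <- cut_at(alpha)
  esc <- 0L
  while (esc < max_doublings) {
    mesh2 <- cut_at(alpha * 2)
    v1 <- attr(mesh, "enclosed_volume"); v2 <- attr(mesh2, "enclosed_volume")
    if (attr(mesh, "watertight") && v2 <= v1 * (1 + plateau_tol)) break
    alpha <- alpha * 2
    mesh <- mesh2
    esc <- esc + 1L
  }
  if (!attr(mesh, "watertight"))
    warning("alpha-shape surface is not closed; volume is best-effort")
  structure(list(volume_cm3 = attr(mesh, "enclosed_volume") * 1e6,
                 alpha = alpha, watertight = attr(mesh, "watertight"),
                 n_triangles = nrow(mesh$faces), escalations = esc,
                 mesh = mesh),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf(
    "<volume_result: %.2f cm^3, alpha = %.4f m, %d triangles, %s%s>\n",
    x$volume_cm3, x$alpha, x$n_triangles,
    if (x$watertight) "watertight" else "open",
    if (x$escalations > 0) sprintf(", %d alpha doublings", x$escalations)
    else ""))
  invisible(x)
}

#' Convex hull volume of a point cloud
#'
#' The alpha -> Inf limit of the alpha shape; exposed as the baseline
#' convex-hull volumetry.
#'
#' @param cloud A `point_cloud`.
#' @return Volume in the cloud's units cubed.
#' @export
convex_hull_volume <- function(cloud) {
  tet <- delaunay_tetrahedra(cloud$xyz)
  sum(tetra_volumes(cloud$xyz, tet))
}
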