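#' Analytic test primitives
#'
#' Triangle meshes of simple solids with closed-form volumes, used as ground
#' truth for the volume-estimation pipeline in place of scanned household
#' objects. Sizes are given in centimetres (the unit volumes are reported in);
#' mesh vertex coordinates are in metres, matching the rest of the geometry
#' stack.
#'
#' Kinds and size parameters:
#' \describe{
#'   \item{cube}{`edge` (cm); volume `edge^3`.}
#'   \item{sphere}{`r` (cm); volume `4/3 pi r^3`. Icosphere tessellation.}
#'   \item{cylinder}{`r`, `h` (cm); volume `pi r^2 h`.}
#'   \item{ellipsoid}{`a`, `b`, `c` semi-axes (cm); volume `4/3 pi a b c`.}
#'   \item{capsule}{`r`, `h` cylindrical section (cm); volume
#'     `pi r^2 h + 4/3 pi r^3`.}
#'   \item{bent_capsule}{`r` tube radius, `arc_radius` centre-line bend
#'     radius, `arc_degrees` swept angle (cm/deg); a banana-like solid. By
#'     Pappus' centroid theorem the tube part has volume `pi r^2 * L` with
#'     `L` the centre-line arc length (valid while `arc_radius > r`), plus two
#'     hemispherical caps.}
#' }
#'
#' @param kind Primitive kind, see Details.
#' @param ... Size parameters in cm (see Details).
#' @param resolution Tessellation level: icosphere subdivision depth for
#'   curved solids (default 4) and azimuthal segment count for
#'   cylinder/capsule-like solids (default 96).
#' @return A list of class `trimesh` with `vertices` (n x 3, metres), `faces`
#'   (m x 3, 1-based, outward-oriented) and `analytic_volume_cm3`.
#' @examples
#' m <- make_primitive("cube", edge = 5.7)
#' m$analytic_volume_cm3          # 185.193
#' mesh_volume(m) * 1e6           # agrees
#' @export
make_primitive <- function(kind = c("cube", "sphere", "cylinder", "ellipsoid",
                                    "capsule", "bent_capsule"),
                           ..., resolution = NULL) {
  kind <- match.arg(kind)
  p <- list(...)
  need <- function(nm, default = NULL) {
    if (!is.null(p[[nm]])) {
      v <- p[[nm]]
      if (!is.numeric(v) || v <= 0) stop(sprintf("'%s' must be positive", nm))
      v
    } else if (!is.null(default)) default
    else stop(sprintf("primitive '%s' needs size parameter '%s'", kind, nm))
  }
  mesh <- switch(kind,
    cube = {
      e <- need("edge") / 100
      m <- mesh_cube(e)
      m$analytic_volume_cm3 <- (e * 100)^3
      m
    },
    sphere = {
      r <- need("r") / 100
      m <- mesh_icosphere(r, if (is.null(resolution)) 4L else resolution)
      m$analytic_volume_cm3 <- 4 / 3 * pi * (r * 100)^3
      m
    },
    ellipsoid = {
      a <- need("a") / 100; b <- need("b") / 100; cc <- need("c") / 100
      m <- mesh_icosphere(1, if (is.null(resolution)) 4L else resolution)
      m$vertices <- m$vertices %*% diag(c(a, b, cc))
      m$analytic_volume_cm3 <- 4 / 3 * pi * a * b * cc * 1e6
      m
    },
    cylinder = {
      r <- need("r") / 100; h <- need("h") / 100
      m <- mesh_cylinder(r, h, if (is.null(resolution)) 96L else resolution)
      m$analytic_volume_cm3 <- pi * (r * 100)^2 * (h * 100)
      m
    },
    capsule = {
      r <- need("r") / 100; h <- need("h") / 100
      m <- mesh_capsule(r, h, if (is.null(resolution)) 96L else resolution)
      m$analytic_volume_cm3 <- (pi * r^2 * h + 4 / 3 * pi * r^3) * 1e6
      m
    },
    bent_capsule = {
      r <- need("r") / 100
      ar <- need("arc_radius") / 100
      ad <- need("arc_degrees", 120)
      if (ar <= r) stop("arc_radius must exceed the tube radius")
      m <- mesh_bent_capsule(r, ar, ad,
                             if (is.null(resolution)) 96L else resolution)
      arc_len <- ar * ad * pi / 180
      m$analytic_volume_cm3 <- (pi * r^2 * arc_len + 4 / 3 * pi * r^3) * 1e6
      m
    })
  if (signed_mesh_volume(mesh) < 0)   # enforce outward winding
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh$kind <- kind
  class(mesh) <- "trimesh"
  mesh
}

signed_mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh%s: %d vertices, %d faces%s>\n",
              if (is.null(x$kind)) "" else paste0(" ", x$kind),
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$analytic_volume_cm3)) "" else
                sprintf(", analytic volume %.3f cm^3", x$analytic_volume_cm3)))
  invisible(x)
}

mesh_cube <- function(edge) {
  s <- edge / 2
  v <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  dimnames(v) <- NULL
  # 12 triangles, outward-oriented
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -s
    c(5, 6, 7), c(6, 8, 7),   # z = +s
    c(1, 2, 5), c(2, 6, 5),   # y = -s
    c(3, 7, 4), c(4, 7, 8),   # y = +s
    c(1, 5, 3), c(3, 5, 7),   # x = -s
    c(2, 4, 6), c(4, 8, 6))   # x = +s
  list(vertices = v, faces = f)
}

mesh_icosphere <- function(r, subdiv = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdiv)) {
    sub <- subdivide_mesh(v, f)
    v <- sub$vertices; f <- sub$faces
    v <- v / sqrt(rowSums(v^2))  # reproject to the sphere each level
  }
  v <- v / sqrt(rowSums(v^2))
  list(vertices = v * r, faces = f)
}

subdivide_mesh <- function(v, f) {
  # split each triangle in four; midpoint vertices shared via an edge key
  nv <- nrow(v)
  e1 <- pmin(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
  e2 <- pmax(f[, c(1, 2, 3)], f[, c(2, 3, 1)])
  key <- as.numeric(e1) * (nv + 1) + as.numeric(e2)
  uk <- unique(key)
  mid_id <- nv + match(key, uk)
  ua <- as.numeric(e1)[match(uk, key)]
  ub <- as.numeric(e2)[match(uk, key)]
  vmid <- (v[ua, , drop = FALSE] + v[ub, , drop = FALSE]) / 2
  m <- matrix(mid_id, ncol = 3)  # midpoints of edges (1,2), (2,3), (3,1)
  fnew <- rbind(
    cbind(f[, 1], m[, 1], m[, 3]),
    cbind(f[, 2], m[, 2], m[, 1]),
    cbind(f[, 3], m[, 3], m[, 2]),
    m)
  list(vertices = rbind(v, vmid), faces = fnew)
}

mesh_cylinder <- function(r, h, n = 96L) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  top <- cbind(r * cos(ang), rep(h / 2, n), r * sin(ang))
  bot <- cbind(r * cos(ang), rep(-h / 2, n), r * sin(ang))
  v <- rbind(top, bot, c(0, h / 2, 0), c(0, -h / 2, 0))
  ct <- 2L * n + 1L; cb <- 2L * n + 2L
  nxt <- c(seq_len(n)[-1], 1L)
  f <- rbind(
    cbind(seq_len(n), nxt, n + seq_len(n)),          # side upper tris
    cbind(nxt, n + nxt, n + seq_len(n)),             # side lower tris
    cbind(ct, nxt, seq_len(n)),                      # top cap (y = +h/2)
    cbind(cb, n + seq_len(n), n + nxt))              # bottom cap
  list(vertices = v, faces = f)
}

# capsule: cylinder of height h about y, hemispherical caps, n azimuthal
# segments and n/2 rings per cap (UV tessellation)
mesh_capsule <- function(r, h, n = 96L) {
  stacks <- max(8L, as.integer(n / 2))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  vs <- list(); rings <- list()
  # from top pole down: lat in [0, pi/2] upper cap, then lower cap [pi/2, pi]
  lat_top <- seq(0, pi / 2, length.out = stacks + 1)[-1]
  lat_bot <- seq(pi / 2, pi, length.out = stacks + 1)[-(stacks + 1)]
  vtx <- rbind(c(0, h / 2 + r, 0))
  ring_ids <- list()
  for (la in lat_top) {
    y <- h / 2 + r * cos(la); rr <- r * sin(la)
    ring_ids[[length(ring_ids) + 1]] <- nrow(vtx) + seq_len(n)
    vtx <- rbind(vtx, cbind(rr * cos(ang), y, rr * sin(ang)))
  }
  for (la in lat_bot) {
    y <- -h / 2 + r * cos(la); rr <- r * sin(la)
    ring_ids[[length(ring_ids) + 1]] <- nrow(vtx) + seq_len(n)
    vtx <- rbind(vtx, cbind(rr * cos(ang), y, rr * sin(ang)))
  }
  vtx <- rbind(vtx, c(0, -h / 2 - r, 0))
  south <- nrow(vtx)
  nxt <- c(seq_len(n)[-1], 1L)
  f <- cbind(1L, ring_ids[[1]][nxt], ring_ids[[1]])         # north fan
  for (i in seq_len(length(ring_ids) - 1)) {
    a <- ring_ids[[i]]; b <- ring_ids[[i + 1]]
    f <- rbind(f,
               cbind(a, a[nxt], b),
               cbind(a[nxt], b[nxt], b))
  }
  last <- ring_ids[[length(ring_ids)]]
  f <- rbind(f, cbind(south, last, last[nxt]))              # south fan
  list(vertices = vtx, faces = f)
}

# bent capsule: tube of radius r swept along a circular arc of radius
# arc_radius in the x-y plane, spherical caps at both ends
mesh_bent_capsule <- function(r, arc_radius, arc_degrees, n = 96L) {
  nseg <- max(16L, as.integer(n / 2))      # segments along the arc
  half <- arc_degrees / 2 * pi / 180
  tvals <- seq(-half, half, length.out = nseg + 1)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  vtx <- NULL; ring_ids <- list()
  for (tt in tvals) {
    centre <- c(arc_radius * sin(tt), arc_radius * cos(tt) - arc_radius, 0)
    # local frame: radial (in-plane) and z
    rad <- c(sin(tt), cos(tt), 0)
    ez <- c(0, 0, 1)
    ring <- t(centre + outer(rad, r * cos(ang)) + outer(ez, r * sin(ang)))
    ring_ids[[length(ring_ids) + 1]] <- NROW(vtx) + seq_len(n)
    vtx <- rbind(vtx, ring)
  }
  nxt <- c(seq_len(n)[-1], 1L)
  f <- NULL
  for (i in seq_len(length(ring_ids) - 1)) {
    a <- ring_ids[[i]]; b <- ring_ids[[i + 1]]
    f <- rbind(f, cbind(a, b, a[nxt]), cbind(a[nxt], b, b[nxt]))
  }
  # hemispherical caps: UV hemisphere aligned with the arc tangent at each end
  for (end in c(-1, 1)) {
    tt <- end * half
    centre <- c(arc_radius * sin(tt), arc_radius * cos(tt) - arc_radius, 0)
    tangent <- end * c(cos(tt), -sin(tt), 0)
    rad <- c(sin(tt), cos(tt), 0); ez <- c(0, 0, 1)
    stacks <- max(6L, as.integer(n / 6))
    lats <- seq(0, pi / 2, length.out = stacks + 1)[-1]  # pole excluded
    pole <- centre + r * tangent
    vtx <- rbind(vtx, pole); pole_id <- nrow(vtx)
    prev <- if (end == 1) ring_ids[[length(ring_ids)]] else ring_ids[[1]]
    # rings from equator (the tube's end ring) towards the pole
    for (la in rev(lats[-length(lats)])) {
      rr <- r * sin(la); y <- r * cos(la)
      ring <- t(centre + y * tangent + outer(rad, rr * cos(ang)) +
                  outer(ez, rr * sin(ang)))
      ids <- nrow(vtx) + seq_len(n)
      vtx <- rbind(vtx, ring)
      fl <- if (end == 1) cbind(prev, ids, prev[nxt]) else
        cbind(prev, prev[nxt], ids)
      fl2 <- if (end == 1) cbind(prev[nxt], ids, ids[nxt]) else
        cbind(prev[nxt], ids[nxt], ids)
      f <- rbind(f, fl, fl2)
      prev <- ids
    }
    fcap <- if (end == 1) cbind(prev, pole_id, prev[nxt]) else
      cbind(prev, prev[nxt], pole_id)
    f <- rbind(f, fcap)
  }
  list(vertices = vtx, faces = f)
}

#' Signed-tetrahedron mesh volume
#'
#' Volume of a closed triangle mesh by the divergence theorem: the absolute
#' value of the sum over faces of `det(v1, v2, v3) / 6`. Orientation
#' independent through the absolute value (a mesh with all faces inverted
#' yields the same volume). Units are the cube of the mesh's coordinate units.
#'
#' @param mesh A `trimesh` (or any list with `vertices` and `faces`).
#' @param warn_open Warn if the mesh is not closed (some edge not shared by
#'   exactly two faces); the returned value is then best-effort.
#' @return Volume in the mesh's units cubed.
#' @export
mesh_volume <- function(mesh, warn_open = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  if (is.null(f) || nrow(f) == 0) return(0)
  if (warn_open && !mesh_is_closed(f))
    warning("mesh is not closed; volume is best-effort")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  s <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
           a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
           a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))
  abs(s) / 6
}

mesh_is_closed <- function(f) {
  if (nrow(f) == 0) return(FALSE)
  n <- max(f) + 1
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  key <- pmin(e[, 1], e[, 2]) * n + pmax(e[, 1], e[, 2])
  all(table(key) == 2)
}

#' Uniform surface sampling of a triangle mesh
#'
#' Draws points uniformly by area: faces sampled proportionally to area, then
#' uniform barycentric coordinates. Used to build synthetic point-cloud
#' fixtures with known enclosed volume.
#'
#' @param mesh A `trimesh`.
#' @param n Number of points.
#' @return An n x 3 matrix of points on the surface.
#' @export
sample_mesh_surface <- function(mesh, n) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  pick <- sample.int(nrow(f), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  w1 * a[pick, , drop = FALSE] +
    w2 * (a + ab)[pick, , drop = FALSE] +
    w3 * (a + ac)[pick, , drop = FALSE]
}
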