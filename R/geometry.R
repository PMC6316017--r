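#' Pinhole camera intrinsics
#'
#' Container for the intrinsic matrix parameters of an ideal (distortion-free)
#' pinhole camera. Pixel centres sit at integer coordinates; `(cx, cy)` is the
#' principal point in the same 0-based pixel coordinate system, so a point on
#' the optical axis projects to pixel `(u = cx, v = cy)`.
#'
#' @param fx,fy Focal lengths in pixels (positive).
#' @param cx,cy Principal point in pixels; must lie inside the image.
#' @param width,height Image dimensions in pixels.
#' @return An object of class `intrinsics`.
#' @examples
#' k <- intrinsics(570, 570, 319.5, 239.5, 640, 480)
#' intrinsics_matrix(k)
#' @export
intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point (cx, cy) must lie inside the image")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "intrinsics")
}

#' @rdname intrinsics
#' @param k An `intrinsics` object.
#' @return `intrinsics_matrix`: the 3x3 upper-triangular matrix K.
#' @export
intrinsics_matrix <- function(k) {
  matrix(c(k$fx, 0, 0, 0, k$fy, 0, k$cx, k$cy, 1), 3, 3)
}

#' Default camera intrinsics
#'
#' A typical structured-light depth camera: 640x480, 570 px focal length,
#' principal point at the image centre. `scale` shrinks both the resolution
#' and the focal length proportionally (e.g. `scale = 1/4` gives 160x120,
#' fx = 142.5), which leaves the field of view unchanged -- handy for fast
#' tests.
#'
#' @param scale Isotropic resolution scale factor.
#' @return An `intrinsics` object.
#' @export
default_intrinsics <- function(scale = 1) {
  w <- as.integer(round(640 * scale)); h <- as.integer(round(480 * scale))
  intrinsics(570 * scale, 570 * scale, w / 2 - 0.5, h / 2 - 0.5, w, h)
}

#' Metric depth image
#'
#' Validates and tags a depth map: a numeric matrix of metric depths (metres)
#' indexed `[v + 1, u + 1]` (row = image row v, column = image column u),
#' where exactly 0 marks an invalid (no measurement) pixel. Negative or
#' non-finite values are rejected.
#'
#' @param mat Numeric matrix of depths in metres.
#' @return The matrix with class `depth_image`.
#' @export
depth_image <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("depth must be a numeric matrix")
  if (anyNA(mat) || any(!is.finite(mat))) stop("depth values must be finite")
  if (any(mat < 0)) stop("negative depths are invalid; use 0 for missing pixels")
  class(mat) <- c("depth_image", class(unclass(mat)))
  mat
}

#' Rigid camera pose
#'
#' Pose convention: a world point `p_w` maps into the camera frame as
#' `p_c = R %*% p_w + t`. `R` must be orthonormal with determinant +1.
#'
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector in metres.
#' @param tol Orthonormality tolerance.
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(R, t = c(0, 0, 0), tol = 1e-9) {
  R <- unname(as.matrix(R)); t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3, all(is.finite(R)),
            all(is.finite(t)))
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("R is not orthonormal")
  if (abs(det(R) - 1) > tol)
    stop("R must be a proper rotation (det = +1)")
  structure(list(R = R, t = t), class = "rigid_pose")
}

#' Labelled 3D point cloud
#'
#' @param xyz n x 3 numeric matrix of points in metres.
#' @param frame Frame label: `"initial_camera"`, `"opposite_camera"` or
#'   `"world"`. The world frame of the fusion pipeline coincides with the
#'   initial camera frame.
#' @return An object of class `point_cloud` with fields `xyz` and `frame`.
#' @export
point_cloud <- function(xyz, frame = c("world", "initial_camera",
                                       "opposite_camera")) {
  frame <- match.arg(frame)
  xyz <- as.matrix(xyz)
  if (length(xyz) == 0L) xyz <- matrix(numeric(0), 0, 3)
  stopifnot(ncol(xyz) == 3)
  if (anyNA(xyz) || any(!is.finite(xyz))) stop("point coordinates must be finite")
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz, frame = frame), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points, frame = %s>\n", nrow(x$xyz), x$frame))
  invisible(x)
}

#' Rotation about the camera y-axis
#'
#' Returns the rotation matrix
#' \deqn{R_y(\theta) = \begin{pmatrix} \cos\theta & 0 & \sin\theta \\ 0 & 1 &
#' 0 \\ -\sin\theta & 0 & \cos\theta \end{pmatrix}}
#' used by the opposite-camera model: the second camera's orientation is
#' `rotation_about_y(180)` relative to the first, where y is the initial
#' camera's vertical axis. Evaluated with `cospi`/`sinpi` so that multiples of
#' 90 degrees come out exact (`rotation_about_y(180)` is exactly
#' `diag(c(-1, 1, -1))`).
#'
#' @param theta_degrees Rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @examples
#' rotation_about_y(180)
#' @export
rotation_about_y <- function(theta_degrees) {
  stopifnot(is.finite(theta_degrees))
  ct <- cospi(theta_degrees / 180)
  st <- sinpi(theta_degrees / 180)
  matrix(c(ct, 0, -st,
           0,  1,  0,
           st, 0,  ct), 3, 3)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Back-project a depth image to a camera-frame point cloud
#'
#' Every valid pixel (depth > 0, inside `mask` if given) becomes one 3D point
#' via the inverse pinhole map `(X, Y, Z) = Z * K^{-1} (u, v, 1)`, i.e.
#' `X = Z (u - cx) / fx`, `Y = Z (v - cy) / fy`. The Z coordinate of each
#' point equals its source pixel's depth exactly.
#'
#' @param depth A `depth_image` (or numeric matrix).
#' @param k An `intrinsics` whose dimensions match `depth`.
#' @param mask Optional logical matrix (same shape) restricting the pixels.
#' @param frame Frame label for the returned cloud.
#' @return A `point_cloud` in the camera frame.
#' @export
back_project <- function(depth, k, mask = NULL, frame = "initial_camera") {
  if (nrow(depth) != k$height || ncol(depth) != k$width)
    stop(sprintf("depth is %dx%d but intrinsics expect %dx%d",
                 nrow(depth), ncol(depth), k$height, k$width))
  keep <- depth > 0
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(unclass(depth))))
      stop("mask dimensions must match the depth image")
    keep <- keep & mask
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    return(point_cloud(matrix(numeric(0), 0, 3), frame))
  v <- (idx - 1L) %% nrow(depth)        # 0-based row
  u <- (idx - 1L) %/% nrow(depth)       # 0-based column
  z <- as.numeric(depth[idx])
  point_cloud(cbind(z * (u - k$cx) / k$fx, z * (v - k$cy) / k$fy, z), frame)
}

#' Project a camera-frame point cloud to a depth image
#'
#' Inverse of [back_project()]: each point with Z > 0 lands on pixel
#' `(round(fx X / Z + cx), round(fy Y / Z + cy))` (ties round half away from
#' zero). When several points map to one pixel the smallest Z wins (z-buffer);
#' points behind the camera or projecting outside the frame are dropped.
#'
#' @param cloud A `point_cloud` in the camera frame.
#' @param k An `intrinsics`.
#' @return A `depth_image` of the intrinsics' dimensions.
#' @export
project <- function(cloud, k) {
  xyz <- cloud$xyz
  out <- matrix(0, k$height, k$width)
  infront <- xyz[, 3] > 0
  xyz <- xyz[infront, , drop = FALSE]
  if (nrow(xyz) > 0) {
    u <- round_half_away(k$fx * xyz[, 1] / xyz[, 3] + k$cx)
    v <- round_half_away(k$fy * xyz[, 2] / xyz[, 3] + k$cy)
    ok <- u >= 0 & u < k$width & v >= 0 & v < k$height
    if (any(ok)) {
      lin <- v[ok] + 1 + u[ok] * k$height
      z <- xyz[ok, 3]
      # z-buffer: keep nearest point per pixel
      o <- order(lin, z)
      lin <- lin[o]; z <- z[o]
      first <- !duplicated(lin)
      out[lin[first]] <- z[first]
    }
  }
  depth_image(out)
}

#' Register a camera-frame cloud into the world frame
#'
#' Applies the inverse rigid transform `p_w = R^{-1} (p_c - t)` for a pose
#' with convention `p_c = R p_w + t`. In the fusion pipeline the world frame
#' is the initial camera frame and the opposite view's pose is
#' `R = rotation_about_y(180)` with the inter-camera translation `t`.
#'
#' @param cloud A `point_cloud` in the camera frame of `pose`.
#' @param pose A `rigid_pose` (validated: orthonormal R).
#' @return A `point_cloud` in the world frame.
#' @export
register_to_world <- function(cloud, pose) {
  if (!inherits(pose, "rigid_pose")) pose <- rigid_pose(pose$R, pose$t)
  xyz <- sweep(cloud$xyz, 2, pose$t) %*% pose$R  # (p - t) R == t(R^T (p - t)^T)
  point_cloud(xyz, "world")
}

#' Apply a rigid pose to world points
#'
#' Forward map `p_c = R p_w + t`; inverse of [register_to_world()].
#'
#' @inheritParams register_to_world
#' @param frame Frame label for the result.
#' @return A `point_cloud` in the camera frame.
#' @export
world_to_camera <- function(cloud, pose, frame = "initial_camera") {
  xyz <- sweep(cloud$xyz %*% t(pose$R), 2, pose$t, "+")
  point_cloud(xyz, frame)
}
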