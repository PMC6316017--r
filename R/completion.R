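#' Bilateral hole filling of a depth image
#'
#' Fills invalid (zero) pixels with the bilateral-weighted average of the
#' valid pixels within `radius`: spatial weights `exp(-d2 / (2 sigma_spatial^2))`
#' combined with range weights `exp(-(z - z_ref)^2 / (2 sigma_range^2))`
#' around the nearest-neighbourhood median, so filled values respect depth
#' discontinuities. Valid pixels are never modified. Passes repeat until no
#' fillable pixel remains or a pass fills nothing.
#'
#' By default only *enclosed* holes are filled: zero-regions 4-connected to
#' the image border count as background (an opposite-view render's empty
#' surround) and are left alone -- filling them would iteratively flood the
#' whole frame with copies of the object's depth. `holes = "all"` removes
#' that restriction.
#'
#' @param depth A `depth_image`.
#' @param radius Neighbourhood radius in pixels (>= 1).
#' @param sigma_spatial Spatial kernel SD in pixels.
#' @param sigma_range Range kernel SD in metres.
#' @param holes `"enclosed"` (default) or `"all"`.
#' @return A `depth_image` with holes filled.
#' @export
fill_depth_holes <- function(depth, radius = 2, sigma_spatial = 1.5,
                             sigma_range = 0.01,
                             holes = c("enclosed", "all")) {
  stopifnot(radius >= 1)
  holes <- match.arg(holes)
  d <- unclass(depth)
  fillable_mask <- if (holes == "enclosed") {
    lab <- .label_components_cpp(d == 0)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0]
    d == 0 & !(lab %in% border)
  } else d == 0
  dim(fillable_mask) <- dim(d)
  off <- expand.grid(dv = -radius:radius, du = -radius:radius)
  off <- off[off$dv != 0 | off$du != 0, ]
  sw <- exp(-(off$dv^2 + off$du^2) / (2 * sigma_spatial^2))
  keep <- off$dv^2 + off$du^2 <= radius^2
  off <- off[keep, ]; sw <- sw[keep]
  h <- nrow(d); w <- ncol(d)
  repeat {
    idx <- which(fillable_mask & d == 0)
    if (length(idx) == 0) break
    v0 <- (idx - 1L) %% h; u0 <- (idx - 1L) %/% h
    num <- numeric(length(idx)); den <- numeric(length(idx))
    vals <- matrix(NA_real_, length(idx), nrow(off))
    for (j in seq_len(nrow(off))) {
      v <- v0 + off$dv[j]; u <- u0 + off$du[j]
      ok <- v >= 0 & v < h & u >= 0 & u < w
      z <- rep(0, length(idx))
      z[ok] <- d[v[ok] + 1L + u[ok] * h]
      vals[, j] <- ifelse(z > 0, z, NA_real_)
    }
    nvalid <- rowSums(!is.na(vals))
    fill <- nvalid >= 1
    if (!any(fill)) break
    zref <- apply(vals[fill, , drop = FALSE], 1, stats::median, na.rm = TRUE)
    for (j in seq_len(nrow(off))) {
      z <- vals[fill, j]
      wgt <- sw[j] * exp(-(z - zref)^2 / (2 * sigma_range^2))
      wgt[is.na(z)] <- 0; z[is.na(z)] <- 0
      num[fill] <- num[fill] + wgt * z
      den[fill] <- den[fill] + wgt
    }
    d[idx[fill]] <- num[fill] / den[fill]
  }
  depth_image(d)
}

#' Extract the object pixel mask from a depth image
#'
#' Valid (positive-depth) pixels, optionally minus pixels within
#' `background_tol` of a known background depth (a table plane), reduced to
#' the largest 4-connected component. Rendered object-only images therefore
#' yield exactly their valid pixels.
#'
#' @param depth A `depth_image`.
#' @param background_depth Optional scalar background depth in metres.
#' @param background_tol Tolerance around `background_depth` (m).
#' @return Logical matrix of the same shape as `depth`.
#' @export
extract_object_mask <- function(depth, background_depth = NULL,
                                background_tol = 0.005) {
  m <- unclass(depth) > 0
  if (!is.null(background_depth))
    m <- m & abs(unclass(depth) - background_depth) > background_tol
  if (!any(m)) stop("no object found: mask is empty")
  lab <- .label_components_cpp(m)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Edge-preserving bilateral smoothing of a depth image
#'
#' Classic bilateral filter over the valid pixels: each valid pixel is
#' replaced by the average of the valid pixels within `radius`, weighted by a
#' spatial Gaussian and a range Gaussian centred on the pixel's own depth, so
#' depth discontinuities larger than a few `sigma_range` are preserved.
#' Invalid (zero) pixels stay invalid. Used to suppress per-pixel noise in
#' synthesised opposite-view maps before back-projection.
#'
#' @param depth A `depth_image`.
#' @param radius Window radius in pixels.
#' @param sigma_spatial Spatial kernel SD in pixels.
#' @param sigma_range Range kernel SD in metres.
#' @param passes Number of smoothing passes (repeated application reduces
#'   the residual noise near depth discontinuities, where the range kernel
#'   restricts averaging).
#' @return A smoothed `depth_image`.
#' @export
bilateral_smooth <- function(depth, radius = 3, sigma_spatial = 1.5,
                             sigma_range = 0.01, passes = 1) {
  for (p in seq_len(passes))
    depth <- bilateral_smooth_once(depth, radius, sigma_spatial, sigma_range)
  depth
}

bilateral_smooth_once <- function(depth, radius, sigma_spatial, sigma_range) {
  d <- unclass(depth)
  h <- nrow(d); w <- ncol(d)
  valid <- d > 0
  off <- expand.grid(dv = -radius:radius, du = -radius:radius)
  keep <- off$dv^2 + off$du^2 <= radius^2
  off <- off[keep, ]
  sw <- exp(-(off$dv^2 + off$du^2) / (2 * sigma_spatial^2))
  num <- matrix(0, h, w); den <- matrix(0, h, w)
  for (j in seq_len(nrow(off))) {
    dv <- off$dv[j]; du <- off$du[j]
    rs <- max(1, 1 - dv):min(h, h - dv)
    cs <- max(1, 1 - du):min(w, w - du)
    zn <- matrix(0, h, w)
    zn[rs, cs] <- d[rs + dv, cs + du]
    wgt <- sw[j] * exp(-(zn - d)^2 / (2 * sigma_range^2)) * (zn > 0)
    num <- num + wgt * zn
    den <- den + wgt
  }
  out <- d
  upd <- valid & den > 0
  out[upd] <- num[upd] / den[upd]
  depth_image(out)
}

#' Rim cloud with extrapolated tangent depths
#'
#' The outermost valid pixels of a depth map systematically land *short* of
#' the true occluding contour: on a curved surface the depth profile falls
#' off like a square root towards the limb, so the rim pixel's depth is
#' biased towards the camera by up to several millimetres at typical
#' resolutions. For each contour pixel this routine samples the depth along
#' the inward mask direction, fits `z(delta) = z_t - c * sqrt(delta + 0.5)`
#' by least squares, and back-projects the contour pixel at the extrapolated
#' tangent depth `z_t`. The resulting rim curves from two opposite views are
#' unbiased estimates of the same occluding contour and can be aligned by
#' ICP without a systematic depth collapse.
#'
#' @param depth A `depth_image` (hole-filled).
#' @param mask Logical object mask.
#' @param k An `intrinsics`.
#' @param n_samples Profile length in pixels (default 7).
#' @param smooth_k Contour-neighbourhood size for smoothing the fitted
#'   depths and slopes (0 or 1 disables).
#' @return A `point_cloud` (camera frame) of corrected rim points, with
#'   attribute `slope` (the fitted square-root coefficient, m per sqrt
#'   pixel; ~0 on flat-face boundaries). Contour pixels whose profile fit
#'   fails (too few valid samples, noise-inverted slope, out-of-range
#'   extrapolation) are dropped rather than kept at their biased raw depth,
#'   so the surviving rim is an unbiased contour estimate.
#' @export
rim_tangent_cloud <- function(depth, mask, k, n_samples = 7,
                              smooth_k = 15) {
  d <- unclass(depth)
  h <- nrow(d); w <- ncol(d)
  rim <- which(mask_contour(mask))
  v0 <- (rim - 1L) %% h + 1L
  u0 <- (rim - 1L) %/% h + 1L
  # inward direction from the local mask centroid
  zs <- rep(NA_real_, length(rim))
  slopes <- numeric(length(rim))
  zt_s <- rep(NA_real_, length(rim)); zt_l <- rep(NA_real_, length(rim))
  drss <- numeric(length(rim)); sl_s <- numeric(length(rim))
  z00 <- rep(NA_real_, length(rim))
  nrm_u <- numeric(length(rim)); nrm_v <- numeric(length(rim))
  for (i in seq_along(rim)) {
    vv <- max(1, v0[i] - 2):min(h, v0[i] + 2)
    uu <- max(1, u0[i] - 2):min(w, u0[i] + 2)
    sub <- mask[vv, uu, drop = FALSE]
    cv <- sum(vv * rowSums(sub)) / sum(sub) - v0[i]
    cu <- sum(uu * colSums(sub)) / sum(sub) - u0[i]
    nn <- sqrt(cv^2 + cu^2)
    z0 <- d[v0[i], u0[i]]
    if (!is.finite(nn) || nn < 1e-6) next
    cv <- cv / nn; cu <- cu / nn
    delta <- 0:(n_samples - 1)
    vi <- round(v0[i] + cv * delta); ui <- round(u0[i] + cu * delta)
    ok <- vi >= 1 & vi <= h & ui >= 1 & ui <= w
    zi <- rep(0, length(delta))
    zi[ok] <- d[cbind(vi[ok], ui[ok])]
    ok <- ok & zi > 0 & mask[cbind(pmax(vi, 1), pmax(ui, 1))]
    if (sum(ok) < 4) next
    dd <- delta[ok]; zz <- zi[ok]
    # two candidate boundary models: occluding contour on a curved surface
    # falls off like sqrt(delta); a face or edge boundary is linear. Both
    # fits are kept here; the choice is made after smoothing the residual
    # difference along the contour, because per-point selection flips under
    # noise and biases the extrapolation.
    fit_s <- stats::lm.fit(cbind(1, sqrt(dd + 0.5)), zz)
    fit_l <- stats::lm.fit(cbind(1, dd + 0.5), zz)
    zt_s[i] <- fit_s$coefficients[1]
    zt_l[i] <- fit_l$coefficients[1]
    drss[i] <- sum(fit_l$residuals^2) - sum(fit_s$residuals^2)
    sl_s[i] <- max(-fit_s$coefficients[2], 0)
    z00[i] <- z0
    nrm_u[i] <- cu; nrm_v[i] <- cv
  }
  # contour-smoothed model choice, then the winning intercept per point;
  # wild extrapolations are dropped (the fitted sign is never censored:
  # rejecting "impossible" inverted fits would bias the rim under noise)
  fitted <- is.finite(zt_s) & is.finite(zt_l)
  if (sum(fitted) > 15) {
    uvf <- cbind(u0[fitted], v0[fitted])
    nnf <- RANN::nn2(uvf, uvf, k = min(15, sum(fitted)))
    drss_s <- rowMeans(matrix(drss[fitted][nnf$nn.idx], nrow = sum(fitted)))
    drss[fitted] <- drss_s
  }
  use_sqrt <- fitted & drss > 0
  zs[use_sqrt] <- zt_s[use_sqrt]
  slopes[use_sqrt] <- sl_s[use_sqrt]
  lin <- fitted & !use_sqrt
  zs[lin] <- zt_l[lin]
  slopes[lin] <- 0
  bad <- !is.na(zs) & abs(zs - z00) > 0.05
  zs[bad] <- NA_real_
  keep <- !is.na(zs)
  zk <- zs[keep]
  uk <- u0[keep]; vk <- v0[keep]
  sk <- slopes[keep]
  # smooth tangent depths and slopes along the contour: per-point fits on a
  # noisy map scatter by several mm, and nearest-neighbour matching of two
  # scattered rings is minimum-seeking (it would pull them together); local
  # averaging removes the scatter while following the contour's depth trend
  if (smooth_k > 1 && length(zk) > smooth_k) {
    nn <- RANN::nn2(cbind(uk, vk), cbind(uk, vk),
                    k = min(smooth_k, length(zk)))
    zk <- rowMeans(matrix(zk[nn$nn.idx], nrow = length(zk)))
    sk <- rowMeans(matrix(sk[nn$nn.idx], nrow = length(sk)))
  }
  # limb-separation correction: a camera's occluding contour sits short of
  # the tangent ring shared by two opposite views by R_c * rho_perp / z
  # (R_c the local meridional curvature radius, rho_perp the transverse
  # offset from the optical axis along the curvature -- i.e. contour-normal
  # -- direction). R_c follows from the fitted sqrt coefficient c via
  # z(delta) = sqrt(2 R_c s), s = delta * z / fx, so R_c = c^2 fx / (2 z).
  # Pushing each rim point deeper by that amount places both rims on the
  # mutual contour; flat edges (c = 0) are shared as-is and move nothing.
  xn <- (uk - 1 - k$cx) / k$fx
  yn <- (vk - 1 - k$cy) / k$fy
  rc <- sk^2 * k$fx / (2 * zk)
  rho_perp <- abs(xn * nrm_u[keep] + yn * nrm_v[keep])
  zk <- zk + pmin(rc * rho_perp, 0.006)
  pts <- cbind(zk * xn, zk * yn, zk)
  out <- point_cloud(pts, "initial_camera")
  attr(out, "slope") <- sk
  out
}

#' Silhouette contour of a pixel mask
#'
#' Mask pixels with at least one 4-neighbour outside the mask (or on the
#' image border): the rim used for contour-based ICP alignment.
#'
#' @param mask Logical matrix.
#' @return Logical matrix marking the contour pixels.
#' @export
mask_contour <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask & !interior
}

#' Statistical outlier removal
#'
#' Computes each point's mean distance to its `k` nearest neighbours and
#' removes points whose mean distance exceeds the global mean plus
#' `std_ratio` standard deviations. Survivor order is preserved. Clouds with
#' `k` or fewer points are returned unchanged with a warning.
#'
#' @param cloud A `point_cloud`.
#' @param k Neighbour count (default 20).
#' @param std_ratio Threshold in SDs above the mean (default 2).
#' @return A filtered `point_cloud`; attribute `removed` gives the dropped
#'   count.
#' @export
remove_outliers <- function(cloud, k = 20, std_ratio = 2.0) {
  stopifnot(k >= 1)
  n <- nrow(cloud$xyz)
  if (n == 0) return(cloud)
  if (n <= k) {
    warning("cloud has <= k points; returned unchanged")
    return(cloud)
  }
  nn <- RANN::nn2(cloud$xyz, cloud$xyz, k = k + 1)
  mdist <- rowMeans(nn$nn.dists[, -1, drop = FALSE])
  thr <- mean(mdist) + std_ratio * stats::sd(mdist)
  keep <- mdist <= thr
  out <- point_cloud(cloud$xyz[keep, , drop = FALSE], cloud$frame)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Parameters of the translation-only ICP
#'
#' @param max_iterations Iteration cap.
#' @param tolerance Convergence tolerance on the change of the RMS
#'   point-to-point distance (m).
#' @param step_size Gradient-descent step as a fraction of the mean residual
#'   (1 = full centroid-alignment step); halved whenever a step would
#'   increase the cost.
#' @param rejection_dist Correspondence rejection distance floor (m). `NULL`
#'   (default) resolves at run time to 5 x the median nearest-neighbour
#'   spacing of the target cloud. While the alignment is still coarse the
#'   effective radius is `max(rejection_dist, 3 x current RMS)`, shrinking to
#'   the floor as the clouds approach.
#' @param k,std_ratio Outlier-removal settings carried by the parameter set
#'   for pipeline use.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100, tolerance = 1e-5,
                       step_size = 0.5, rejection_dist = NULL,
                       k = 20, std_ratio = 2.0) {
  stopifnot(max_iterations >= 1, tolerance > 0, step_size > 0, k >= 1,
            std_ratio > 0)
  if (!is.null(rejection_dist)) {
    stopifnot(rejection_dist > 0)
    if (tolerance >= rejection_dist)
      stop("tolerance must be smaller than the rejection distance")
  }
  structure(list(max_iterations = max_iterations, tolerance = tolerance,
                 step_size = step_size, rejection_dist = rejection_dist,
                 k = k, std_ratio = std_ratio), class = "icp_params")
}

median_nn_spacing <- function(xyz) {
  if (nrow(xyz) < 2) return(NA_real_)
  nn <- RANN::nn2(xyz, xyz, k = 2)
  stats::median(nn$nn.dists[, 2])
}

#' Translation-only iterative closest point
#'
#' Aligns `source` onto `target` by a pure translation: starting from
#' `t_init`, each iteration (1) shifts the source by the current translation,
#' (2) finds nearest-neighbour correspondences in the target (k-d tree),
#' rejecting pairs beyond the rejection radius, and (3) takes a
#' gradient-descent step on the RMS point-to-point cost with respect to the
#' translation only -- the closed-form gradient direction is the mean
#' residual vector of the accepted pairs, so a full step is a damped centroid
#' alignment. The rotation is never touched. Steps that would increase the
#' cost are rejected and retried with a halved step, making the cost
#' non-increasing. Stops when the RMS change drops below `tolerance`, the
#' step degenerates, or `max_iterations` is reached.
#'
#' @param source,target `point_cloud`s in the same (world) frame.
#' @param t_init Initial translation (length 3, m).
#' @param params An [icp_params()].
#' @param axes Logical length-3: which translation components may move
#'   (default all). The gradient is projected onto the allowed axes.
#' @param anneal Widen the rejection radius to `3 x` the current RMS while
#'   the alignment is still coarse (default TRUE). With `FALSE` the fixed
#'   floor is used throughout, which keeps far-apart structures from being
#'   dragged together but needs a reasonable initialisation.
#' @return A list of class `icp_result`: `t` (refined translation such that
#'   source + t aligns to target), `rms` (final RMS distance over accepted
#'   correspondences, m), `iterations`, `converged`, `rms_trace`.
#' @export
icp_translation <- function(source, target, t_init = c(0, 0, 0),
                            params = icp_params(),
                            axes = c(TRUE, TRUE, TRUE), anneal = TRUE) {
  stopifnot(nrow(source$xyz) > 0, nrow(target$xyz) > 0,
            all(is.finite(t_init)))
  floor_rej <- params$rejection_dist
  if (is.null(floor_rej))
    floor_rej <- 5 * median_nn_spacing(target$xyz)
  if (!is.finite(floor_rej) || floor_rej <= 0) floor_rej <- 0.01
  tr <- as.numeric(t_init)
  src <- source$xyz
  rms_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iter_used <- 0

  eval_cost <- function(tr) {
    shifted <- sweep(src, 2, tr, "+")
    nn <- RANN::nn2(target$xyz, shifted, k = 1)
    d <- nn$nn.dists[, 1]
    rej <- if (anneal) max(floor_rej, 3 * sqrt(mean(d^2))) else floor_rej
    acc <- d <= rej
    if (!any(acc)) return(NULL)
    resid <- target$xyz[nn$nn.idx[acc, 1], , drop = FALSE] -
      shifted[acc, , drop = FALSE]
    list(rms = sqrt(mean(d[acc]^2)), grad = colMeans(resid) * axes,
         n = sum(acc))
  }

  st <- eval_cost(tr)
  if (is.null(st))
    return(structure(list(t = tr, rms = NA_real_, iterations = 0L,
                          converged = FALSE, rms_trace = numeric(0),
                          message = "no correspondences under the rejection distance"),
                     class = "icp_result"))
  for (it in seq_len(params$max_iterations)) {
    iter_used <- it
    trace <- c(trace, st$rms)
    if (abs(rms_prev - st$rms) < params$tolerance) { converged <- TRUE; break }
    rms_prev <- st$rms
    step <- params$step_size
    advanced <- FALSE
    while (step > 1e-4) {
      cand <- tr + step * st$grad
      st2 <- eval_cost(cand)
      if (!is.null(st2) && st2$rms <= st$rms + 1e-15) {
        tr <- cand; st <- st2; advanced <- TRUE; break
      }
      step <- step / 2
    }
    if (!advanced) { converged <- TRUE; break }   # at a (local) optimum
  }
  structure(list(t = tr, rms = st$rms, iterations = iter_used,
                 converged = converged, rms_trace = trace,
                 n_correspondences = st$n),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf(
    "<icp_result: t = (%.4f, %.4f, %.4f) m, rms = %.5f m, %d iter, %s>\n",
    x$t[1], x$t[2], x$t[3], x$rms, x$iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Projective alignment polish of the registered opposite cloud against the
# initial view: (1) lateral -- the projected silhouette of the opposite shell
# must coincide with the initial mask (both are the object's silhouette for
# convex bodies), matched by mask centroids at sub-pixel precision;
# (2) depth -- over co-visible pixels the gap between the far (opposite) and
# near (initial) surface behaves like
#   gap(delta) = dz + c * sqrt(delta) [+ linear terms]
# where delta is the pixel's distance to the silhouette: both limbs coincide
# on the occluding contour, so the intercept of a regression of the gap on
# (1, sqrt(delta), delta) over the near-silhouette band estimates the depth
# misalignment dz directly, for curved limbs (sqrt profile) and edges
# (linear profile) alike. Returns the world-frame correction.
refine_projective <- function(cloud, d1, m1, k, iterations = 3,
                              band_px = 8, depth = TRUE) {
  xyz <- cloud$xyz
  tshift <- c(0, 0, 0)
  dz <- NA_real_
  a1 <- unclass(d1); a1[!m1] <- 0
  cent1 <- mask_centroid(m1)
  zbar <- stats::median(a1[m1])
  h <- nrow(a1)
  contour_idx <- which(mask_contour(m1))
  cont_uv <- cbind((contour_idx - 1L) %/% h, (contour_idx - 1L) %% h)
  for (it in seq_len(iterations)) {
    dB <- unclass(project(point_cloud(sweep(xyz, 2, tshift, "+"), "world"),
                          k))
    mB <- dB > 0
    if (!any(mB)) break
    centB <- mask_centroid(fill_mask_holes(mB))
    du <- cent1[1] - centB[1]; dv <- cent1[2] - centB[2]
    co_idx <- which(mB & a1 > 0)
    dz <- 0
    if (depth && length(co_idx) >= 50 && nrow(cont_uv) >= 8) {
      co_uv <- cbind((co_idx - 1L) %/% h, (co_idx - 1L) %% h)
      delta <- RANN::nn2(cont_uv, co_uv, k = 1)$nn.dists[, 1]
      # regression sectors: only where the opposite view's coverage extends
      # beyond the initial silhouette (wrap side), so its far surface truly
      # reaches the limb; where its own limb falls inside the mask the gap
      # profile terminates at mid-depth and would bias the intercept
      mBf <- fill_mask_holes(mB)
      contB <- which(mask_contour(mBf))
      contB_uv <- cbind((contB - 1L) %/% h, (contB - 1L) %% h)
      deltaB <- RANN::nn2(contB_uv, co_uv, k = 1)$nn.dists[, 1]
      sel <- delta <= band_px & deltaB >= delta + 1
      if (sum(sel) >= 30) {
        gap <- dB[co_idx[sel]] - a1[co_idx[sel]]
        X <- cbind(1, sqrt(delta[sel] + 0.5), delta[sel])
        fit <- stats::lm.fit(X, gap)
        res <- fit$residuals
        keep <- abs(res) <= 2.5 * stats::sd(res)    # trim mismatched pixels
        if (sum(keep) >= 30)
          fit <- stats::lm.fit(X[keep, , drop = FALSE], gap[keep])
        dz <- fit$coefficients[1]
        if (!is.finite(dz)) dz <- 0
      }
    }
    step <- c(du * zbar / k$fx, dv * zbar / k$fy, -dz)
    tshift <- tshift + step
    if (max(abs(step)) < 1e-4) break
  }
  list(t = tshift, dz_last = dz)
}

# most negative robust gap between the projected opposite surface and the
# initial surface (m); negative values mean the far shell pokes through the
# near one, which is physically impossible
interpenetration_depth <- function(cloud, d1, m1, k) {
  dB <- unclass(project(cloud, k))
  a1 <- unclass(d1); a1[!m1] <- 0
  co <- dB > 0 & a1 > 0
  if (sum(co) < 50) return(NA_real_)
  stats::quantile(dB[co] - a1[co], 0.002, names = FALSE)
}

# fill interior holes (zero-regions not connected to the border) of a mask
fill_mask_holes <- function(m) {
  lab <- .label_components_cpp(!m)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  out <- m | !(lab %in% border | lab == 0)
  dim(out) <- dim(m)
  out
}

mask_centroid <- function(m) {
  idx <- which(m)
  h <- nrow(m)
  c(mean((idx - 1L) %/% h), mean((idx - 1L) %% h))   # (u, v), 0-based
}

#' Two-view point cloud completion
#'
#' Fuses an initial-view depth image with its (synthesised or rendered)
#' opposite-view counterpart into a single world-frame cloud: both images are
#' hole-filled and masked, back-projected, the opposite cloud is registered
#' into the world (= initial camera) frame under the 180-degree rotation
#' model with translation `translation`, optionally refined by the
#' translation-only ICP, and the fused cloud is cleaned by statistical
#' outlier removal. The rotation applied to the opposite view is exactly
#' `rotation_about_y(180)` throughout; refinement adjusts the translation
#' only.
#'
#' @param initial_depth,opposite_depth `depth_image`s sharing `k`.
#' @param k An `intrinsics`.
#' @param translation Inter-camera translation estimate (m): ground truth or
#'   a prediction.
#' @param refine Run ICP refinement of the translation (default TRUE).
#' @param icp_on Run the ICP on the `"contours"` (silhouette rims of the two
#'   masks, the default) or on the `"full"` masked clouds. Rim-to-rim
#'   alignment is well-posed for two opposite-side surface shells, whose
#'   full-cloud point-to-point optimum degenerately collapses the shells
#'   onto each other along the viewing axis.
#' @param params An [icp_params()].
#' @param denoise_opposite Bilaterally smooth the opposite (synthesised)
#'   depth map before back-projection; the initial sensor map is never
#'   smoothed. Defaults to `refine`: the denoising/outlier preprocessing
#'   chain belongs to the ICP pipeline, while the known-extrinsics reference
#'   completion consumes the registered views as-is.
#' @param outlier_removal Apply statistical outlier removal to the fused
#'   cloud (defaults to `refine`, see above).
#' @param max_depth_correction Largest admissible ICP depth correction (m);
#'   larger moves indicate depth-degenerate silhouettes and are discarded.
#' @param background_depth Passed to [extract_object_mask()].
#' @return A world-frame `point_cloud` with attributes `translation` (the
#'   translation actually used, after refinement), `icp` (the `icp_result`
#'   when `refine`), `n_initial`, `n_opposite`, `removed`.
#' @export
complete_cloud <- function(initial_depth, opposite_depth, k, translation,
                           refine = TRUE, icp_on = c("contours", "full"),
                           params = icp_params(), denoise_opposite = refine,
                           outlier_removal = refine,
                           max_depth_correction = 0.05,
                           background_depth = NULL) {
  stopifnot(all(is.finite(translation)), length(translation) == 3)
  icp_on <- match.arg(icp_on)
  d1 <- fill_depth_holes(initial_depth)
  d2_raw <- fill_depth_holes(opposite_depth)
  d2 <- if (denoise_opposite)
    bilateral_smooth(d2_raw, radius = 4, sigma_spatial = 2.5, passes = 2)
  else d2_raw
  m1 <- extract_object_mask(d1, background_depth)
  m2 <- extract_object_mask(d2, background_depth)
  c1 <- back_project(d1, k, m1, frame = "initial_camera")
  c1 <- point_cloud(c1$xyz, "world")     # world frame == initial camera frame
  c2 <- back_project(d2, k, m2, frame = "opposite_camera")
  ry <- rotation_about_y(180)
  tr <- as.numeric(translation)
  c2w <- register_to_world(c2, rigid_pose(ry, tr))
  icp <- NULL
  if (refine) {
    if (icp_on == "contours") {
      # Rim-to-rim alignment on tangent-corrected contours, fitted on the
      # unsmoothed maps (noise averages out along the contour, smoothing
      # would bias the grazing profile). Pass 1 refines the lateral axes
      # using the whole rims, seeded by the closed-form rim-centroid offset.
      # Pass 2 refines depth using only rim points with a clear square-root
      # falloff: those lie on true occluding contours, which opposite views
      # share; flat-profile rim points sit on face-boundary edges (the front
      # face for one camera, the back face for the other) and carry no
      # common depth.
      rim2 <- rim_tangent_cloud(d2_raw, m2, k)
      rim1 <- rim_tangent_cloud(d1, m1, k)
      src <- register_to_world(rim2, rigid_pose(ry, tr))
      tgt <- point_cloud(rim1$xyz, "world")
      curved_frac <- min(mean(attr(rim1, "slope") >= 0.003),
                         mean(attr(rim2, "slope") >= 0.003))
      # lateral pass on the xy-flattened rims: the two contours are
      # congruent laterally, and flattening keeps their (possibly
      # misaligned) depth structure from contaminating the xy match
      flat <- function(pc) point_cloud(cbind(pc$xyz[, 1:2], 0), "world")
      t0 <- c((colMeans(tgt$xyz) - colMeans(src$xyz))[1:2], 0)
      icp <- icp_translation(flat(src), flat(tgt), t_init = t0,
                             params = params, axes = c(TRUE, TRUE, FALSE))
      # depth pass on the rims, gated twice against depth-degenerate
      # geometry: (1) mostly flat rim profiles mean the silhouettes bound
      # the near/far faces (no shared occluding contour), so depth is left
      # at the prediction; (2) a correction far beyond the expected
      # prediction error likewise indicates degeneracy and is rejected.
      # Iterated once more because large offsets converge only partway.
      depth_total <- 0
      for (zpass in 1:2) {
        srcz <- point_cloud(sweep(src$xyz, 2, icp$t, "+"), "world")
        icpz <- icp_translation(srcz, tgt, t_init = c(0, 0, 0),
                                params = params,
                                axes = c(FALSE, FALSE, TRUE))
        ok <- curved_frac >= 0.4 && is.finite(icpz$t[3]) &&
          abs(depth_total + icpz$t[3]) <= max_depth_correction
        if (!ok) break
        icp$t <- icp$t + icpz$t
        depth_total <- depth_total + icpz$t[3]
        icp$rms <- icpz$rms
        if (abs(icpz$t[3]) < 1e-4) break
      }
      if (depth_total == 0) {
        # fallback for gated/rejected depth passes: unless the pose is
        # exactly face-on, both clouds contain grazing side-surface points
        # spanning the object's full depth, so aligning their robust near
        # and far z-extents recovers the depth offset; the extents of the
        # two clouds must agree for the estimate to be valid
        zb <- sweep(c2w$xyz, 2, icp$t, "+")[, 3]
        za <- c1$xyz[, 3]
        qa <- stats::quantile(za, c(0.005, 0.995), names = FALSE)
        qb <- stats::quantile(zb, c(0.005, 0.995), names = FALSE)
        ea <- qa[2] - qa[1]; eb <- qb[2] - qb[1]
        dzf <- mean(qa - qb)
        if (ea > 0.015 && abs(ea - eb) < 0.2 * max(ea, eb) &&
            is.finite(dzf) && abs(dzf) <= max_depth_correction) {
          icp$t[3] <- icp$t[3] + dzf
          depth_total <- dzf
        }
      }
      icp$stages <- list(depth = depth_total)
      # one-sided sanity clamp: the opposite surface can touch but never
      # cross the initial surface along a shared ray
      pen <- interpenetration_depth(
        point_cloud(sweep(c2w$xyz, 2, icp$t, "+"), "world"), d1, m1, k)
      if (is.finite(pen) && pen < -0.003)
        icp$t[3] <- icp$t[3] - (pen + 0.003)
    } else {
      src <- c2w
      tgt <- c1
      icp <- icp_translation(src, tgt, t_init = c(0, 0, 0), params = params)
    }
    c2w <- point_cloud(sweep(c2w$xyz, 2, icp$t, "+"), "world")
    # world-frame shift delta corresponds to camera translation t - Ry %*% delta
    tr <- tr - as.numeric(ry %*% icp$t)
  }
  fused <- point_cloud(rbind(c1$xyz, c2w$xyz), "world")
  out <- if (outlier_removal)
    remove_outliers(fused, k = params$k, std_ratio = params$std_ratio)
  else fused
  attr(out, "translation") <- tr
  attr(out, "icp") <- icp
  attr(out, "n_initial") <- nrow(c1$xyz)
  attr(out, "n_opposite") <- nrow(c2$xyz)
  out
}
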