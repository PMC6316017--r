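#' Pose-sampling configuration for paired depth views
#'
#' Ranges of the extrinsic camera parameters from which initial/opposite view
#' pairs are drawn. The defaults are the study conditions: initial azimuth
#' 0-360 deg, elevation 90-270 deg (a polar sweep placing the initial camera
#' anywhere in the upper viewing hemisphere, including horizontal), camera
#' distance ("height") 0.5-0.6 m with lateral centre shifts of +-0.1 m in the
#' camera's own x/y; the opposite camera mirrors the axis (elevation + 180
#' deg, height -0.5 to -0.6 m) with its own independent shift draw.
#'
#' @param azimuth,elevation Degree ranges (length-2) for the initial view.
#' @param height Metre range of the initial camera distance along the view
#'   axis.
#' @param shift_x,shift_y Metre ranges of the lateral camera offsets.
#' @param opp_height Metre range (negative) of the opposite camera's signed
#'   distance along the same axis.
#' @return A list of class `view_config`.
#' @export
view_config <- function(azimuth = c(0, 360), elevation = c(90, 270),
                        height = c(0.5, 0.6), shift_x = c(-0.1, 0.1),
                        shift_y = c(-0.1, 0.1), opp_height = c(-0.6, -0.5)) {
  for (r in list(azimuth, elevation, height, shift_x, shift_y, opp_height))
    if (length(r) != 2 || r[1] > r[2])
      stop("each range must be c(min, max) with min <= max")
  structure(list(azimuth = azimuth, elevation = elevation, height = height,
                 shift_x = shift_x, shift_y = shift_y,
                 opp_height = opp_height), class = "view_config")
}

# viewing axis: unit vector from the object origin towards the initial
# camera. Azimuth about the lab vertical; elevation is a polar sweep with 90
# and 270 deg horizontal and 180 deg straight above.
view_axis <- function(azimuth_deg, elevation_deg) {
  a <- azimuth_deg * pi / 180; e <- elevation_deg * pi / 180
  c(sin(e) * cos(a), -cos(e), sin(e) * sin(a))
}

# camera basis with x right / y down / z forward (towards the object);
# y chosen as the projection of lab "down" onto the image plane
camera_rotation <- function(axis_to_camera) {
  z <- -axis_to_camera / sqrt(sum(axis_to_camera^2))
  down <- c(0, -1, 0)
  y <- down - sum(down * z) * z
  ny <- sqrt(sum(y^2))
  if (ny < 1e-9) {          # looking straight up/down: pick a stable fallback
    y <- c(0, 0, 1) - sum(c(0, 0, 1) * z) * z
    ny <- sqrt(sum(y^2))
  }
  y <- y / ny
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  rbind(x, y, z, deparse.level = 0)   # rows = camera basis in lab coords
}

#' Sample an initial/opposite camera pose pair
#'
#' Draws one set of extrinsic parameters uniformly from a [view_config()] and
#' returns the two camera poses (lab frame, convention `p_c = R p_l + t`)
#' together with the ground-truth inter-camera translation `t_gt` of the
#' fusion model: a point expressed in the opposite camera's frame maps into
#' the initial camera's frame as
#' `p_init = Ry(180)^{-1} (p_opp - t_gt)`.
#' The opposite camera's orientation is exactly `rotation_about_y(180)`
#' composed with the initial camera's (the 180-degree model); its centre sits
#' on the far side of the object along the same viewing axis at the sampled
#' (negative) height, plus its own lateral shift.
#'
#' @param config A [view_config()].
#' @param opposite_shift `"independent"` (default): the opposite camera
#'   draws its own lateral shift, the harder registration setting used by
#'   the volume-estimation protocol; `"mirrored"`: one centre-shifting
#'   movement applies to the pair (the opposite camera reuses the initial
#'   draw in its own axes), which makes the opposite view a deterministic
#'   function of the initial one -- the setting for view-synthesis
#'   training, where an independently shifted target would be
#'   unpredictable in principle.
#' @return A list with `initial`, `opposite` (both `rigid_pose`), `t_gt`
#'   (length-3, metres) and `params` (the drawn scalars). Uses the R RNG;
#'   seed with [set.seed()] for reproducibility.
#' @export
sample_pose_pair <- function(config = view_config(),
                             opposite_shift = c("independent", "mirrored")) {
  opposite_shift <- match.arg(opposite_shift)
  draw <- function(r) stats::runif(1, r[1], r[2])
  az <- draw(config$azimuth)
  el <- draw(config$elevation)
  hgt <- draw(config$height)
  s1 <- c(draw(config$shift_x), draw(config$shift_y))
  s2 <- if (opposite_shift == "independent")
    c(draw(config$shift_x), draw(config$shift_y)) else s1
  hopp <- draw(config$opp_height)

  u <- view_axis(az, el)
  R1 <- camera_rotation(u)                       # initial camera
  C1 <- hgt * u + s1[1] * R1[1, ] + s1[2] * R1[2, ]
  R2 <- rotation_about_y(180) %*% R1             # opposite camera
  C2 <- hopp * u + s2[1] * R2[1, ] + s2[2] * R2[2, ]
  pose1 <- rigid_pose(R1, -as.numeric(R1 %*% C1))
  pose2 <- rigid_pose(R2, -as.numeric(R2 %*% C2))
  # relative model: p_opp = Ry(180) p_init + t_gt
  t_gt <- as.numeric(pose2$t - rotation_about_y(180) %*% pose1$t)
  list(initial = pose1, opposite = pose2, t_gt = t_gt,
       params = list(azimuth = az, elevation = el, height = hgt,
                     shift_init = s1, shift_opp = s2, opp_height = hopp))
}

#' Render a depth image of a triangle mesh
#'
#' Per-pixel ray casting against a bounding-volume hierarchy: each pixel ray
#' leaves the camera centre through `((u - cx)/fx, (v - cy)/fy, 1)` and the
#' pixel value is the camera-Z depth of the first intersection (0 where the
#' ray misses). Deterministic; an empty mesh yields an all-zero image.
#'
#' @param mesh A `trimesh` in lab coordinates (metres).
#' @param pose A `rigid_pose` mapping lab points into the camera frame.
#' @param k An `intrinsics`.
#' @param quantize_mm Round depths to whole millimetres (the storage
#'   resolution of the dataset PNGs), so in-memory pipelines match what a
#'   written-and-reread image would contain. Default TRUE.
#' @return A `depth_image`.
#' @export
render_depth <- function(mesh, pose, k, quantize_mm = TRUE) {
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0)
    return(depth_image(matrix(0, k$height, k$width)))
  vc <- sweep(mesh$vertices %*% t(pose$R), 2, pose$t, "+")
  d <- .render_depth_cpp(vc, mesh$faces, k$fx, k$fy, k$cx, k$cy,
                         k$width, k$height)
  if (quantize_mm) d <- round(d * 1000) / 1000
  depth_image(d)
}

#' Render one initial/opposite depth pair
#'
#' Convenience wrapper: samples a pose pair and renders both views.
#'
#' @param mesh A `trimesh`.
#' @param k An `intrinsics`.
#' @param config A [view_config()].
#' @param quantize_mm See [render_depth()].
#' @return A list of class `render_sample`: `initial`, `opposite`
#'   (depth images), `t_gt`, `poses`, `params`.
#' @export
render_pair <- function(mesh, k = default_intrinsics(),
                        config = view_config(), quantize_mm = TRUE,
                        opposite_shift = "independent") {
  pp <- sample_pose_pair(config, opposite_shift)
  structure(list(
    initial = render_depth(mesh, pp$initial, k, quantize_mm),
    opposite = render_depth(mesh, pp$opposite, k, quantize_mm),
    t_gt = pp$t_gt, poses = pp[c("initial", "opposite")],
    params = pp$params), class = "render_sample")
}

#' Render a dataset of depth-image pairs to disk
#'
#' Writes `n_pairs_per_object` initial/opposite pairs per object under
#' `out_dir/<object>/<trial>_init.png`, `<trial>_opp.png` and
#' `<trial>.json` (pose parameters and ground-truth translation), plus a
#' JSON-lines `index.jsonl` listing every sample. Fully reproducible from
#' `seed`.
#'
#' @param meshes Named list of `trimesh` objects.
#' @param n_pairs_per_object Pairs per object (>= 1).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param k An `intrinsics`.
#' @param config A [view_config()].
#' @return Data frame index of the written samples (object, trial, paths,
#'   seed), invisibly also written as `index.jsonl`.
#' @export
build_dataset <- function(meshes, n_pairs_per_object, seed, out_dir,
                          k = default_intrinsics(), config = view_config()) {
  stopifnot(n_pairs_per_object >= 1, length(names(meshes)) == length(meshes))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (obj in names(meshes)) {
    odir <- file.path(out_dir, obj)
    dir.create(odir, showWarnings = FALSE)
    for (trial in seq_len(n_pairs_per_object)) {
      trial_seed <- (seed + 7919 * match(obj, names(meshes)) + trial) %%
        .Machine$integer.max
      set.seed(trial_seed)
      s <- render_pair(meshes[[obj]], k, config)
      pi_ <- file.path(odir, sprintf("%05d_init.png", trial))
      po <- file.path(odir, sprintf("%05d_opp.png", trial))
      write_depth_png(s$initial, pi_, k, s$poses$initial)
      write_depth_png(s$opposite, po, k, s$poses$opposite)
      jsonlite::write_json(
        list(object = obj, trial = trial, seed = trial_seed,
             t_gt = s$t_gt, params = s$params),
        file.path(odir, sprintf("%05d.json", trial)),
        auto_unbox = TRUE, digits = NA)
      rows[[length(rows) + 1]] <- data.frame(
        object = obj, trial = trial, init = pi_, opp = po,
        meta = file.path(odir, sprintf("%05d.json", trial)),
        seed = trial_seed, stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, rows)
  writeLines(vapply(seq_len(nrow(index)), function(i)
    jsonlite::toJSON(as.list(index[i, ]), auto_unbox = TRUE, digits = NA),
    character(1)), file.path(out_dir, "index.jsonl"))
  index
}

#' Holdout split of a dataset index
#'
#' Shuffles the index with `seed` and partitions it into train / validation /
#' test sets. Sizes are the floor of `fractions * n`, with every remainder
#' row assigned to the training set, so the three parts are disjoint and
#' exhaustive.
#'
#' @param index Data frame (or anything with rows) to split.
#' @param fractions Length-3 numeric summing to 1 (train, validation, test).
#' @param seed Integer seed for the shuffle.
#' @return List with `train`, `validation`, `test` subsets of `index`.
#' @examples
#' holdout_sizes <- vapply(holdout_split(data.frame(i = 1:10), seed = 1),
#'                         nrow, integer(1))  # 7, 1, 2
#' @export
holdout_split <- function(index, fractions = c(0.7, 0.1, 0.2), seed = 1) {
  n <- nrow(index)
  if (is.null(n) || n == 0) stop("cannot split an empty index")
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(seed)
  ord <- sample.int(n)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test     # floor + remainder to train
  list(train = index[ord[seq_len(n_train)], , drop = FALSE],
       validation = index[ord[n_train + seq_len(n_val)], , drop = FALSE],
       test = index[ord[n_train + n_val + seq_len(n_test)], , drop = FALSE])
}
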