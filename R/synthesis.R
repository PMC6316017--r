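#' View-synthesis training loss
#'
#' The cost of a predicted opposite-view depth image and inter-camera
#' translation against ground truth:
#' \deqn{\sum_{u,v} (\tilde d(u,v) - d(u,v))^2 + \lambda \|\tilde t - t\|^2}
#' The pixel term is an unnormalised sum of squared differences over all
#' pixels (a `per_pixel` toggle divides by the pixel count for
#' cross-resolution comparability); the translation term is weighted by the
#' regularisation constant `lambda` (default 1e-3). Zero if and only if both
#' predictions are exact.
#'
#' @param d_pred,d_true Depth images of identical shape.
#' @param t_pred,t_true Length-3 translations (m); omit both to score a
#'   depth-only model.
#' @param lambda Translation weight.
#' @param per_pixel Divide the pixel term by the number of pixels.
#' @return Non-negative scalar.
#' @export
synthesis_loss <- function(d_pred, d_true, t_pred = NULL, t_true = NULL,
                           lambda = 1e-3, per_pixel = FALSE) {
  if (!identical(dim(unclass(d_pred)), dim(unclass(d_true))))
    stop("depth images must have the same shape")
  px <- sum((unclass(d_pred) - unclass(d_true))^2)
  if (per_pixel) px <- px / length(d_pred)
  tt <- 0
  if (!is.null(t_pred) || !is.null(t_true)) {
    if (is.null(t_pred) || is.null(t_true))
      stop("provide both translations or neither")
    tt <- lambda * sum((as.numeric(t_pred) - as.numeric(t_true))^2)
  }
  px + tt
}

#' Geometric oracle for opposite-view synthesis
#'
#' Stands in for a trained network so the completion and volumetry stages can
#' be exercised in isolation: the opposite view is rendered from the mesh at
#' the true opposite pose, then corrupted with i.i.d. Gaussian depth noise
#' (valid pixels only, clipped at zero), and the ground-truth inter-camera
#' translation is perturbed with per-axis Gaussian noise. With both noise
#' levels at zero the prediction is exact.
#'
#' @param mesh A `trimesh`.
#' @param pose_pair A pose pair from [sample_pose_pair()] (fields `opposite`,
#'   `t_gt`).
#' @param k An `intrinsics`.
#' @param depth_noise_sd Depth noise SD in metres (>= 0).
#' @param translation_noise_sd Per-axis translation noise SD in metres (>= 0).
#' @param quantize_mm Passed to [render_depth()].
#' @return A list of class `prediction`: `depth` (a `depth_image`),
#'   `translation` (length 3). Uses the R RNG.
#' @export
oracle_synthesize <- function(mesh, pose_pair, k, depth_noise_sd = 0,
                              translation_noise_sd = 0, quantize_mm = TRUE) {
  stopifnot(depth_noise_sd >= 0, translation_noise_sd >= 0)
  d <- render_depth(mesh, pose_pair$opposite, k, quantize_mm)
  if (depth_noise_sd > 0) {
    valid <- d > 0
    noise <- stats::rnorm(sum(valid), 0, depth_noise_sd)
    d[valid] <- pmax(d[valid] + noise, 0)
  }
  t_pred <- pose_pair$t_gt
  if (translation_noise_sd > 0)
    t_pred <- t_pred + stats::rnorm(3, 0, translation_noise_sd)
  structure(list(depth = depth_image(unclass(d)), translation = t_pred),
            class = "prediction")
}
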