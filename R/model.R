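#' View-synthesis model configuration
#'
#' Settings for the opposite-view depth prediction network. The encoder
#' downsamples by a factor of 16, so the input resolution must be divisible
#' by 16. Defaults target the reduced study resolution of 64x64; at full
#' 480x640 the same architecture applies with proportionally wider layers.
#'
#' @param input_h,input_w Input resolution in pixels.
#' @param latent Latent vector width.
#' @param inception_kernels Kernel sizes of the parallel inception branches.
#' @param lambda Translation regularisation weight of the loss (> 0).
#' @param iterations Training iteration budget.
#' @param lr Adam learning rate.
#' @param batch Mini-batch size.
#' @param seed RNG seed for weight initialisation and batch sampling.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(input_h = 64, input_w = 64, latent = 128,
                         inception_kernels = c(3, 5, 7), lambda = 1e-3,
                         iterations = 300, lr = 1e-3, batch = 16, seed = 1) {
  stopifnot(lambda > 0, iterations >= 1, lr > 0, batch >= 1)
  if (input_h %% 16 != 0 || input_w %% 16 != 0)
    stop("input resolution must be divisible by 16 (four stride-2 stages)")
  structure(list(input_h = input_h, input_w = input_w, latent = latent,
                 inception_kernels = inception_kernels, lambda = lambda,
                 iterations = iterations, lr = lr, batch = batch,
                 seed = seed), class = "synth_config")
}

#' Build a view-synthesis model
#'
#' Two variants of the depth-to-depth encoder-decoder:
#' \describe{
#'   \item{naive}{plain convolutional encoder to a latent vector, then a
#'     transposed-convolution decoder; depth output only.}
#'   \item{inception_extrinsic}{two inception blocks (parallel convolutions
#'     with the configured kernel sizes, concatenated) in front of the same
#'     encoder, plus a second head predicting the inter-camera translation
#'     from the latent vector.}
#' }
#' Weight initialisation uses the config seed; a forward pass is
#' deterministic given fixed weights.
#'
#' @param config A [synth_config()].
#' @param variant `"naive"` or `"inception_extrinsic"`.
#' @return A list of class `synth_model` with `encoder`, `decoder`,
#'   `t_head` (inception variant), `config`, `variant`, `n_params`.
#' @export
build_model <- function(config = synth_config(),
                        variant = c("naive", "inception_extrinsic")) {
  variant <- match.arg(variant)
  set.seed(config$seed)
  h <- config$input_h; w <- config$input_w
  hb <- h %/% 16; wb <- w %/% 16
  enc_tail <- list(
    layer_conv(9, 12, 3, 2, 1),
    layer_conv(12, 16, 3, 2, 1),
    layer_conv(16, 24, 3, 2, 1),
    layer_fc(hb * wb * 24, config$latent))
  if (variant == "inception_extrinsic") {
    nk <- length(config$inception_kernels)
    ch <- ceiling(9 / nk)
    head <- list(
      layer_inception(1, ch, config$inception_kernels, 2),
      layer_inception(ch * nk, ch, config$inception_kernels, 1,
                      reduce = 3))
    enc_tail[[1]]$cin <- ch * nk
    enc_tail[[1]]$W <- he_init(12, 9 * ch * nk)
  } else {
    head <- list(
      layer_conv(1, 9, 3, 2, 1),
      layer_conv(9, 9, 3, 1, 1))
  }
  encoder <- c(head, enc_tail)
  decoder <- list(
    layer_fc(config$latent, hb * wb * 24),
    layer_tconv(24, 16, 4, 2, 1),
    layer_tconv(16, 12, 4, 2, 1),
    layer_tconv(12, 8, 4, 2, 1),
    layer_tconv(8, 1, 4, 2, 1, act = "relu"))
  t_head <- if (variant == "inception_extrinsic")
    list(layer_fc(config$latent, 3, act = "linear")) else NULL
  id <- 0
  tag <- function(ls) lapply(ls, function(l) { id <<- id + 1; l$id <- id; l })
  encoder <- tag(encoder); decoder <- tag(decoder)
  if (!is.null(t_head)) t_head <- tag(t_head)
  np <- sum(vapply(c(encoder, decoder, t_head), function(l) {
    if (l$type == "inception")
      sum(vapply(l$branches, function(b)
        sum(lengths(b[intersect(c("W", "b", "Wr", "br"), names(b))])), 0))
    else length(l$W) + length(l$b)
  }, 0))
  structure(list(encoder = encoder, decoder = decoder, t_head = t_head,
                 config = config, variant = variant, n_params = np,
                 decoder_in = c(hb, wb, 24)),
            class = "synth_model")
}

#' @export
print.synth_model <- function(x, ...) {
  cat(sprintf("<synth_model '%s': %d parameters, %dx%d input>\n",
              x$variant, x$n_params, x$config$input_h, x$config$input_w))
  invisible(x)
}

seq_forward <- function(layers, x, B, cache_env) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_forward_layer(layers[[i]], x, B, cache_env)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- nn_backward_layer(layers[[i]], dout, caches[[i]])
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

model_forward <- function(model, x, cache_env, with_cache = FALSE) {
  B <- dim(x)[4]
  enc <- seq_forward(model$encoder, x, B, cache_env)
  latent <- enc$out
  # decoder: fc latent -> feature grid, then the deconvolution stack
  fcr <- nn_forward_layer(model$decoder[[1]], latent, B, cache_env)
  grid <- array(fcr$out, c(model$decoder_in, B))
  dec <- seq_forward(model$decoder[-1], grid, B, cache_env)
  th <- if (!is.null(model$t_head))
    seq_forward(model$t_head, latent, B, cache_env) else NULL
  out <- list(depth = dec$out,
              translation = if (!is.null(th)) th$out else NULL)
  if (with_cache) out$caches <- list(enc = enc, dec = dec, fc = fcr$cache,
                                     th = th)
  out
}

# batch loss and parameter gradients for Eq.-style cost: per-sample pixel SSD
# plus lambda * squared translation error, averaged over the batch
model_loss_grad <- function(model, x, y, t_true, cache_env) {
  B <- dim(x)[4]
  fw <- model_forward(model, x, cache_env, with_cache = TRUE)
  resid <- fw$depth - y
  loss_px <- sum(resid^2) / B
  loss_t <- 0
  dlat_t <- NULL
  gt <- NULL
  if (!is.null(model$t_head)) {
    dt <- fw$translation - t(t_true)
    loss_t <- model$config$lambda * sum(dt^2) / B
    bt <- seq_backward(model$t_head, 2 * model$config$lambda * dt / B,
                       fw$caches$th$caches)
    dlat_t <- bt$dx
    gt <- bt$grads
  }
  bd <- seq_backward(model$decoder[-1], 2 * resid / B, fw$caches$dec$caches)
  dgrid <- matrix(bd$dx, prod(model$decoder_in), B)
  bfc <- nn_backward_layer(model$decoder[[1]], dgrid, fw$caches$fc)
  dlat <- bfc$dx
  if (!is.null(dlat_t)) dlat <- dlat + dlat_t
  be <- seq_backward(model$encoder, dlat, fw$caches$enc$caches)
  list(loss = loss_px + loss_t, loss_px = loss_px,
       grads = list(encoder = be$grads,
                    decoder = c(list(bfc$grads), bd$grads), t_head = gt))
}

# evaluate the mean per-sample loss over an index set without gradients
model_eval_loss <- function(model, data, idx, cache_env, pixel_only = FALSE) {
  cfg <- model$config
  tot <- 0
  for (start in seq(1, length(idx), by = cfg$batch)) {
    ii <- idx[start:min(start + cfg$batch - 1, length(idx))]
    x <- data$x[, , , ii, drop = FALSE]
    fw <- model_forward(model, x, cache_env)
    resid <- fw$depth - data$y[, , , ii, drop = FALSE]
    tot <- tot + sum(resid^2)
    if (!pixel_only && !is.null(fw$translation)) {
      dt <- fw$translation - t(data$t[ii, , drop = FALSE])
      tot <- tot + cfg$lambda * sum(dt^2)
    }
  }
  tot / length(idx)
}

apply_grads <- function(layers, grads, states, lr, t) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]; s <- states[[i]]
    if (l$type == "inception") {
      for (j in seq_along(l$branches)) {
        for (pn in intersect(c("W", "b", "Wr", "br"),
                             names(l$branches[[j]]))) {
          if (is.null(g$branches[[j]][[pn]])) next
          up <- adam_update(l$branches[[j]][[pn]], g$branches[[j]][[pn]],
                            s$branches[[j]][[pn]], lr, t)
          l$branches[[j]][[pn]] <- up$param
          s$branches[[j]][[pn]] <- up$state
        }
      }
    } else {
      up <- adam_update(l$W, g$W, s$W, lr, t)
      l$W <- up$param; s$W <- up$state
      up <- adam_update(l$b, g$b, s$b, lr, t)
      l$b <- up$param; s$b <- up$state
    }
    layers[[i]] <- l; states[[i]] <- s
  }
  list(layers = layers, states = states)
}

#' Train a view-synthesis model
#'
#' Mini-batch Adam on the synthesis loss. Training is deterministic given
#' the config seed (single-threaded BLAS assumed). Divergence (non-finite
#' loss) aborts with a diagnostic.
#'
#' @param model A `synth_model` from [build_model()].
#' @param data Training data: list with `x` (input depth array
#'   `[H, W, 1, N]`), `y` (target opposite depth, same shape) and `t`
#'   (N x 3 ground-truth translations). See [render_training_set()].
#' @param split Optional list of index vectors `train`, `validation`,
#'   `test` (defaults to a 70/10/20 holdout on the sample index).
#' @param val_every Validation cadence in iterations.
#' @return The trained model -- the best-validation checkpoint seen during
#'   the run (early stopping) -- with `history` (data frame of iteration,
#'   training-batch loss, validation loss), `initial_val_loss` and
#'   `final_val_loss` attached.
#' @export
train_model <- function(model, data, split = NULL, val_every = 25) {
  cfg <- model$config
  n <- dim(data$x)[4]
  if (is.null(split)) {
    split <- holdout_split(data.frame(i = seq_len(n)), seed = cfg$seed)
    split <- lapply(split, function(s) s$i)
  }
  cache_env <- new.env(parent = emptyenv())
  states <- list(encoder = adam_init(model$encoder),
                 decoder = adam_init(model$decoder),
                 t_head = if (!is.null(model$t_head))
                   adam_init(model$t_head))
  set.seed(cfg$seed + 1)
  hist <- list()
  val0 <- model_eval_loss(model, data, split$validation, cache_env)
  best_val <- val0
  best_model <- model
  for (it in seq_len(cfg$iterations)) {
    ii <- sample(split$train, cfg$batch, replace = cfg$batch >
                   length(split$train))
    lg <- model_loss_grad(model,
                          data$x[, , , ii, drop = FALSE],
                          data$y[, , , ii, drop = FALSE],
                          data$t[ii, , drop = FALSE], cache_env)
    if (!is.finite(lg$loss))
      stop(sprintf("training diverged at iteration %d (loss = %g)",
                   it, lg$loss))
    up <- apply_grads(model$encoder, lg$grads$encoder, states$encoder,
                      cfg$lr, it)
    model$encoder <- up$layers; states$encoder <- up$states
    up <- apply_grads(model$decoder, lg$grads$decoder, states$decoder,
                      cfg$lr, it)
    model$decoder <- up$layers; states$decoder <- up$states
    if (!is.null(model$t_head)) {
      up <- apply_grads(model$t_head, lg$grads$t_head, states$t_head,
                        cfg$lr, it)
      model$t_head <- up$layers; states$t_head <- up$states
    }
    if (it %% val_every == 0 || it == cfg$iterations) {
      vl <- model_eval_loss(model, data, split$validation, cache_env)
      hist[[length(hist) + 1]] <- data.frame(iteration = it,
                                             train_loss = lg$loss,
                                             val_loss = vl)
      if (vl < best_val) {
        best_val <- vl
        best_model <- model
      }
    }
  }
  history <- do.call(rbind, hist)
  # early stopping: the returned model is the best-validation checkpoint
  model <- best_model
  attr(model, "history") <- rbind(
    data.frame(iteration = 0, train_loss = NA_real_, val_loss = val0),
    history)
  attr(model, "initial_val_loss") <- val0
  attr(model, "final_val_loss") <- best_val
  attr(model, "split") <- split
  model
}

#' Predict the opposite view for a single depth image
#'
#' @param model A trained `synth_model`.
#' @param depth A `depth_image` at the model's input resolution.
#' @return A `prediction`: `depth` (non-negative `depth_image`) and
#'   `translation` (length 3, or NULL for the naive variant).
#' @export
predict_model <- function(model, depth) {
  cfg <- model$config
  if (nrow(depth) != cfg$input_h || ncol(depth) != cfg$input_w)
    stop("input resolution does not match the model")
  x <- array(unclass(depth), c(cfg$input_h, cfg$input_w, 1, 1))
  cache_env <- new.env(parent = emptyenv())
  fw <- model_forward(model, x, cache_env)
  structure(list(depth = depth_image(matrix(fw$depth[, , 1, 1],
                                            cfg$input_h, cfg$input_w)),
                 translation = if (!is.null(fw$translation))
                   as.numeric(fw$translation[, 1])),
            class = "prediction")
}

#' Save and load model checkpoints
#'
#' A checkpoint is an RDS file holding the full model (weights, config,
#' variant) plus its training history; `write_history()` exports the loss
#' curves as CSV.
#'
#' @param model A `synth_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "synth_model")) stop("not a synth_model checkpoint")
  model
}

#' @rdname save_model
#' @param csv Output CSV path for the loss curves.
#' @export
write_history <- function(model, csv) {
  h <- attr(model, "history")
  if (is.null(h)) stop("model has no training history")
  utils::write.csv(h, csv, row.names = FALSE)
  invisible(csv)
}

#' Render an in-memory training set of depth pairs
#'
#' Draws `n_pairs` pose pairs for one mesh and renders both views at the
#' given intrinsics, returning arrays ready for [train_model()].
#'
#' @param mesh A `trimesh`.
#' @param n_pairs Number of pairs.
#' @param k An `intrinsics` (use a 16-divisible resolution).
#' @param config A [view_config()].
#' @param seed Integer seed.
#' @return List with `x`, `y` (`[H, W, 1, n]` arrays) and `t` (n x 3).
#' @export
render_training_set <- function(mesh, n_pairs, k, config = view_config(),
                                seed = 1,
                                opposite_shift = "mirrored") {
  set.seed(seed)
  x <- array(0, c(k$height, k$width, 1, n_pairs))
  y <- array(0, c(k$height, k$width, 1, n_pairs))
  tm <- matrix(0, n_pairs, 3)
  for (i in seq_len(n_pairs)) {
    s <- render_pair(mesh, k, config, opposite_shift = opposite_shift)
    x[, , 1, i] <- unclass(s$initial)
    y[, , 1, i] <- unclass(s$opposite)
    tm[i, ] <- s$t_gt
  }
  list(x = x, y = y, t = tm)
}
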