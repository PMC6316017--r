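# Minimal convolutional network engine (im2col on BLAS, hand-written
# backprop, Adam). Activations are [H, W, C, B] arrays; weights of a
# convolution with kernel k and C_in -> C_out channels are stored as a
# (C_out x k*k*C_in) matrix so forward/backward are single matrix products.

# gather/scatter geometry of a conv that reads an [H, W, C, B] array with
# kernel k, stride s, zero padding p
conv_geom <- function(H, W, C, k, s, p, B) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  # 0-based offsets of kernel taps within the padded array
  kk <- expand.grid(ki = 0:(k - 1), kj = 0:(k - 1), c = 0:(C - 1))
  row_off <- kk$ki + Hp * kk$kj + Hp * Wp * kk$c
  pos <- expand.grid(i = 0:(Ho - 1), j = 0:(Wo - 1))
  pos_off <- pos$i * s + Hp * (pos$j * s)
  batch_off <- Hp * Wp * C * (0:(B - 1))
  cols <- as.numeric(outer(pos_off, batch_off, "+"))     # npos*B
  idx <- outer(row_off, cols, "+") + 1                   # (k2C) x (npos*B)
  list(H = H, W = W, C = C, k = k, s = s, p = p, B = B,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
       idx = idx, row_off = row_off, col_idx = cols + 1)
}

pad_input <- function(x, g) {
  if (g$p == 0L) return(x)
  xp <- array(0, c(g$Hp, g$Wp, g$C, g$B))
  xp[g$p + seq_len(g$H), g$p + seq_len(g$W), , ] <- x
  xp
}

unpad_grad <- function(dxp, g) {
  if (g$p == 0L) return(dxp)
  dxp[g$p + seq_len(g$H), g$p + seq_len(g$W), , , drop = FALSE]
}

# col matrix (k2C x npos*B) from an input array. The index is flattened
# before use: a matrix subscript whose width equals the array's rank would
# otherwise be read as per-row coordinates.
conv_gather <- function(x, g) {
  xp <- pad_input(x, g)
  col <- xp[as.vector(g$idx)]
  dim(col) <- dim(g$idx)
  col
}

# adjoint of conv_gather: accumulate a col matrix back into an input array
conv_scatter <- function(col, g) {
  dxp <- array(0, c(g$Hp, g$Wp, g$C, g$B))
  for (r in seq_along(g$row_off)) {
    ii <- g$col_idx + g$row_off[r]
    dxp[ii] <- dxp[ii] + col[r, ]
  }
  unpad_grad(dxp, g)
}

mat_to_act <- function(m, Ho, Wo, Cout, B) {
  # m is (Cout x npos*B) with positions ordered (i, j, b)
  aperm(array(m, c(Cout, Ho, Wo, B)), c(2, 3, 1, 4))
}

act_to_mat <- function(a) {
  d <- dim(a)
  m <- aperm(a, c(3, 1, 2, 4))
  dim(m) <- c(d[3], d[1] * d[2] * d[4])
  m
}

he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

layer_conv <- function(cin, cout, k, s, p, act = "relu") {
  list(type = "conv", cin = cin, cout = cout, k = k, s = s, p = p, act = act,
       W = he_init(cout, k * k * cin), b = numeric(cout))
}

# transposed convolution: maps [H, W, cin] up to [s*H, s*W, cout]; weights are
# those of the adjoint conv (cin x k*k*cout)
layer_tconv <- function(cin, cout, k, s, p, act = "relu") {
  list(type = "tconv", cin = cin, cout = cout, k = k, s = s, p = p, act = act,
       W = he_init(cin, k * k * cout), b = numeric(cout))
}

layer_fc <- function(nin, nout, act = "relu") {
  list(type = "fc", nin = nin, nout = nout, act = act,
       W = he_init(nout, nin), b = numeric(nout))
}

# parallel single-kernel branches concatenated along channels; wide-kernel
# branches optionally go through a 1x1 reduction first (the classic
# inception bottleneck), which dominates the compute savings at full
# resolution
layer_inception <- function(cin, cout_each, kernels, s, act = "relu",
                            reduce = NULL) {
  list(type = "inception", cin = cin, kernels = kernels, s = s, act = act,
       cout = cout_each * length(kernels),
       branches = lapply(kernels, function(k) {
         red <- if (!is.null(reduce) && reduce < cin) reduce else NULL
         c(list(k = k, p = (k - 1L) %/% 2L,
                W = he_init(cout_each,
                            k * k * (if (is.null(red)) cin else red)),
                b = numeric(cout_each)),
           if (!is.null(red))
             list(Wr = he_init(red, cin), br = numeric(red)))
       }))
}

apply_act <- function(z, act) {
  switch(act, relu = pmax(z, 0), linear = z,
         stop("unknown activation: ", act))
}

act_grad_mask <- function(z, act) {
  switch(act, relu = (z > 0) * 1, linear = 1)
}

nn_forward_layer <- function(layer, x, B, cache_env) {
  key <- paste0("g", layer$id, "_", B)
  g <- cache_env[[key]]
  if (layer$type == "conv") {
    if (is.null(g)) {
      d <- dim(x)
      g <- conv_geom(d[1], d[2], layer$cin, layer$k, layer$s, layer$p, B)
      cache_env[[key]] <- g
    }
    col <- conv_gather(x, g)
    z <- layer$W %*% col + layer$b
    out <- mat_to_act(apply_act(z, layer$act), g$Ho, g$Wo, layer$cout, B)
    list(out = out, cache = list(col = col, z = z, g = g))
  } else if (layer$type == "tconv") {
    d <- dim(x)
    if (is.null(g)) {
      # geometry of the adjoint conv reading the BIG output array
      g <- conv_geom(layer$s * d[1], layer$s * d[2], layer$cout,
                     layer$k, layer$s, layer$p, B)
      cache_env[[key]] <- g
    }
    xm <- act_to_mat(x)
    col <- crossprod(layer$W, xm)             # k2*cout x npos*B
    big <- conv_scatter(col, g)
    z <- sweep(big, 3, layer$b, "+")
    out <- apply_act(z, layer$act)
    list(out = out, cache = list(xm = xm, z = z, g = g))
  } else if (layer$type == "fc") {
    xm <- if (length(dim(x)) == 4) {
      d <- dim(x); matrix(x, d[1] * d[2] * d[3], d[4])
    } else x
    z <- layer$W %*% xm + layer$b
    list(out = apply_act(z, layer$act),
         cache = list(xm = xm, z = z, in_dim = dim(x)))
  } else if (layer$type == "inception") {
    outs <- vector("list", length(layer$branches))
    caches <- vector("list", length(layer$branches))
    for (i in seq_along(layer$branches)) {
      br <- layer$branches[[i]]
      xi <- x
      rcache <- NULL
      if (!is.null(br$Wr)) {      # 1x1 reduction: a per-pixel channel map
        xm <- act_to_mat(x)
        zr <- br$Wr %*% xm + br$br
        rm <- pmax(zr, 0)
        d <- dim(x)
        xi <- mat_to_act(rm, d[1], d[2], nrow(br$Wr), B)
        rcache <- list(xm = xm, zr = zr)
      }
      bkey <- paste0(key, "_", i)
      gb <- cache_env[[bkey]]
      if (is.null(gb)) {
        d <- dim(xi)
        gb <- conv_geom(d[1], d[2], d[3], br$k, layer$s, br$p, B)
        cache_env[[bkey]] <- gb
      }
      col <- conv_gather(xi, gb)
      z <- br$W %*% col + br$b
      outs[[i]] <- mat_to_act(z, gb$Ho, gb$Wo, nrow(br$W), B)
      caches[[i]] <- list(col = col, z = z, g = gb, r = rcache)
    }
    zcat <- array(0, c(dim(outs[[1]])[1:2], layer$cout, B))
    at <- 0
    for (i in seq_along(outs)) {
      nc <- dim(outs[[i]])[3]
      zcat[, , at + seq_len(nc), ] <- outs[[i]]
      at <- at + nc
    }
    list(out = apply_act(zcat, layer$act), cache = list(br = caches, z = zcat))
  } else stop("unknown layer type")
}

nn_backward_layer <- function(layer, dout, cache) {
  if (layer$type == "conv") {
    g <- cache$g
    dz <- act_to_mat(dout) * act_grad_mask(cache$z, layer$act)
    grads <- list(W = tcrossprod(dz, cache$col), b = rowSums(dz))
    dcol <- crossprod(layer$W, dz)
    dx <- conv_scatter(dcol, g)
    list(dx = dx, grads = grads)
  } else if (layer$type == "tconv") {
    g <- cache$g
    dz <- dout * act_grad_mask(cache$z, layer$act)
    db <- apply(dz, 3, sum)
    dcol <- conv_gather(dz, g)                 # adjoint of conv_scatter
    dW <- tcrossprod(cache$xm, dcol)           # cin x k2*cout
    dxm <- layer$W %*% dcol                    # col = t(W) xm => dxm = W dcol
    d_small <- dim(cache$z)
    Hs <- d_small[1] %/% layer$s; Ws <- d_small[2] %/% layer$s
    dx <- mat_to_act(dxm, Hs, Ws, layer$cin, dim(cache$z)[4])
    list(dx = dx, grads = list(W = dW, b = db))
  } else if (layer$type == "fc") {
    dz <- dout * act_grad_mask(cache$z, layer$act)
    grads <- list(W = tcrossprod(dz, cache$xm), b = rowSums(dz))
    dxm <- crossprod(layer$W, dz)
    dx <- if (length(cache$in_dim) == 4) array(dxm, cache$in_dim) else dxm
    list(dx = dx, grads = grads)
  } else if (layer$type == "inception") {
    dzc <- dout * act_grad_mask(cache$z, layer$act)
    dx <- NULL
    grads <- list(branches = vector("list", length(layer$branches)))
    at <- 0
    for (i in seq_along(layer$branches)) {
      br <- layer$branches[[i]]
      cb <- cache$br[[i]]
      nc <- nrow(br$W)
      dz <- act_to_mat(dzc[, , at + seq_len(nc), , drop = FALSE])
      at <- at + nc
      g_i <- list(W = tcrossprod(dz, cb$col), b = rowSums(dz))
      dcol <- crossprod(br$W, dz)
      dxi <- conv_scatter(dcol, cb$g)
      if (!is.null(cb$r)) {       # back through the 1x1 reduction
        drm <- act_to_mat(dxi) * (cb$r$zr > 0)
        g_i$Wr <- tcrossprod(drm, cb$r$xm)
        g_i$br <- rowSums(drm)
        dxm <- crossprod(br$Wr, drm)
        d <- dim(dzc)
        dxi <- mat_to_act(dxm, d[1] * ifelse(layer$s > 1, layer$s, 1),
                          d[2] * ifelse(layer$s > 1, layer$s, 1),
                          layer$cin, d[4])
      }
      grads$branches[[i]] <- g_i
      dx <- if (is.null(dx)) dxi else dx + dxi
    }
    list(dx = dx, grads = grads)
  } else stop("unknown layer type")
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    zero_like <- function(x) {
      if (is.list(x)) lapply(x, zero_like) else x * 0
    }
    if (l$type == "inception")
      list(branches = lapply(l$branches, function(b)
        c(list(W = list(m = b$W * 0, v = b$W * 0),
               b = list(m = b$b * 0, v = b$b * 0)),
          if (!is.null(b$Wr))
            list(Wr = list(m = b$Wr * 0, v = b$Wr * 0),
                 br = list(m = b$br * 0, v = b$br * 0)))))
    else
      list(W = list(m = l$W * 0, v = l$W * 0),
           b = list(m = l$b * 0, v = l$b * 0))
  })
}

adam_update <- function(param, grad, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}
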