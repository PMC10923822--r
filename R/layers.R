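# Neural-network layer primitives with explicit forward/backward passes.
#
# A "batch" is a list of (H, W, C) numeric arrays. Every layer_forward()
# returns list(out = <batch>, cache = <opaque>) and layer_backward() returns
# list(dx = <batch>, grads = <named list matching layer$params> or NULL).
# Convolutions run through im2col/col2im C++ kernels with the GEMM done by
# BLAS; batch normalization couples samples (statistics over batch + space).

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

new_conv_layer <- function(c_in, filters, k = 3, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(
    type = "conv", k = as.integer(k), stride = 1L, pad = as.integer(pad),
    c_in = as.integer(c_in), filters = as.integer(filters),
    params = list(
      W = he_uniform(c(k, k, c_in, filters), fan_in = k * k * c_in),
      b = numeric(filters)
    )
  )
}

new_bn_layer <- function(channels, momentum = 0.99, eps = 1e-3) {
  list(
    type = "bn", channels = as.integer(channels),
    momentum = momentum, eps = eps,
    params = list(gamma = rep(1, channels), beta = numeric(channels)),
    state = list(run_mean = numeric(channels), run_var = rep(1, channels))
  )
}

new_relu_layer <- function() list(type = "relu", params = list())

new_sigmoid_layer <- function() list(type = "sigmoid", params = list())

new_pool_layer <- function() list(type = "pool", params = list())

# Transposed convolution, stride 2. pad_mode "valid" maps H -> 2H + 1,
# "same" maps H -> 2H (the full 2H+1 output with its last row/col cropped).
new_convt_layer <- function(c_in, filters, pad_mode, k = 3) {
  stopifnot(pad_mode %in% c("same", "valid"))
  list(
    type = "convt", k = as.integer(k), pad_mode = pad_mode,
    c_in = as.integer(c_in), filters = as.integer(filters),
    params = list(
      V = he_uniform(c(k, k, filters, c_in), fan_in = k * k * c_in),
      b = numeric(filters)
    )
  )
}

# CBAM: channel attention (shared 2-layer MLP over per-channel average and
# max descriptors, reduction ratio r) followed by spatial attention (kxk
# convolution over the channel-wise average/max planes).
new_cbam_layer <- function(channels, reduction = 16, spatial_kernel = 7) {
  h <- max(1L, channels %/% reduction)
  ks <- as.integer(spatial_kernel)
  list(
    type = "cbam", channels = as.integer(channels), hidden = h, ks = ks,
    params = list(
      W1 = he_uniform(c(h, channels), fan_in = channels),
      b1 = numeric(h),
      W2 = he_uniform(c(channels, h), fan_in = h),
      b2 = numeric(channels),
      Ws = he_uniform(c(ks, ks, 2, 1), fan_in = ks * ks * 2),
      bs = 0
    )
  )
}


layer_forward <- function(layer, xs, training = TRUE) {
  switch(layer$type,
    conv = {
      k <- layer$k; pad <- layer$pad
      d <- dim(xs[[1]])
      oh <- d[1]; ow <- d[2]  # stride 1, shape-preserving padding
      Wm <- matrix(layer$params$W, k * k * layer$c_in, layer$filters)
      out <- lapply(xs, function(x)
        cpp_conv_fw(x, Wm, layer$params$b, k, 1L, pad, oh, ow))
      list(out = out, cache = list(xs = xs, oh = oh, ow = ow))
    },
    convt = {
      k <- layer$k
      d <- dim(xs[[1]])
      H <- d[1]; W <- d[2]
      oh <- if (layer$pad_mode == "valid") 2L * H + 1L else 2L * H
      ow <- if (layer$pad_mode == "valid") 2L * W + 1L else 2L * W
      Vm <- matrix(layer$params$V, k * k * layer$filters, layer$c_in)
      b <- layer$params$b
      out <- lapply(xs, function(x) cpp_convt_fw(x, Vm, b, k, oh, ow))
      list(out = out, cache = list(xs = xs, H = H, W = W, oh = oh, ow = ow))
    },
    bn = {
      eps <- layer$eps
      if (training) {
        N <- sum(vapply(xs, function(x) prod(dim(x)[1:2]), numeric(1)))
        st <- lapply(xs, cpp_channel_stats)
        mu <- Reduce(`+`, lapply(st, `[[`, "sum")) / N
        v <- pmax(Reduce(`+`, lapply(st, `[[`, "sqsum")) / N - mu^2, 0)
      } else {
        mu <- layer$state$run_mean
        v <- layer$state$run_var
        N <- NA_real_
      }
      inv_std <- 1 / sqrt(v + eps)
      g <- layer$params$gamma
      out <- lapply(xs, cpp_channel_affine, a = g * inv_std,
                    b = layer$params$beta - g * inv_std * mu)
      cache <- list(xs = xs, mu = mu, inv_std = inv_std, N = N)
      if (training) {
        m <- layer$momentum
        cache$new_state <- list(
          run_mean = m * layer$state$run_mean + (1 - m) * mu,
          run_var = m * layer$state$run_var + (1 - m) * v
        )
      }
      list(out = out, cache = cache)
    },
    relu = {
      out <- lapply(xs, cpp_relu_fw)
      list(out = out, cache = out)
    },
    sigmoid = {
      out <- lapply(xs, function(x) 1 / (1 + exp(-x)))
      list(out = out, cache = out)
    },
    pool = {
      res <- lapply(xs, cpp_maxpool)
      out <- lapply(res, `[[`, "y")
      list(out = out, cache = list(
        idx = lapply(res, `[[`, "idx"),
        H = dim(xs[[1]])[1], W = dim(xs[[1]])[2]
      ))
    },
    cbam = cbam_forward(layer, xs),
    stop("unknown layer type: ", layer$type)
  )
}

sweep_channels <- function(x, b) {
  d <- dim(x)
  array(sweep(matrix(x, ncol = d[3]), 2L, b, "+"), dim = d)
}

layer_backward <- function(layer, dys, cache) {
  switch(layer$type,
    conv = {
      k <- layer$k; pad <- layer$pad
      Wm <- matrix(layer$params$W, k * k * layer$c_in, layer$filters)
      dW <- matrix(0, nrow(Wm), ncol(Wm))
      db <- numeric(layer$filters)
      dx <- vector("list", length(dys))
      for (i in seq_along(dys)) {
        r <- cpp_conv_bw(cache$xs[[i]], Wm, dys[[i]], k, 1L, pad,
                         cache$oh, cache$ow)
        dW <- dW + r$dW
        db <- db + r$db
        dx[[i]] <- r$dx
      }
      list(dx = dx,
           grads = list(W = array(dW, dim(layer$params$W)), b = db))
    },
    convt = {
      k <- layer$k
      Vm <- matrix(layer$params$V, k * k * layer$filters, layer$c_in)
      dV <- matrix(0, nrow(Vm), ncol(Vm))
      db <- numeric(layer$filters)
      dx <- vector("list", length(dys))
      for (i in seq_along(dys)) {
        r <- cpp_convt_bw(cache$xs[[i]], Vm, dys[[i]], k)
        dV <- dV + r$dV
        db <- db + r$db
        dx[[i]] <- r$dx
      }
      list(dx = dx,
           grads = list(V = array(dV, dim(layer$params$V)), b = db))
    },
    bn = {
      g <- layer$params$gamma
      sums <- Map(cpp_bn_bw_sums, cache$xs, dys,
                  MoreArgs = list(mu = cache$mu, inv_std = cache$inv_std))
      dbta <- Reduce(`+`, lapply(sums, `[[`, "sum_dy"))
      dg <- Reduce(`+`, lapply(sums, `[[`, "sum_dy_xhat"))
      dx <- Map(cpp_bn_bw_dx, cache$xs, dys,
                MoreArgs = list(mu = cache$mu, inv_std = cache$inv_std,
                                gamma = g, s1 = dbta * g, s2 = dg * g,
                                N = cache$N))
      list(dx = dx, grads = list(gamma = dg, beta = dbta))
    },
    relu = {
      list(dx = Map(cpp_relu_bw, cache, dys), grads = NULL)
    },
    sigmoid = {
      list(dx = Map(function(dy, y) dy * y * (1 - y), dys, cache),
           grads = NULL)
    },
    pool = {
      dx <- Map(function(dy, idx) cpp_maxpool_bw(dy, idx, cache$H, cache$W),
                dys, cache$idx)
      list(dx = dx, grads = NULL)
    },
    cbam = cbam_backward(layer, dys, cache),
    stop("unknown layer type: ", layer$type)
  )
}

cbam_forward <- function(layer, xs) {
  C <- layer$channels; ks <- layer$ks
  p <- layer$params
  Wsm <- matrix(p$Ws, ks * ks * 2, 1)
  zeroC <- numeric(C)
  caches <- vector("list", length(xs))
  out <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    d <- dim(x)
    # channel attention: shared MLP over mean and max descriptors
    cd <- cpp_chan_descr(x)
    h1a <- pmax(as.vector(p$W1 %*% cd$va) + p$b1, 0)
    h1m <- pmax(as.vector(p$W1 %*% cd$vm) + p$b1, 0)
    o <- as.vector(p$W2 %*% h1a) + as.vector(p$W2 %*% h1m) + 2 * p$b2
    s <- 1 / (1 + exp(-o))
    x1 <- cpp_channel_affine(x, s, zeroC)
    # spatial attention over the gated tensor's mean/max planes
    sd <- cpp_spatial_descr(x1)
    sp <- array(c(sd$savg, sd$smax), dim = c(d[1], d[2], 2))
    smap <- as.vector(cpp_conv_fw(sp, Wsm, c(p$bs), ks, 1L,
                                  (ks - 1L) %/% 2L, d[1], d[2]))
    S <- 1 / (1 + exp(-smap))
    out[[i]] <- cpp_scale_spatial(x1, S)
    caches[[i]] <- list(x = x, x1 = x1, s = s, S = S, d = d,
                        carg = cd$carg, sarg = sd$sarg, va = cd$va,
                        vm = cd$vm, h1a = h1a, h1m = h1m, sp = sp)
  }
  list(out = out, cache = caches)
}

cbam_backward <- function(layer, dys, cache) {
  C <- layer$channels; ks <- layer$ks
  p <- layer$params
  Wsm <- matrix(p$Ws, ks * ks * 2, 1)
  gW1 <- array(0, dim(p$W1)); gb1 <- numeric(layer$hidden)
  gW2 <- array(0, dim(p$W2)); gb2 <- numeric(C)
  gWs <- matrix(0, ks * ks * 2, 1); gbs <- 0
  dx <- vector("list", length(dys))
  for (i in seq_along(dys)) {
    cc <- cache[[i]]
    d <- cc$d; np <- d[1] * d[2]
    dy <- dys[[i]]
    # y = x1 * S
    dxm1 <- cpp_scale_spatial(dy, cc$S)
    dS <- cpp_pixel_dot(dy, cc$x1)
    dsmap <- dS * cc$S * (1 - cc$S)
    rs <- cpp_conv_bw(cc$sp, Wsm, array(dsmap, c(d[1], d[2], 1)), ks, 1L,
                      (ks - 1L) %/% 2L, d[1], d[2])
    gWs <- gWs + rs$dW
    gbs <- gbs + rs$db
    # avg plane spreads over channels, max plane hits each pixel's argmax
    dxm1 <- cpp_cbam_spatial_bw(dxm1, as.vector(rs$dx[, , 1]),
                                as.vector(rs$dx[, , 2]), cc$sarg)
    # x1 = x * s
    dxm <- cpp_channel_affine(dxm1, cc$s, numeric(C))
    ds <- cpp_channel_dot(dxm1, cc$x)
    do <- ds * cc$s * (1 - cc$s)
    # o = W2 h1a + W2 h1m + 2 b2 (shared MLP applied to both descriptors)
    gb2 <- gb2 + 2 * do
    gW2 <- gW2 + outer(do, cc$h1a) + outer(do, cc$h1m)
    dh1 <- as.vector(crossprod(p$W2, do))
    dh1a <- dh1 * (cc$h1a > 0)
    dh1m <- dh1 * (cc$h1m > 0)
    gW1 <- gW1 + outer(dh1a, cc$va) + outer(dh1m, cc$vm)
    gb1 <- gb1 + dh1a + dh1m
    dva <- as.vector(crossprod(p$W1, dh1a))
    dvm <- as.vector(crossprod(p$W1, dh1m))
    # va = channel means; vm picks the per-channel argmax pixel
    dxm <- cpp_channel_affine(dxm, rep(1, C), dva / np)
    idx <- (seq_len(C) - 1) * np + cc$carg
    dxm[idx] <- dxm[idx] + dvm
    dx[[i]] <- dxm
  }
  list(dx = dx, grads = list(
    W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
    Ws = array(gWs, dim(p$Ws)), bs = gbs
  ))
}

# Forward through a list of layers. Returns outputs and (optionally) the
# per-layer caches needed for backprop plus refreshed batch-norm running
# statistics.
net_forward <- function(layers, xs, training = TRUE, keep_cache = training) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  new_states <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    res <- layer_forward(layers[[li]], xs, training = training)
    xs <- res$out
    if (keep_cache) caches[[li]] <- res$cache
    if (training && layers[[li]]$type == "bn")
      new_states[[li]] <- res$cache$new_state
  }
  list(out = xs, caches = caches, bn_states = new_states)
}

# Backward through a list of layers; returns input gradients and a list of
# per-layer parameter gradients (NULL for parameter-free layers).
net_backward <- function(layers, caches, dys) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    res <- layer_backward(layers[[li]], dys, caches[[li]])
    dys <- res$dx
    grads[li] <- list(res$grads)  # [[<- with NULL would drop the slot
  }
  list(dx = dys, grads = grads)
}

apply_bn_states <- function(layers, bn_states) {
  for (li in seq_along(layers)) {
    if (!is.null(bn_states[[li]])) layers[[li]]$state <- bn_states[[li]]
  }
  layers
}
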