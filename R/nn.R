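# Native convolutional network engine. Tensors are R arrays (H, W, D, C):
# 2-D images enter as (227, 227, 1, 3), spectral cubes as (227, 227, 5, 1).
# Convolution and pooling are im2col-based: patch index tables are
# precomputed per layer at build time, so the forward pass is one gather
# plus one BLAS matmul per layer, and the backward pass one matmul plus a
# rowsum scatter.

lin_index <- function(h, w, d, c, dims) {
  h + dims[1] * (w - 1 + dims[2] * (d - 1 + dims[3] * (c - 1)))
}

# Index table for conv patches over padded dims `pdims`, kernel k = (kh,
# kw, kd), spatial stride s, all input channels stacked. Output positions
# enumerated h-fastest, then w, then d.
conv_index <- function(pdims, k, stride) {
  ho <- (pdims[1] - k[1]) %/% stride + 1L
  wo <- (pdims[2] - k[2]) %/% stride + 1L
  do <- pdims[3] - k[3] + 1L
  offs <- as.vector(outer(
    lin_index(rep(seq_len(k[1]), times = k[2]),
              rep(seq_len(k[2]), each = k[1]), 1, 1, pdims) - 1L,
    as.vector(outer(lin_index(1, 1, seq_len(k[3]), 1, pdims) - 1L,
                    lin_index(1, 1, 1, seq_len(pdims[4]), pdims) - 1L,
                    "+")), "+"))
  base_h <- (seq_len(ho) - 1L) * stride + 1L
  base_w <- (seq_len(wo) - 1L) * stride + 1L
  base_d <- seq_len(do)
  bases <- lin_index(rep(base_h, times = wo * do),
                     rep(rep(base_w, each = ho), times = do),
                     rep(base_d, each = ho * wo), 1, pdims)
  idx <- outer(offs, bases, "+")
  list(idx = idx, out = c(ho, wo, do))
}

# Pooling index over (H, W, D) of one channel; kernel clipped to depth.
pool_index <- function(dims, k = 3L, stride = 2L, kd = 3L) {
  kd <- min(kd, dims[3])
  ho <- (dims[1] - k) %/% stride + 1L
  wo <- (dims[2] - k) %/% stride + 1L
  do <- max(1L, (dims[3] - kd) %/% stride + 1L)
  d3 <- dims
  offs <- as.vector(outer(
    lin_index(rep(seq_len(k), times = k), rep(seq_len(k), each = k),
              1, 1, d3) - 1L,
    lin_index(1, 1, seq_len(kd), 1, d3) - 1L, "+"))
  base_h <- (seq_len(ho) - 1L) * stride + 1L
  base_w <- (seq_len(wo) - 1L) * stride + 1L
  base_d <- (seq_len(do) - 1L) * stride + 1L
  bases <- lin_index(rep(base_h, times = wo * do),
                     rep(rep(base_w, each = ho), times = do),
                     rep(base_d, each = ho * wo), 1, d3)
  list(idx = outer(offs, bases, "+"), out = c(ho, wo, do))
}

pad_tensor <- function(x, pad_hw, pad_d) {
  if (pad_hw == 0 && all(pad_d == 0)) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad_hw, d[2] + 2 * pad_hw,
                    d[3] + sum(pad_d), d[4]))
  out[pad_hw + seq_len(d[1]), pad_hw + seq_len(d[2]),
      pad_d[1] + seq_len(d[3]), ] <- x
  out
}

layer_conv <- function(in_dims, n_filters, k_hw, k_d, stride, pad_hw,
                       depth_same = TRUE) {
  kd <- min(k_d, in_dims[3])
  pad_d <- if (depth_same && kd > 1) {
    c((kd - 1L) %/% 2L, (kd - 1L) - (kd - 1L) %/% 2L)
  } else c(0L, 0L)
  pdims <- c(in_dims[1] + 2L * pad_hw, in_dims[2] + 2L * pad_hw,
             in_dims[3] + sum(pad_d), in_dims[4])
  ci <- conv_index(pdims, c(k_hw, k_hw, kd), stride)
  fan_in <- k_hw * k_hw * kd * in_dims[4]
  list(type = "conv", in_dims = in_dims,
       out_dims = c(ci$out, n_filters),
       W = matrix(rnorm(n_filters * fan_in, sd = sqrt(2 / fan_in)),
                  n_filters, fan_in),
       b = numeric(n_filters),
       idx = ci$idx, pad_hw = pad_hw, pad_d = pad_d, pdims = pdims)
}

layer_pool <- function(in_dims, k = 3L, stride = 2L, kd = 3L) {
  pi <- pool_index(in_dims[1:3], k, stride, kd)
  list(type = "pool", in_dims = in_dims, out_dims = c(pi$out, in_dims[4]),
       idx = pi$idx)
}

layer_lrn <- function(in_dims, n = 5, k = 2, alpha = 1e-4, beta = 0.75) {
  list(type = "lrn", in_dims = in_dims, out_dims = in_dims,
       n = n, k = k, alpha = alpha, beta = beta)
}

layer_relu <- function(in_dims) {
  list(type = "relu", in_dims = in_dims, out_dims = in_dims)
}

layer_fc <- function(n_in, n_out) {
  list(type = "fc", in_dims = n_in, out_dims = n_out,
       W = matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

layer_dropout <- function(n, rate = 0.5) {
  list(type = "dropout", in_dims = n, out_dims = n, rate = rate)
}

layer_flatten <- function(in_dims) {
  list(type = "flatten", in_dims = in_dims, out_dims = prod(in_dims))
}

forward_layer <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      xp <- pad_tensor(x, layer$pad_hw, layer$pad_d)
      cols <- matrix(xp[layer$idx], nrow = nrow(layer$idx))
      out <- layer$W %*% cols + layer$b
      list(out = array(t(out), layer$out_dims), cache = cols)
    },
    pool = {
      d <- dim(x)
      npos <- ncol(layer$idx)
      out <- array(0, layer$out_dims)
      arg <- matrix(0L, npos, d[4])
      for (ch in seq_len(d[4])) {
        v <- x[, , , ch, drop = FALSE]
        m <- matrix(v[layer$idx], nrow = nrow(layer$idx))
        best <- m[1, ]; bi <- rep(1L, npos)
        for (r in seq_len(nrow(m))[-1]) {
          gt <- m[r, ] > best
          best[gt] <- m[r, gt]; bi[gt] <- r
        }
        out[, , , ch] <- best
        arg[, ch] <- layer$idx[cbind(bi, seq_len(npos))]
      }
      list(out = out, cache = arg)
    },
    lrn = {
      cdim <- dim(x)[4]
      m <- matrix(x, ncol = cdim)
      s <- matrix(layer$k, nrow(m), cdim)
      sq <- m^2
      half <- (layer$n - 1) %/% 2
      for (cc in seq_len(cdim)) {
        js <- max(1, cc - half):min(cdim, cc + half)
        s[, cc] <- layer$k + layer$alpha *
          rowSums(sq[, js, drop = FALSE])
      }
      sb <- s^(-layer$beta)
      list(out = array(m * sb, dim(x)), cache = list(m = m, s = s, sb = sb))
    },
    relu = {
      pos <- x > 0
      list(out = x * pos, cache = pos)
    },
    flatten = list(out = as.vector(x), cache = dim(x)),
    fc = list(out = as.vector(layer$W %*% x + layer$b), cache = x),
    dropout = {
      if (training) {
        mask <- (runif(length(x)) > layer$rate) / (1 - layer$rate)
        list(out = x * mask, cache = mask)
      } else list(out = x, cache = NULL)
    })
}

backward_layer <- function(layer, dout, cache, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      dm <- t(matrix(dout, ncol = layer$out_dims[4]))
      grads <- list(W = dm %*% t(cache), b = rowSums(dm))
      dx <- NULL
      if (need_dx) {
        dcols <- crossprod(layer$W, dm)
        acc <- rowsum(as.vector(dcols), as.vector(layer$idx))
        dxp <- numeric(prod(layer$pdims))
        dxp[as.integer(rownames(acc))] <- acc
        dxp <- array(dxp, layer$pdims)
        dx <- dxp[layer$pad_hw + seq_len(layer$in_dims[1]),
                  layer$pad_hw + seq_len(layer$in_dims[2]),
                  layer$pad_d[1] + seq_len(layer$in_dims[3]), ,
                  drop = FALSE]
      }
      list(dx = dx, grads = grads)
    },
    pool = {
      d4 <- layer$in_dims[4]
      dx <- array(0, layer$in_dims)
      npix <- prod(layer$in_dims[1:3])
      dm <- matrix(dout, ncol = d4)
      for (ch in seq_len(d4)) {
        acc <- rowsum(dm[, ch], cache[, ch])
        page <- numeric(npix)
        page[as.integer(rownames(acc))] <- acc
        dx[, , , ch] <- page
      }
      list(dx = dx, grads = NULL)
    },
    lrn = {
      m <- cache$m; s <- cache$s; sb <- cache$sb
      cdim <- ncol(m)
      dm <- matrix(dout, ncol = cdim)
      tmat <- dm * m * s^(-layer$beta - 1)
      half <- (layer$n - 1) %/% 2
      dx <- dm * sb
      for (cc in seq_len(cdim)) {
        js <- max(1, cc - half):min(cdim, cc + half)
        dx[, cc] <- dx[, cc] - 2 * layer$alpha * layer$beta * m[, cc] *
          rowSums(tmat[, js, drop = FALSE])
      }
      list(dx = array(dx, layer$in_dims), grads = NULL)
    },
    relu = list(dx = dout * cache, grads = NULL),
    flatten = list(dx = array(dout, cache), grads = NULL),
    fc = list(dx = as.vector(crossprod(layer$W, dout)),
              grads = list(W = outer(dout, cache), b = dout)),
    dropout = list(dx = if (is.null(cache)) dout else dout * cache,
                   grads = NULL))
}

net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    st <- forward_layer(net$layers[[i]], x, training)
    x <- st$out
    caches[i] <- list(st$cache)
  }
  list(scores = x, caches = caches)
}

softmax_loss <- function(scores, y) {
  z <- scores - max(scores)
  p <- exp(z) / sum(exp(z))
  dz <- p
  dz[y] <- dz[y] - 1
  list(loss = -log(max(p[y], 1e-12)), dscores = dz)
}

net_backward <- function(net, caches, dscores) {
  grads <- vector("list", length(net$layers))
  dout <- dscores
  for (i in rev(seq_along(net$layers))) {
    bk <- backward_layer(net$layers[[i]], dout, caches[[i]],
                         need_dx = i > 1)
    grads[i] <- list(bk$grads)
    dout <- bk$dx
  }
  grads
}
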