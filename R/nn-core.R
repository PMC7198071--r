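# Internal neural-network primitives.
#
# Tensors are dense double arrays laid out (height, width, channel, batch);
# a single image is (H, W, C).  Convolutions are evaluated as one BLAS
# matrix product over an im2col patch matrix; the patch index maps are
# cached per (shape, kernel, stride, pad) so repeated forward/backward
# passes through the same layer pay the indexing cost once.
#
# Every *_forward() returns list(out, cache, layer); `layer` is returned
# because batch-norm layers update their running statistics in training
# mode and R lists have value semantics.  Every *_backward() returns
# list(dx, grads) where `grads` holds arrays named exactly like the
# layer's parameters (W, b, gamma, beta, W1, b1, W2, b2).

.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "/")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) {
    stop(sprintf("kernel %dx%d does not fit input %dx%d (pad %d)", kh, kw, H, W, pad))
  }
  # patch-row order: kernel row fastest, then kernel col, then channel --
  # matches the flattening of weights stored as array(dim = c(kh, kw, Cin, Cout))
  ki <- rep.int(seq_len(kh), kw)
  kj <- rep(seq_len(kw), each = kh)
  koff <- (ki - 1L) + (kj - 1L) * Hp
  koff <- rep.int(koff, C) + rep(seq_len(C) - 1L, each = kh * kw) * (Hp * Wp)
  # output-pixel order: row fastest, then col (column-major image layout)
  oi <- rep.int(seq_len(Ho), Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  poff <- (oi - 1L) * stride + (oj - 1L) * stride * Hp
  idx <- outer(koff, poff, `+`) + 1L
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

pad_hw <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# expand a single-image patch index to a whole batch (plane offset per image)
batch_index <- function(idx, plane, B) {
  if (B == 1L) return(as.vector(idx))
  rep(as.vector(idx), times = B) +
    rep((seq_len(B) - 1L) * plane, each = length(idx))
}

## ---- convolution -----------------------------------------------------------

conv2d_init <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L, bias = TRUE) {
  fan_in <- kernel * kernel * in_ch
  bound <- sqrt(6 / fan_in)
  list(
    type = "conv2d", kh = as.integer(kernel), kw = as.integer(kernel),
    stride = as.integer(stride), pad = as.integer(pad),
    in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
    W = array(stats::runif(kernel * kernel * in_ch * out_ch, -bound, bound),
              dim = c(kernel, kernel, in_ch, out_ch)),
    b = if (bias) numeric(out_ch) else NULL
  )
}

conv2d_forward <- function(layer, x, want_cache = FALSE) {
  d <- dim(x)
  if (d[3] != layer$in_ch) {
    stop(sprintf("conv2d: expected %d input channels, got %d", layer$in_ch, d[3]))
  }
  ic <- im2col_index(d[1], d[2], d[3], layer$kh, layer$kw, layer$stride, layer$pad)
  xp <- pad_hw(x, layer$pad)
  P <- xp[batch_index(ic$idx, ic$Hp * ic$Wp * d[3], d[4])]
  dim(P) <- c(nrow(ic$idx), ic$Ho * ic$Wo * d[4])
  Wmat <- matrix(layer$W, nrow = layer$kh * layer$kw * layer$in_ch)
  out <- crossprod(Wmat, P)                       # Cout x (Ho*Wo*B)
  if (!is.null(layer$b)) out <- out + layer$b
  out <- array(t(out), dim = c(ic$Ho, ic$Wo, d[4], layer$out_ch))
  out <- aperm(out, c(1L, 2L, 4L, 3L))
  cache <- if (want_cache) list(P = P, ic = ic, dims = d) else NULL
  list(out = out, cache = cache, layer = layer)
}

conv2d_backward <- function(layer, cache, dout) {
  ic <- cache$ic
  d <- cache$dims
  B <- d[4]
  kh <- layer$kh; kw <- layer$kw; C <- layer$in_ch
  dmat <- aperm(dout, c(3L, 1L, 2L, 4L))
  dim(dmat) <- c(layer$out_ch, ic$Ho * ic$Wo * B)
  dW <- tcrossprod(dmat, cache$P)                 # Cout x (kh*kw*C)
  dW <- array(t(dW), dim = c(kh, kw, C, layer$out_ch))
  grads <- list(W = dW)
  if (!is.null(layer$b)) grads$b <- rowSums(dmat)
  Wmat <- matrix(layer$W, nrow = kh * kw * C)
  dP <- Wmat %*% dmat                             # (kh*kw*C) x (Ho*Wo*B)
  dPa <- array(dP, dim = c(kh, kw, C, ic$Ho, ic$Wo, B))
  dxp <- array(0, dim = c(ic$Hp, ic$Wp, C, B))
  ri <- (seq_len(ic$Ho) - 1L) * layer$stride
  cj <- (seq_len(ic$Wo) - 1L) * layer$stride
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      sl <- dPa[i, j, , , , , drop = FALSE]
      dim(sl) <- c(C, ic$Ho, ic$Wo, B)
      dxp[ri + i, cj + j, , ] <- dxp[ri + i, cj + j, , , drop = FALSE] +
        aperm(sl, c(2L, 3L, 1L, 4L))
    }
  }
  p <- layer$pad
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
  list(dx = dx, grads = grads)
}

## ---- batch normalization ---------------------------------------------------

bn_init <- function(C, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, C), beta = rep(0, C),
       running_mean = rep(0, C), running_var = rep(1, C),
       eps = eps, momentum = momentum)
}

# core on an n x C matrix; used for both 2-d (n = H*W*B) and 1-d (n = B) cases
bn_forward_mat <- function(layer, xm, training, want_cache = FALSE) {
  n <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    m <- layer$momentum
    layer$running_mean <- (1 - m) * layer$running_mean + m * mu
    vu <- if (n > 1) v * n / (n - 1) else v
    layer$running_var <- (1 - m) * layer$running_var + m * vu
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - rep(mu, each = n)) * rep(inv, each = n)
  y <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  cache <- if (want_cache) list(xhat = xhat, inv = inv, n = n) else NULL
  list(out = y, cache = cache, layer = layer)
}

bn_backward_mat <- function(layer, cache, dy) {
  n <- cache$n
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  g <- rep(layer$gamma * cache$inv / n, each = n)
  dx <- g * (n * dy - rep(dbeta, each = n) - xhat * rep(dgamma, each = n))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

bn2d_forward <- function(layer, x, training, want_cache = FALSE) {
  d <- dim(x)
  xm <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  r <- bn_forward_mat(layer, xm, training, want_cache)
  y <- r$out
  dim(y) <- c(d[1], d[2], d[4], d[3])
  r$out <- aperm(y, c(1L, 2L, 4L, 3L))
  if (want_cache) r$cache$dims <- d
  r
}

bn2d_backward <- function(layer, cache, dout) {
  d <- cache$dims
  dm <- aperm(dout, c(1L, 2L, 4L, 3L))
  dim(dm) <- c(d[1] * d[2] * d[4], d[3])
  r <- bn_backward_mat(layer, cache, dm)
  dx <- r$dx
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  r$dx <- aperm(dx, c(1L, 2L, 4L, 3L))
  r
}

## ---- activations -----------------------------------------------------------

relu_forward <- function(x, want_cache = FALSE) {
  y <- x
  y[y < 0] <- 0
  list(out = y, cache = if (want_cache) list(mask = x > 0) else NULL)
}

relu_backward <- function(cache, dout) {
  dout * cache$mask
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- pooling ---------------------------------------------------------------

maxpool_forward <- function(x, kernel = 3L, stride = 2L, pad = 1L, want_cache = FALSE) {
  d <- dim(x)
  ic <- im2col_index(d[1], d[2], 1L, kernel, kernel, stride, pad)
  xp <- pad_hw(x, pad, value = -Inf)
  nplane <- d[3] * d[4]
  idx <- batch_index(ic$idx, ic$Hp * ic$Wp, nplane)
  P <- xp[idx]
  dim(P) <- c(kernel * kernel, ic$Ho * ic$Wo * nplane)
  am <- max.col(t(P), ties.method = "first")
  mx <- P[(seq_along(am) - 1L) * (kernel * kernel) + am]
  out <- array(mx, dim = c(ic$Ho, ic$Wo, d[3], d[4]))
  cache <- NULL
  if (want_cache) {
    # flat positions (in the padded tensor) of each window's maximum
    pos <- idx[(seq_along(am) - 1L) * (kernel * kernel) + am]
    cache <- list(pos = pos, dims = d, Hp = ic$Hp, Wp = ic$Wp, pad = pad)
  }
  list(out = out, cache = cache)
}

maxpool_backward <- function(cache, dout) {
  d <- cache$dims
  acc <- rowsum(as.vector(dout), cache$pos)
  flat <- numeric(cache$Hp * cache$Wp * d[3] * d[4])
  flat[as.integer(rownames(acc))] <- acc
  dxp <- array(flat, dim = c(cache$Hp, cache$Wp, d[3], d[4]))
  p <- cache$pad
  if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
}

# 2x2 average pooling, stride 2, floor semantics for odd sizes
avgpool2_forward <- function(x, want_cache = FALSE) {
  d <- dim(x)
  Ho <- d[1] %/% 2L
  Wo <- d[2] %/% 2L
  i1 <- seq.int(1L, by = 2L, length.out = Ho)
  j1 <- seq.int(1L, by = 2L, length.out = Wo)
  out <- (x[i1, j1, , , drop = FALSE] + x[i1 + 1L, j1, , , drop = FALSE] +
          x[i1, j1 + 1L, , , drop = FALSE] + x[i1 + 1L, j1 + 1L, , , drop = FALSE]) / 4
  dim(out) <- c(Ho, Wo, d[3], d[4])
  list(out = out, cache = if (want_cache) list(dims = d, Ho = Ho, Wo = Wo) else NULL)
}

avgpool2_backward <- function(cache, dout) {
  d <- cache$dims
  dx <- array(0, dim = d)
  i1 <- seq.int(1L, by = 2L, length.out = cache$Ho)
  j1 <- seq.int(1L, by = 2L, length.out = cache$Wo)
  q <- dout / 4
  dx[i1, j1, , ] <- q
  dx[i1 + 1L, j1, , ] <- q
  dx[i1, j1 + 1L, , ] <- q
  dx[i1 + 1L, j1 + 1L, , ] <- q
  dx
}

# global average pooling: (H,W,C,B) -> B x C matrix
gap_forward <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  g <- colMeans(xm)
  dim(g) <- c(d[3], d[4])
  list(out = t(g), dims = d)
}

gap_backward <- function(dims, dg) {
  n <- dims[1] * dims[2]
  array(rep(as.vector(t(dg)) / n, each = n), dim = dims)
}

## ---- linear ----------------------------------------------------------------

linear_init <- function(in_dim, out_dim, bias = TRUE) {
  bound <- sqrt(6 / in_dim)
  list(type = "linear",
       W = matrix(stats::runif(in_dim * out_dim, -bound, bound), in_dim, out_dim),
       b = if (bias) numeric(out_dim) else NULL)
}

linear_forward <- function(layer, x, want_cache = FALSE) {
  y <- x %*% layer$W
  if (!is.null(layer$b)) y <- sweep(y, 2L, layer$b, `+`)
  list(out = y, cache = if (want_cache) list(x = x) else NULL)
}

linear_backward <- function(layer, cache, dy) {
  grads <- list(W = crossprod(cache$x, dy))
  if (!is.null(layer$b)) grads$b <- colSums(dy)
  list(dx = dy %*% t(layer$W), grads = grads)
}

## ---- parameter-tree utilities ----------------------------------------------

.param_names <- c("W", "b", "gamma", "beta", "W1", "b1", "W2", "b2")

# recursively collect parameter arrays of a model subtree as a flat named list
flatten_params <- function(node, prefix = "") {
  out <- list()
  if (!is.list(node)) return(out)
  nm <- names(node)
  for (i in seq_along(node)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    path <- if (nzchar(prefix)) paste(prefix, key, sep = ".") else key
    el <- node[[i]]
    if (is.numeric(el) && key %in% .param_names) {
      out[[path]] <- el
    } else if (is.list(el)) {
      out <- c(out, flatten_params(el, path))
    }
  }
  out
}

# elementwise count of parameters in a subtree
n_params <- function(node) {
  sum(vapply(flatten_params(node), length, integer(1)))
}
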