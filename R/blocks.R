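# Building blocks of the architecture: dense layers/blocks, transition
# layers, squeeze-and-excitation modules, classification branches, softmax
# and the binary cross-entropy loss.  Public functions accept a single
# feature map (H, W, C) or a batch (H, W, C, B); internal *_fc ("forward
# cached") variants used by the training loop always take batches.

ensure_batch <- function(x, what = "feature map") {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop(sprintf("%s must be an (H, W, C) or (H, W, C, B) array", what))
  }
  if (length(d) == 3L) list(x = array(x, dim = c(d, 1L)), single = TRUE)
  else list(x = x, single = FALSE)
}

unbatch <- function(x, single) {
  if (!single) return(x)
  d <- dim(x)
  array(x, dim = d[1:3])
}

concat_channels <- function(maps) {
  dims <- lapply(maps, dim)
  hw <- vapply(dims, function(d) d[1:2], numeric(2))
  if (any(hw[1, ] != hw[1, 1]) || any(hw[2, ] != hw[2, 1])) {
    stop("concat_channels: feature maps differ in spatial size")
  }
  B <- dims[[1]][4]
  chans <- vapply(dims, function(d) d[3], numeric(1))
  out <- array(0, dim = c(hw[1, 1], hw[2, 1], sum(chans), B))
  at <- 0L
  for (i in seq_along(maps)) {
    out[, , at + seq_len(chans[i]), ] <- maps[[i]]
    at <- at + chans[i]
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    sl <- x[, , at + seq_len(s), , drop = FALSE]
    at <<- at + s
    sl
  })
}

## ---- squeeze-and-excitation --------------------------------------------------

#' Construct a squeeze-and-excitation module
#'
#' A channel-attention unit: the spatial mean of each channel (squeeze) is
#' passed through a two-layer bottleneck (`C -> C/r -> C`) with a ReLU in the
#' middle and a sigmoid gate at the end (excitation), and the resulting
#' per-channel weights rescale the input map.
#'
#' @param channels number of input channels `C`.
#' @param reduction_ratio bottleneck ratio `r`; `C` must be divisible by `r`.
#'   Larger `r` means fewer parameters per module.
#' @param bias logical; carry biases on the two bottleneck layers.
#' @return an object of class `se_module`.
#' @export
se_module <- function(channels, reduction_ratio, bias = TRUE) {
  C <- as.integer(channels)
  r <- as.integer(reduction_ratio)
  if (C < 1L || r < 1L) stop("channels and reduction_ratio must be positive")
  if (C %% r != 0L) {
    stop(sprintf("channels (%d) must be divisible by reduction_ratio (%d)", C, r))
  }
  h <- C %/% r
  b1 <- sqrt(6 / C)
  b2 <- sqrt(6 / h)
  m <- list(
    channels = C, reduction_ratio = r, bias = bias,
    W1 = matrix(stats::runif(h * C, -b1, b1), h, C),
    b1 = if (bias) numeric(h) else NULL,
    W2 = matrix(stats::runif(C * h, -b2, b2), C, h),
    b2 = if (bias) numeric(C) else NULL
  )
  class(m) <- "se_module"
  m
}

#' Squeeze: per-channel spatial mean
#'
#' @param x feature map, `(H, W, C)` or `(H, W, C, B)`.
#' @return length-`C` vector for a single map, `C x B` matrix for a batch.
#' @export
se_squeeze <- function(x) {
  eb <- ensure_batch(x)
  g <- gap_forward(eb$x)$out       # B x C
  if (eb$single) as.vector(g[1L, ]) else t(g)
}

#' Excitation: bottleneck gate producing channel weights in (0, 1)
#'
#' @param z squeezed descriptor: length-`C` vector or `C x B` matrix.
#' @param module an [se_module()].
#' @return channel weights, same shape as `z`, all strictly in (0, 1).
#' @export
se_excite <- function(z, module) {
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, ncol = 1L) else z
  if (nrow(Z) != module$channels) {
    stop(sprintf("se_excite: descriptor length %d != module channels %d",
                 nrow(Z), module$channels))
  }
  h <- module$W1 %*% Z
  if (!is.null(module$b1)) h <- h + module$b1
  h[h < 0] <- 0
  s <- module$W2 %*% h
  if (!is.null(module$b2)) s <- s + module$b2
  s <- sigmoid(s)
  if (single) as.vector(s) else s
}

#' Rescale channels of a feature map by per-channel weights
#'
#' @param x feature map, `(H, W, C)` or `(H, W, C, B)`.
#' @param s length-`C` vector (recycled over the batch) or `C x B` matrix.
#' @return feature map of the same shape with channel `k` multiplied by `s_k`.
#' @export
se_scale <- function(x, s) {
  eb <- ensure_batch(x)
  d <- dim(eb$x)
  if (is.null(dim(s)) && length(s) != d[3]) {
    stop(sprintf("se_scale: weight length %d incompatible with %d channels",
                 length(s), d[3]))
  }
  S <- if (is.null(dim(s))) matrix(s, d[3], d[4]) else s
  if (nrow(S) != d[3] || ncol(S) != d[4]) {
    stop(sprintf("se_scale: weight shape (%d, %d) incompatible with %d channels, batch %d",
                 nrow(S), ncol(S), d[3], d[4]))
  }
  y <- eb$x * rep(as.vector(S), each = d[1] * d[2])
  unbatch(y, eb$single)
}

#' Apply a squeeze-and-excitation module to a feature map
#'
#' Composition `se_scale(x, se_excite(se_squeeze(x), module))`.
#'
#' @inheritParams se_scale
#' @param module an [se_module()].
#' @return rescaled feature map, same shape as `x`.
#' @export
se_forward <- function(x, module) {
  se_scale(x, se_excite(se_squeeze(x), module))
}

# batched forward with cache / backward, used in training
se_fc <- function(module, x) {
  d <- dim(x)
  g <- gap_forward(x)
  Z <- t(g$out)                              # C x B
  pre1 <- module$W1 %*% Z
  if (!is.null(module$b1)) pre1 <- pre1 + module$b1
  h <- pre1
  h[h < 0] <- 0
  pre2 <- module$W2 %*% h
  if (!is.null(module$b2)) pre2 <- pre2 + module$b2
  S <- sigmoid(pre2)                          # C x B
  out <- x * rep(as.vector(S), each = d[1] * d[2])
  list(out = out, cache = list(x = x, Z = Z, h = h, mask1 = pre1 > 0, S = S, dims = d))
}

se_backward <- function(module, cache, dout) {
  d <- cache$dims
  n <- d[1] * d[2]
  S <- cache$S
  dx <- dout * rep(as.vector(S), each = n)
  # dS: per-(channel, image) sum of dout * x
  prod_ <- dout * cache$x
  dim(prod_) <- c(n, d[3] * d[4])
  dS <- matrix(colSums(prod_), d[3], d[4])
  dpre2 <- dS * S * (1 - S)
  grads <- list(W2 = tcrossprod(dpre2, cache$h))
  if (!is.null(module$b2)) grads$b2 <- rowSums(dpre2)
  dh <- crossprod(module$W2, dpre2)
  dpre1 <- dh * cache$mask1
  grads$W1 <- tcrossprod(dpre1, cache$Z)
  if (!is.null(module$b1)) grads$b1 <- rowSums(dpre1)
  dZ <- crossprod(module$W1, dpre1)           # C x B
  dx <- dx + array(rep(as.vector(dZ) / n, each = n), dim = d)
  list(dx = dx, grads = grads)
}

#' Number of parameters of a squeeze-and-excitation module (closed form)
#'
#' `2 C^2 / r`, plus `C + C/r` when the bottleneck layers carry biases.
#'
#' @param channels number of channels `C`.
#' @param reduction_ratio bottleneck ratio `r`.
#' @param bias logical; include bias terms.
#' @return integer parameter count.
#' @export
se_param_count <- function(channels, reduction_ratio, bias = TRUE) {
  C <- channels
  r <- reduction_ratio
  2 * C^2 / r + if (bias) C + C / r else 0
}

## ---- dense blocks ------------------------------------------------------------

#' Configuration of a dense block
#'
#' A dense block stacks `num_layers` composite layers; layer `l` consumes the
#' channel-concatenation of the block input and all previous layers' outputs
#' and emits `growth_rate` new channels.  Each composite layer is the
#' bottleneck variant: BN -> ReLU -> 1x1 conv (to
#' `bottleneck_factor * growth_rate` channels) -> BN -> ReLU -> 3x3 conv
#' (padded, to `growth_rate` channels).
#'
#' @param num_layers number of composite layers `L` (0 gives an identity block).
#' @param growth_rate channels added per layer `k`.
#' @param input_channels channels of the block input.
#' @param bottleneck_factor width of the 1x1 bottleneck in units of `k`.
#' @return an object of class `dense_block_config`.
#' @export
dense_block_config <- function(num_layers, growth_rate, input_channels,
                               bottleneck_factor = 4L) {
  stopifnot(num_layers >= 0, growth_rate >= 1, input_channels >= 1,
            bottleneck_factor >= 1)
  cfg <- list(num_layers = as.integer(num_layers),
              growth_rate = as.integer(growth_rate),
              input_channels = as.integer(input_channels),
              bottleneck_factor = as.integer(bottleneck_factor))
  cfg$output_channels <- cfg$input_channels + cfg$num_layers * cfg$growth_rate
  class(cfg) <- "dense_block_config"
  cfg
}

#' Initialize the weights of a dense block
#'
#' @param cfg a [dense_block_config()].
#' @return an object of class `dense_block` holding one parameter set per layer.
#' @export
dense_block_init <- function(cfg) {
  stopifnot(inherits(cfg, "dense_block_config"))
  k <- cfg$growth_rate
  width <- cfg$bottleneck_factor * k
  layers <- lapply(seq_len(cfg$num_layers), function(l) {
    in_ch <- cfg$input_channels + (l - 1L) * k
    list(bn1 = bn_init(in_ch),
         conv1 = conv2d_init(in_ch, width, 1L),
         bn2 = bn_init(width),
         conv2 = conv2d_init(width, k, 3L, pad = 1L))
  })
  structure(list(cfg = cfg, layers = layers), class = "dense_block")
}

dense_layer_fc <- function(layer, x, training) {
  r1 <- bn2d_forward(layer$bn1, x, training, want_cache = TRUE)
  a1 <- relu_forward(r1$out, want_cache = TRUE)
  c1 <- conv2d_forward(layer$conv1, a1$out, want_cache = TRUE)
  r2 <- bn2d_forward(layer$bn2, c1$out, training, want_cache = TRUE)
  a2 <- relu_forward(r2$out, want_cache = TRUE)
  c2 <- conv2d_forward(layer$conv2, a2$out, want_cache = TRUE)
  layer$bn1 <- r1$layer
  layer$bn2 <- r2$layer
  list(out = c2$out, layer = layer,
       cache = list(bn1 = r1$cache, relu1 = a1$cache, conv1 = c1$cache,
                    bn2 = r2$cache, relu2 = a2$cache, conv2 = c2$cache))
}

dense_layer_bw <- function(layer, cache, dout) {
  b2 <- conv2d_backward(layer$conv2, cache$conv2, dout)
  d <- relu_backward(cache$relu2, b2$dx)
  n2 <- bn2d_backward(layer$bn2, cache$bn2, d)
  b1 <- conv2d_backward(layer$conv1, cache$conv1, n2$dx)
  d <- relu_backward(cache$relu1, b1$dx)
  n1 <- bn2d_backward(layer$bn1, cache$bn1, d)
  list(dx = n1$dx,
       grads = list(bn1 = n1$grads, conv1 = b1$grads,
                    bn2 = n2$grads, conv2 = b2$grads))
}

#' Forward pass of one dense layer
#'
#' Applies the composite function (BN -> ReLU -> 1x1 conv -> BN -> ReLU ->
#' 3x3 conv) to the channel-concatenation of the given feature maps,
#' returning the `growth_rate` new channels.
#'
#' @param inputs list of feature maps sharing the same spatial size (the
#'   block input followed by outputs of earlier layers).
#' @param block a [dense_block_init()] parameter set.
#' @param layer_index 1-based index of the layer to apply.
#' @param training logical; use batch statistics in the BN steps.
#' @return feature map with `growth_rate` channels and unchanged spatial size.
#' @export
dense_layer_forward <- function(inputs, block, layer_index, training = FALSE) {
  stopifnot(inherits(block, "dense_block"))
  if (layer_index < 1L || layer_index > block$cfg$num_layers) {
    stop(sprintf("layer_index %d out of range 1..%d", layer_index,
                 block$cfg$num_layers))
  }
  ebs <- lapply(inputs, ensure_batch)
  single <- ebs[[1L]]$single
  x <- concat_channels(lapply(ebs, `[[`, "x"))
  r <- dense_layer_fc(block$layers[[layer_index]], x, training)
  unbatch(r$out, single)
}

#' Forward pass of a dense block
#'
#' @param x input feature map with `cfg$input_channels` channels.
#' @param block a [dense_block_init()] parameter set.
#' @param training logical; use batch statistics in BN steps.
#' @return feature map with `input_channels + L * growth_rate` channels:
#'   the input concatenated with every layer's output.
#' @export
dense_block_forward <- function(x, block, training = FALSE) {
  stopifnot(inherits(block, "dense_block"))
  eb <- ensure_batch(x)
  d <- dim(eb$x)
  if (d[3] != block$cfg$input_channels) {
    stop(sprintf("dense block expects %d input channels, got %d",
                 block$cfg$input_channels, d[3]))
  }
  feats <- list(eb$x)
  for (l in seq_len(block$cfg$num_layers)) {
    r <- dense_layer_fc(block$layers[[l]], concat_channels(feats), training)
    feats[[l + 1L]] <- r$out
  }
  unbatch(if (length(feats) == 1L) feats[[1L]] else concat_channels(feats),
          eb$single)
}

dense_block_fc <- function(block, x, training) {
  feats <- list(x)
  caches <- vector("list", block$cfg$num_layers)
  for (l in seq_len(block$cfg$num_layers)) {
    r <- dense_layer_fc(block$layers[[l]], concat_channels(feats), training)
    feats[[l + 1L]] <- r$out
    caches[[l]] <- r$cache
    block$layers[[l]] <- r$layer
  }
  out <- if (length(feats) == 1L) feats[[1L]] else concat_channels(feats)
  list(out = out, block = block,
       cache = list(caches = caches,
                    sizes = vapply(feats, function(f) dim(f)[3], integer(1))))
}

dense_block_bw <- function(block, cache, dout) {
  L <- block$cfg$num_layers
  sizes <- cache$sizes
  g <- split_channels(dout, sizes)       # gradients w.r.t. x0, x1, ..., xL
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    r <- dense_layer_bw(block$layers[[l]], cache$caches[[l]], g[[l + 1L]])
    grads[[l]] <- r$grads
    din <- split_channels(r$dx, sizes[seq_len(l)])
    for (j in seq_len(l)) g[[j]] <- g[[j]] + din[[j]]
  }
  list(dx = g[[1L]], grads = list(layers = grads))
}

## ---- transition layers -------------------------------------------------------

#' Initialize a transition layer
#'
#' BN -> ReLU -> 1x1 convolution to `floor(compression * input_channels)`
#' channels -> 2x2 average pooling with stride 2 (floor semantics for odd
#' spatial sizes).
#'
#' @param input_channels channels of the incoming feature map.
#' @param compression channel compression factor in (0, 1].
#' @return an object of class `transition_layer`.
#' @export
transition_init <- function(input_channels, compression = 0.5) {
  if (compression <= 0 || compression > 1) stop("compression must be in (0, 1]")
  out_ch <- max(1L, as.integer(floor(compression * input_channels)))
  structure(list(input_channels = as.integer(input_channels),
                 compression = compression, output_channels = out_ch,
                 bn = bn_init(input_channels),
                 conv = conv2d_init(input_channels, out_ch, 1L)),
            class = "transition_layer")
}

transition_fc <- function(trans, x, training) {
  r <- bn2d_forward(trans$bn, x, training, want_cache = TRUE)
  a <- relu_forward(r$out, want_cache = TRUE)
  cv <- conv2d_forward(trans$conv, a$out, want_cache = TRUE)
  pl <- avgpool2_forward(cv$out, want_cache = TRUE)
  trans$bn <- r$layer
  list(out = pl$out, trans = trans,
       cache = list(bn = r$cache, relu = a$cache, conv = cv$cache, pool = pl$cache))
}

transition_bw <- function(trans, cache, dout) {
  d <- avgpool2_backward(cache$pool, dout)
  cv <- conv2d_backward(trans$conv, cache$conv, d)
  d <- relu_backward(cache$relu, cv$dx)
  bn <- bn2d_backward(trans$bn, cache$bn, d)
  list(dx = bn$dx, grads = list(bn = bn$grads, conv = cv$grads))
}

#' Forward pass of a transition layer
#'
#' @param x input feature map.
#' @param trans a [transition_init()] parameter set.
#' @param training logical; use batch statistics in the BN step.
#' @return feature map with `floor(compression * C)` channels and halved
#'   spatial size.
#' @export
transition_forward <- function(x, trans, training = FALSE) {
  stopifnot(inherits(trans, "transition_layer"))
  eb <- ensure_batch(x)
  if (dim(eb$x)[3] != trans$input_channels) {
    stop(sprintf("transition expects %d input channels, got %d",
                 trans$input_channels, dim(eb$x)[3]))
  }
  unbatch(transition_fc(trans, eb$x, training)$out, eb$single)
}

## ---- classification branch ---------------------------------------------------

#' Initialize a classification branch
#'
#' Global average pooling followed by a batch normalization over the pooled
#' feature vector.  Each branch keeps its own BN running statistics.  With
#' `aux_head = TRUE` the branch also carries a small fully connected head
#' used for deep supervision during training.
#'
#' @param channels channels of the tapped feature map.
#' @param num_classes classes of the optional auxiliary head.
#' @param aux_head logical; attach an auxiliary softmax head.
#' @return an object of class `class_branch`.
#' @export
class_branch_init <- function(channels, num_classes = 2L, aux_head = FALSE) {
  structure(list(channels = as.integer(channels),
                 bn = bn_init(channels),
                 aux = if (aux_head) linear_init(channels, num_classes) else NULL),
            class = "class_branch")
}

branch_fc <- function(branch, x, training) {
  g <- gap_forward(x)
  r <- bn_forward_mat(branch$bn, g$out, training, want_cache = TRUE)
  branch$bn <- r$layer
  list(out = r$out, branch = branch,
       cache = list(dims = g$dims, bn = r$cache))
}

branch_bw <- function(branch, cache, dvec) {
  r <- bn_backward_mat(branch$bn, cache$bn, dvec)
  list(dx = gap_backward(cache$dims, r$dx), grads = list(bn = r$grads))
}

#' Forward pass of a classification branch
#'
#' @param x tapped feature map.
#' @param branch a [class_branch_init()] parameter set.
#' @param training logical; use batch statistics (inference uses the
#'   branch's running statistics).
#' @return length-`C` feature vector for a single map, `B x C` matrix for a
#'   batch.
#' @export
classification_branch_forward <- function(x, branch, training = FALSE) {
  stopifnot(inherits(branch, "class_branch"))
  eb <- ensure_batch(x)
  out <- branch_fc(branch, eb$x, training)$out
  if (eb$single) as.vector(out[1L, ]) else out
}

## ---- softmax and loss --------------------------------------------------------

#' Numerically stable softmax
#'
#' `softmax(z)_j = exp(z_j) / sum_k exp(z_k)`, evaluated after subtracting
#' the row maximum so the result is invariant to constant shifts of `z`.
#'
#' @param z numeric vector of logits, or a matrix with one row per sample.
#' @return probabilities of the same shape; each (row) sums to 1.
#' @export
softmax <- function(z) {
  if (is.null(dim(z))) {
    e <- exp(z - max(z))
    return(e / sum(e))
  }
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}

#' Binary cross-entropy loss
#'
#' `-(y * log(p) + (1 - y) * log(1 - p))` with `p` clamped to
#' `[eps, 1 - eps]` so the loss is finite at p in {0, 1}.
#'
#' @param y true label(s), 0 or 1.
#' @param p predicted probability of class 1, in `[0, 1]`.
#' @param eps clamping constant.
#' @return mean loss over the supplied labels (scalar, >= 0).
#' @export
cross_entropy <- function(y, p, eps = 1e-7) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)),
            all(p >= 0 & p <= 1))
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}
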