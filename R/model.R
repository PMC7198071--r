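# Assembly of the full network: a densely connected trunk (stem, four dense
# blocks, three transition layers), squeeze-and-excitation modules on the
# four taps (after each transition and after the last dense block), one
# classification branch per tap, and a final fully connected head over the
# concatenated branch features.

#' Architectural configuration
#'
#' Defaults reproduce the standard DenseNet-121 trunk (growth rate 32, block
#' depths 6/12/24/16, compression 0.5, 7x7 stride-2 stem convolution with
#' 3x3 stride-2 max pooling) with squeeze-and-excitation taps of reduction
#' ratio 8 and a binary head.  The growth rate, depths and input size are
#' fully configurable so reduced desk-scale variants can be built.
#'
#' @param growth_rate channels added per dense layer (`k`).
#' @param block_depths integer vector of dense-layer counts per block.
#' @param compression transition-layer channel compression in (0, 1].
#' @param reduction_ratio SE bottleneck ratio `r`; every tap's channel count
#'   must be divisible by it.
#' @param num_classes number of output classes.
#' @param input_size spatial side of the (square) input image.
#' @param input_channels image channels (3 for RGB).
#' @param stem_channels channels of the stem convolution; default `2 * k`.
#' @param bottleneck_factor dense-layer 1x1 bottleneck width in units of `k`.
#' @param se_placement `"branch"` (SE applied off-path, only on the branch
#'   input; the trunk is unmodified) or `"in_path"` (the SE output also feeds
#'   the next stage of the trunk).
#' @param se_bias carry biases on SE bottleneck layers.
#' @param deep_supervision attach auxiliary per-branch softmax heads whose
#'   losses are averaged into the training objective.
#' @return an object of class `idsnet_config`.
#' @export
model_config <- function(growth_rate = 32L,
                         block_depths = c(6L, 12L, 24L, 16L),
                         compression = 0.5,
                         reduction_ratio = 8L,
                         num_classes = 2L,
                         input_size = 224L,
                         input_channels = 3L,
                         stem_channels = 2L * growth_rate,
                         bottleneck_factor = 4L,
                         se_placement = c("branch", "in_path"),
                         se_bias = TRUE,
                         deep_supervision = FALSE) {
  se_placement <- match.arg(se_placement)
  stopifnot(growth_rate >= 1, length(block_depths) >= 1, all(block_depths >= 0),
            compression > 0, compression <= 1, reduction_ratio >= 1,
            num_classes >= 2, input_size >= 32, input_channels >= 1,
            stem_channels >= 1, bottleneck_factor >= 1)
  cfg <- list(growth_rate = as.integer(growth_rate),
              block_depths = as.integer(block_depths),
              compression = compression,
              reduction_ratio = as.integer(reduction_ratio),
              num_classes = as.integer(num_classes),
              input_size = as.integer(input_size),
              input_channels = as.integer(input_channels),
              stem_channels = as.integer(stem_channels),
              bottleneck_factor = as.integer(bottleneck_factor),
              se_placement = se_placement,
              se_bias = se_bias,
              deep_supervision = deep_supervision)
  class(cfg) <- "idsnet_config"
  tr <- idsnet_trace(cfg)
  bad <- which(tr$taps$channels %% cfg$reduction_ratio != 0L)
  if (length(bad)) {
    stop(sprintf(
      "tap %d (%s) has %d channels, not divisible by reduction_ratio %d",
      bad[1], tr$taps$stage[bad[1]], tr$taps$channels[bad[1]],
      cfg$reduction_ratio))
  }
  cfg
}

conv_out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

#' Channel and spatial-size trace of the architecture
#'
#' Walks the shape arithmetic of every stage (stem, dense blocks,
#' transitions) for a given configuration without building any weights.
#'
#' @param cfg an `idsnet_config` (or a bare list with the same fields).
#' @return list with `stages` (data frame: stage, channels, height, width)
#'   and `taps` (data frame restricted to the four tapped stages, plus the
#'   concatenated feature dimension as attribute `concat_dim`).
#' @export
idsnet_trace <- function(cfg) {
  h <- conv_out_size(cfg$input_size, 7L, 2L, 3L)   # stem convolution
  h <- conv_out_size(h, 3L, 2L, 1L)                # stem max pooling
  ch <- cfg$stem_channels
  nb <- length(cfg$block_depths)
  stages <- data.frame(stage = "stem", channels = ch, height = h, width = h,
                       stringsAsFactors = FALSE)
  taps <- NULL
  for (i in seq_len(nb)) {
    ch <- ch + cfg$block_depths[i] * cfg$growth_rate
    stages <- rbind(stages, data.frame(stage = sprintf("dense_block_%d", i),
                                       channels = ch, height = h, width = h))
    if (i < nb) {
      ch <- max(1L, as.integer(floor(cfg$compression * ch)))
      h <- h %/% 2L
      stages <- rbind(stages, data.frame(stage = sprintf("transition_%d", i),
                                         channels = ch, height = h, width = h))
      taps <- rbind(taps, stages[nrow(stages), ])
    } else {
      taps <- rbind(taps, stages[nrow(stages), ])
    }
  }
  attr(taps, "concat_dim") <- sum(taps$channels)
  list(stages = stages, taps = taps)
}

#' Build the full model
#'
#' @param cfg an [model_config()].
#' @param seed optional integer; seeds the weight initialization.
#' @return an object of class `idsnet` (nested list of layer parameter sets).
#' @export
build_idsnet <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "idsnet_config"))
  build <- function() {
    tr <- idsnet_trace(cfg)
    nb <- length(cfg$block_depths)
    stem <- list(conv = conv2d_init(cfg$input_channels, cfg$stem_channels,
                                    7L, stride = 2L, pad = 3L),
                 bn = bn_init(cfg$stem_channels))
    blocks <- vector("list", nb)
    trans <- vector("list", nb - 1L)
    in_ch <- cfg$stem_channels
    for (i in seq_len(nb)) {
      bc <- dense_block_config(cfg$block_depths[i], cfg$growth_rate, in_ch,
                               cfg$bottleneck_factor)
      blocks[[i]] <- dense_block_init(bc)
      in_ch <- bc$output_channels
      if (i < nb) {
        trans[[i]] <- transition_init(in_ch, cfg$compression)
        in_ch <- trans[[i]]$output_channels
      }
    }
    tap_ch <- tr$taps$channels
    se <- lapply(tap_ch, se_module, reduction_ratio = cfg$reduction_ratio,
                 bias = cfg$se_bias)
    branches <- lapply(tap_ch, class_branch_init,
                       num_classes = cfg$num_classes,
                       aux_head = cfg$deep_supervision)
    fc <- linear_init(sum(tap_ch), cfg$num_classes)
    structure(list(cfg = cfg, stem = stem, blocks = blocks, trans = trans,
                   se = se, branches = branches, fc = fc,
                   tap_channels = tap_ch),
              class = "idsnet")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# full forward pass with optional caches for backpropagation
idsnet_fc <- function(model, x, training = FALSE, want_cache = FALSE) {
  cfg <- model$cfg
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg$input_size || d[2] != cfg$input_size ||
      d[3] != cfg$input_channels) {
    stop(sprintf("expected input (%d, %d, %d, B), got (%s)",
                 cfg$input_size, cfg$input_size, cfg$input_channels,
                 paste(d, collapse = ", ")))
  }
  in_path <- cfg$se_placement == "in_path"
  cv <- conv2d_forward(model$stem$conv, x, want_cache)
  bn <- bn2d_forward(model$stem$bn, cv$out, training, want_cache)
  ac <- relu_forward(bn$out, want_cache)
  mp <- maxpool_forward(ac$out, want_cache = want_cache)
  model$stem$bn <- bn$layer
  cache <- list(stem = list(conv = cv$cache, bn = bn$cache, relu = ac$cache,
                            pool = mp$cache),
                blocks = list(), trans = list(), se = list(), branches = list())
  h <- mp$out
  nb <- length(model$blocks)
  branch_mats <- vector("list", nb)
  for (i in seq_len(nb)) {
    bf <- dense_block_fc(model$blocks[[i]], h, training)
    model$blocks[[i]] <- bf$block
    cache$blocks[[i]] <- bf$cache
    h <- bf$out
    if (i < nb) {
      tf <- transition_fc(model$trans[[i]], h, training)
      model$trans[[i]] <- tf$trans
      cache$trans[[i]] <- tf$cache
      h <- tf$out
    }
    sf <- se_fc(model$se[[i]], h)
    cache$se[[i]] <- sf$cache
    if (in_path) h <- sf$out
    br <- branch_fc(model$branches[[i]], sf$out, training)
    model$branches[[i]] <- br$branch
    cache$branches[[i]] <- br$cache
    branch_mats[[i]] <- br$out
  }
  V <- do.call(cbind, branch_mats)
  fcr <- linear_forward(model$fc, V, want_cache)
  cache$fc <- fcr$cache
  logits <- fcr$out
  probs <- softmax(logits)
  aux <- NULL
  if (cfg$deep_supervision) {
    aux <- lapply(seq_len(nb), function(i) {
      al <- linear_forward(model$branches[[i]]$aux, branch_mats[[i]], want_cache)
      list(logits = al$out, probs = softmax(al$out), cache = al$cache)
    })
    if (want_cache) cache$aux <- lapply(aux, `[[`, "cache")
  }
  list(probs = probs, logits = logits, aux = aux, model = model,
       cache = if (want_cache) cache else NULL)
}

#' Forward pass
#'
#' @param model an [build_idsnet()] model.
#' @param x input batch `(H, W, C, B)` or a single image `(H, W, C)`,
#'   preprocessed to the model's input size.
#' @param training logical; batch-norm layers use batch statistics when TRUE
#'   and their running statistics otherwise.
#' @param return_branches also return per-branch auxiliary probabilities
#'   (requires a model built with `deep_supervision = TRUE`).
#' @return list with `probs` (`B x K`, rows sum to 1) and `logits`; with
#'   `return_branches`, also `branch_probs` (list of `B x K` matrices).
#' @export
idsnet_forward <- function(model, x, training = FALSE, return_branches = FALSE) {
  stopifnot(inherits(model, "idsnet"))
  eb <- ensure_batch(x, "input")
  r <- idsnet_fc(model, eb$x, training = training, want_cache = FALSE)
  out <- list(probs = r$probs, logits = r$logits)
  if (return_branches) out$branch_probs <- lapply(r$aux, `[[`, "probs")
  out
}

# backpropagation through the whole network.
# dlogits: B x K gradient at the final logits; daux: optional list of B x K
# gradients at each auxiliary head's logits.
idsnet_bw <- function(model, cache, dlogits, daux = NULL) {
  cfg <- model$cfg
  in_path <- cfg$se_placement == "in_path"
  nb <- length(model$blocks)
  fcb <- linear_backward(model$fc, cache$fc, dlogits)
  grads <- list(stem = NULL, blocks = vector("list", nb),
                trans = vector("list", max(nb - 1L, 0L)),
                se = vector("list", nb), branches = vector("list", nb),
                fc = fcb$grads)
  dV <- fcb$dx
  at <- 0L
  dvecs <- vector("list", nb)
  for (i in seq_len(nb)) {
    ci <- model$tap_channels[i]
    dvecs[[i]] <- dV[, at + seq_len(ci), drop = FALSE]
    at <- at + ci
    if (!is.null(daux)) {
      ab <- linear_backward(model$branches[[i]]$aux, cache$aux[[i]], daux[[i]])
      dvecs[[i]] <- dvecs[[i]] + ab$dx
      grads$branches[[i]]$aux <- ab$grads
    }
  }
  dtrunk <- NULL   # gradient flowing down the trunk, starts above block nb
  for (i in rev(seq_len(nb))) {
    bb <- branch_bw(model$branches[[i]], cache$branches[[i]], dvecs[[i]])
    grads$branches[[i]]$bn <- bb$grads$bn
    if (in_path) {
      dse_out <- bb$dx
      if (!is.null(dtrunk)) dse_out <- dse_out + dtrunk
      sb <- se_backward(model$se[[i]], cache$se[[i]], dse_out)
      dtap <- sb$dx
    } else {
      sb <- se_backward(model$se[[i]], cache$se[[i]], bb$dx)
      dtap <- sb$dx
      if (!is.null(dtrunk)) dtap <- dtap + dtrunk
    }
    grads$se[[i]] <- sb$grads
    if (i < nb) {
      tb <- transition_bw(model$trans[[i]], cache$trans[[i]], dtap)
      grads$trans[[i]] <- tb$grads
      dtap <- tb$dx
    }
    blb <- dense_block_bw(model$blocks[[i]], cache$blocks[[i]], dtap)
    grads$blocks[[i]] <- blb$grads
    dtrunk <- blb$dx
  }
  dp <- maxpool_backward(cache$stem$pool, dtrunk)
  dp <- relu_backward(cache$stem$relu, dp)
  bnb <- bn2d_backward(model$stem$bn, cache$stem$bn, dp)
  cvb <- conv2d_backward(model$stem$conv, cache$stem$conv, bnb$dx)
  grads$stem <- list(conv = cvb$grads, bn = bnb$grads)
  grads
}

#' Count model parameters
#'
#' @param model an `idsnet` model.
#' @param trainable_only kept for interface symmetry; every counted
#'   parameter of this model is trainable (batch-norm running statistics are
#'   buffers and never counted).
#' @return list with `total` and a per-component `breakdown`
#'   (trunk, se, branches, final_fc) that sums to the total.
#' @export
count_parameters <- function(model, trainable_only = TRUE) {
  stopifnot(inherits(model, "idsnet"))
  breakdown <- c(
    trunk = n_params(model$stem) + n_params(model$blocks) + n_params(model$trans),
    se = n_params(model$se),
    branches = n_params(model$branches),
    final_fc = n_params(model$fc)
  )
  list(total = sum(breakdown), breakdown = as.list(breakdown))
}

## ---- checkpoints ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are plain serialized R objects holding the configuration and
#' every weight and batch-norm running statistic.
#'
#' @param model an `idsnet` model.
#' @param path file path.
#' @return `load_checkpoint` returns the model; `save_checkpoint` returns
#'   `path` invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "idsnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "idsnet")) stop("not an idsnet checkpoint: ", path)
  model
}

.state_names <- function() c(.param_names, "running_mean", "running_var")

flatten_state <- function(node, prefix = "") {
  out <- list()
  if (!is.list(node)) return(out)
  nm <- names(node)
  for (i in seq_along(node)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    path <- if (nzchar(prefix)) paste(prefix, key, sep = ".") else key
    el <- node[[i]]
    if (is.numeric(el) && key %in% .state_names()) out[[path]] <- el
    else if (is.list(el)) out <- c(out, flatten_state(el, path))
  }
  out
}

assign_state <- function(node, flat, prefix = "") {
  nm <- names(node)
  for (i in seq_along(node)) {
    key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
    path <- if (nzchar(prefix)) paste(prefix, key, sep = ".") else key
    el <- node[[i]]
    if (is.numeric(el) && key %in% .state_names()) node[[i]] <- flat[[path]]
    else if (is.list(el)) node[[i]] <- assign_state(el, flat, path)
  }
  node
}

#' Load pretrained trunk weights into a model
#'
#' Replaces the trunk (stem, dense blocks, transitions) of `model` with the
#' trunk of another checkpoint of identical layout, leaving the SE modules,
#' classification branches and final head at their current initialization.
#' Loading is optional: a freshly built model is fully functional without it.
#'
#' @param model target `idsnet` model.
#' @param source an `idsnet` model or a checkpoint path.
#' @return `model` with the trunk weights replaced.
#' @export
load_pretrained_trunk <- function(model, source) {
  stopifnot(inherits(model, "idsnet"))
  if (is.character(source)) source <- load_checkpoint(source)
  stopifnot(inherits(source, "idsnet"))
  for (part in c("stem", "blocks", "trans")) {
    tgt <- flatten_state(model[[part]], part)
    src <- flatten_state(source[[part]], part)
    if (!identical(names(tgt), names(src))) {
      extra <- c(setdiff(names(src), names(tgt)), setdiff(names(tgt), names(src)))
      stop("trunk layout mismatch at tensor: ", extra[1])
    }
    for (nm in names(tgt)) {
      if (!identical(dim2(tgt[[nm]]), dim2(src[[nm]]))) {
        stop(sprintf("trunk layout mismatch at tensor %s: target %s vs source %s",
                     nm, paste(dim2(tgt[[nm]]), collapse = "x"),
                     paste(dim2(src[[nm]]), collapse = "x")))
      }
    }
    model[[part]] <- assign_state(model[[part]], src, part)
  }
  model
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)
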