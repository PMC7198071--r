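# Training protocol: Adam on the cross-entropy objective with a five-stage
# piecewise-constant learning-rate schedule, optional six-fold
# rotation/mirror augmentation of the training pool, per-epoch validation
# accuracy, and model selection by best validation accuracy.

#' Training configuration
#'
#' Defaults follow the study protocol: 60 epochs, batch size 64, Adam with
#' `beta1 = 0.9` (the stated "momentum"), initial learning rate 3e-3 lowered
#' through five stages (see [lr_schedule()]), six-fold augmented training
#' pool, three seeded repeats.  `transformation_rate` is carried in the
#' configuration for completeness but has no defined semantics and is unused.
#'
#' @param epochs number of epochs.
#' @param batch_size images per optimization step.
#' @param lr_initial initial learning rate.
#' @param lr_boundaries epochs at which a new learning-rate stage begins.
#' @param lr_values learning rate of each stage (`length(lr_boundaries) + 1`
#'   values, non-increasing).
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param augment expand the training pool with the five rotation/mirror
#'   variants of every image.
#' @param input_size,normalize preprocessing applied to all images.
#' @param n_repeats seeded repeats for mean/sd reporting (used by
#'   [run_experiment()]; each repeat re-randomizes split and initialization).
#' @param transformation_rate opaque protocol constant; stored, unused.
#' @param seed base seed for splitting, initialization and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 60L, batch_size = 64L,
                         lr_initial = 3e-3,
                         lr_boundaries = c(25L, 30L, 35L, 40L),
                         lr_values = c(lr_initial, lr_initial / 2,
                                       lr_initial / 4, 3e-5, 1e-5),
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         augment = TRUE, input_size = 224L,
                         normalize = "imagenet", n_repeats = 3L,
                         transformation_rate = 0.05, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr_initial > 0,
            length(lr_values) == length(lr_boundaries) + 1L,
            all(lr_values > 0), all(diff(lr_values) <= 0),
            all(diff(lr_boundaries) > 0), n_repeats >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_initial = lr_initial,
                 lr_boundaries = as.integer(lr_boundaries),
                 lr_values = lr_values,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 augment = augment, input_size = as.integer(input_size),
                 normalize = normalize, n_repeats = as.integer(n_repeats),
                 transformation_rate = transformation_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Staged learning-rate schedule
#'
#' Piecewise constant: with the defaults, epochs 1-24 run at 3e-3, the rate
#' is halved at epoch 25 and again at epoch 30, set to 3e-5 at epoch 35 and
#' to 1e-5 at epoch 40, where it stays for the remaining epochs.
#'
#' @param epoch 1-based epoch index.
#' @param config a [train_config()]; supplies boundaries, values and the
#'   valid epoch range.
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  if (any(epoch < 1L) || any(epoch > config$epochs)) {
    stop(sprintf("epoch out of range 1..%d", config$epochs))
  }
  stage <- findInterval(epoch, config$lr_boundaries) + 1L
  config$lr_values[stage]
}

#' Seed every source of randomness
#'
#' Splitting, weight initialization, shuffling and the synthetic generator
#' all draw from R's global RNG stream; this (re)seeds it.
#'
#' @param seed integer seed.
#' @export
set_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

## ---- Adam ----------------------------------------------------------------

zero_like_tree <- function(g) {
  if (is.numeric(g)) return(g * 0)
  lapply(g, zero_like_tree)
}

add_grads <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  out <- a
  for (i in seq_along(a)) if (!is.null(b[[i]])) out[[i]] <- add_grads(a[[i]], b[[i]])
  out
}

adam_step <- function(params, grads, state, lr, cfg) {
  t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^t
  bc2 <- 1 - cfg$beta2^t
  walk <- function(p, g, m, v) {
    if (is.numeric(g)) {
      m <- cfg$beta1 * m + (1 - cfg$beta1) * g
      v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + cfg$adam_eps)
      return(list(p = p, m = m, v = v))
    }
    keys <- if (!is.null(names(g))) names(g) else seq_along(g)
    for (k in keys) {
      if (is.null(g[[k]])) next
      r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
      p[[k]] <- r$p
      m[[k]] <- r$m
      v[[k]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

## ---- training loop ---------------------------------------------------------

onehot <- function(y, K) {
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

# accuracy of probability rows against integer labels (0-based)
prob_accuracy <- function(probs, y) {
  mean(max.col(probs, ties.method = "first") - 1L == y)
}

#' Train a model
#'
#' Mean cross-entropy over each batch is minimized with Adam; the learning
#' rate follows [lr_schedule()].  After every epoch the validation accuracy
#' is computed in inference mode and the weights with the highest validation
#' accuracy (earliest epoch on ties) are kept.  With `deep_supervision`
#' models, the mean of the per-branch auxiliary losses is added to the
#' objective.
#'
#' @param model an [build_idsnet()] model.
#' @param split a [split_dataset()] result with non-empty train and
#'   validation subsets.
#' @param config a [train_config()].
#' @param verbose emit one log line per epoch via `message()`.
#' @return list of class `train_history`: `model` (best weights), `history`
#'   data frame (epoch, lr, train_loss, train_acc, val_acc), `best_epoch`,
#'   `seed`.
#' @export
train_idsnet <- function(model, split, config = train_config(), verbose = TRUE) {
  stopifnot(inherits(model, "idsnet"), inherits(split, "dataset_split"),
            inherits(config, "train_config"))
  if (nrow(split$train) == 0L) stop("empty training set")
  if (nrow(split$validation) == 0L) stop("empty validation set")
  K <- model$cfg$num_classes
  size <- model$cfg$input_size
  if (size != config$input_size) {
    stop(sprintf("model input size %d != training config input size %d",
                 size, config$input_size))
  }
  tr <- load_images(split$train, size, config$normalize)
  if (config$augment) tr <- augment_batch(tr$x, tr$y)
  va <- load_images(split$validation, size, config$normalize)
  n <- length(tr$y)
  set_seed(config$seed)
  state <- list(m = NULL, v = NULL, t = 0L)
  hist <- data.frame(epoch = integer(), lr = numeric(), train_loss = numeric(),
                     train_acc = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, model = model)
  nb <- length(model$blocks)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config)
    ord <- sample.int(n)
    losses <- numeric(0)
    accs <- numeric(0)
    for (start in seq.int(1L, n, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- tr$x[, , , sel, drop = FALSE]
      yb <- tr$y[sel]
      fw <- idsnet_fc(model, xb, training = TRUE, want_cache = TRUE)
      model <- fw$model
      Y <- onehot(yb, K)
      B <- length(yb)
      loss <- cross_entropy(yb, fw$probs[, 2L])
      dlogits <- (fw$probs - Y) / B
      daux <- NULL
      if (model$cfg$deep_supervision) {
        aux_losses <- vapply(fw$aux, function(a) cross_entropy(yb, a$probs[, 2L]),
                             numeric(1))
        loss <- loss + mean(aux_losses)
        daux <- lapply(fw$aux, function(a) (a$probs - Y) / (B * nb))
      }
      grads <- idsnet_bw(model, fw$cache, dlogits, daux)
      if (is.null(state$m)) {
        state$m <- zero_like_tree(grads)
        state$v <- zero_like_tree(grads)
      }
      st <- adam_step(model, grads, state, lr, config)
      # adam_step walks the gradient tree, so only parameter fields change
      model <- st$params
      state <- st$state
      losses <- c(losses, loss)
      accs <- c(accs, prob_accuracy(fw$probs, yb))
    }
    val_probs <- predict_probs(model, va$x)
    val_acc <- prob_accuracy(val_probs, va$y)
    train_loss <- mean(losses)
    train_acc <- mean(accs)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = train_loss,
                                   train_acc = train_acc, val_acc = val_acc))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = epoch, model = model)
    }
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.2e  train loss %.4f  train acc %.3f  val acc %.3f",
        epoch, lr, train_loss, train_acc, val_acc))
    }
  }
  structure(list(model = best$model, history = hist, best_epoch = best$epoch,
                 seed = config$seed, config = config),
            class = "train_history")
}

# inference forward in batches (bounded memory)
predict_probs <- function(model, x, batch_size = 32L) {
  nB <- dim(x)[4]
  out <- matrix(0, nB, model$cfg$num_classes)
  for (start in seq.int(1L, nB, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, nB)
    r <- idsnet_forward(model, x[, , , sel, drop = FALSE], training = FALSE)
    out[sel, ] <- r$probs
  }
  out
}

#' Predict labels for an image record set
#'
#' @param model a trained `idsnet` model.
#' @param records image record data frame.
#' @param normalize preprocessing mode, as used in training.
#' @return prediction record data frame: `records` plus `pred_label` and
#'   `p_malignant`.
#' @export
predict_idsnet <- function(model, records, normalize = "imagenet") {
  records <- validate_records(records, "records")
  if (nrow(records) == 0L) stop("empty record set")
  im <- load_images(records, model$cfg$input_size, normalize)
  probs <- predict_probs(model, im$x)
  records$pred_label <- .labels[max.col(probs, ties.method = "first")]
  records$p_malignant <- probs[, 2L]
  records
}

#' Run the full protocol: split, train, evaluate, repeat
#'
#' Performs `config$n_repeats` seeded repeats; each repeat re-randomizes
#' both the dataset split and the weight initialization (seed `base + i`),
#' trains, and evaluates recognition rates on its test split.
#'
#' @param records image record data frame.
#' @param model_cfg an [model_config()].
#' @param config a [train_config()].
#' @param fractions,split_mode forwarded to [split_dataset()].
#' @param verbose forwarded to [train_idsnet()].
#' @return list with `reports` (one [evaluate_by_magnification()] report per
#'   repeat), `aggregate` (mean/sd table, when more than one repeat),
#'   `histories`, and `models`.
#' @export
run_experiment <- function(records, model_cfg, config = train_config(),
                           fractions = c(0.5, 0.2, 0.3),
                           split_mode = "image", verbose = TRUE) {
  reports <- list()
  histories <- list()
  models <- list()
  for (i in seq_len(config$n_repeats)) {
    seed_i <- config$seed + i - 1L
    split <- split_dataset(records, fractions, seed = seed_i, mode = split_mode)
    model <- build_idsnet(model_cfg, seed = seed_i)
    cfg_i <- config
    cfg_i$seed <- seed_i
    fit <- train_idsnet(model, split, cfg_i, verbose = verbose)
    preds <- predict_idsnet(fit$model, split$test, config$normalize)
    reports[[i]] <- evaluate_by_magnification(preds)
    histories[[i]] <- fit$history
    models[[i]] <- fit$model
  }
  list(reports = reports,
       aggregate = if (length(reports) >= 2L) aggregate_runs(reports) else NULL,
       histories = histories, models = models)
}
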