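# Model assembly: shape trace, forward behaviour, parameter accounting,
# SE placement, checkpoints.

tiny_cfg <- function(...) {
  model_config(growth_rate = 4L, block_depths = c(2L, 2L, 2L, 2L),
               reduction_ratio = 2L, input_size = 64L, ...)
}

test_that("default configuration traces to the canonical channel/size table", {
  tr <- idsnet_trace(model_config())
  expect_equal(tr$taps$channels, c(128L, 256L, 512L, 1024L))
  expect_equal(tr$taps$height, c(28L, 14L, 7L, 7L))
  expect_equal(tr$taps$width, c(28L, 14L, 7L, 7L))
  expect_equal(attr(tr$taps, "concat_dim"), 1920L)
  expect_equal(tr$stages$channels[tr$stages$stage == "dense_block_1"], 256L)
})

test_that("configuration validation names the offending tap", {
  expect_error(model_config(growth_rate = 4L, block_depths = c(1L, 1L, 1L, 1L),
                            reduction_ratio = 2L, input_size = 64L),
               "transition_2.*divisible")
})

test_that("forward yields per-image probability rows, deterministically", {
  set.seed(30)
  m <- build_idsnet(tiny_cfg(), seed = 4)
  one <- array(runif(64 * 64 * 3), c(64, 64, 3))
  x <- array(0, c(64, 64, 3, 2))
  x[, , , 1] <- one
  x[, , , 2] <- one
  r <- idsnet_forward(m, x)
  expect_equal(dim(r$probs), c(2L, 2L))
  expect_equal(rowSums(r$probs), c(1, 1), tolerance = 1e-6)
  expect_equal(r$probs[1, ], r$probs[2, ])           # identical inputs
  expect_equal(idsnet_forward(m, x)$probs, r$probs)  # deterministic

  # permutation equivariance over the batch
  xb <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  p <- idsnet_forward(m, xb)$probs
  perm <- c(3L, 1L, 2L)
  p2 <- idsnet_forward(m, xb[, , , perm])$probs
  expect_equal(p2, p[perm, ], tolerance = 1e-12)

  # all-zero final head: softmax of zeros
  m0 <- m
  m0$fc$W[] <- 0
  m0$fc$b[] <- 0
  expect_true(all(abs(idsnet_forward(m0, xb)$probs - 0.5) < 1e-12))

  expect_error(idsnet_forward(m, array(0, c(32, 32, 3, 1))), "expected input")
})

test_that("parameter count equals an independent per-layer ledger", {
  cfg <- tiny_cfg()
  m <- build_idsnet(cfg, seed = 1)
  tr <- idsnet_trace(cfg)
  k <- cfg$growth_rate
  width <- cfg$bottleneck_factor * k
  # independent ledger from the architecture arithmetic alone
  conv_p <- function(kh, cin, cout) kh * kh * cin * cout + cout
  bn_p <- function(c) 2 * c
  ledger <- conv_p(7, 3, cfg$stem_channels) + bn_p(cfg$stem_channels)
  ch <- cfg$stem_channels
  for (i in seq_along(cfg$block_depths)) {
    for (l in seq_len(cfg$block_depths[i])) {
      cin <- ch + (l - 1) * k
      ledger <- ledger + bn_p(cin) + conv_p(1, cin, width) +
        bn_p(width) + conv_p(3, width, k)
    }
    ch <- ch + cfg$block_depths[i] * k
    if (i < length(cfg$block_depths)) {
      out <- floor(cfg$compression * ch)
      ledger <- ledger + bn_p(ch) + conv_p(1, ch, out)
      ch <- out
    }
  }
  taps <- tr$taps$channels
  ledger <- ledger + sum(se_param_count(taps, cfg$reduction_ratio, TRUE)) +
    sum(bn_p(taps)) + (sum(taps) * cfg$num_classes + cfg$num_classes)
  pc <- count_parameters(m)
  expect_equal(pc$total, ledger)
  expect_equal(pc$total, Reduce(`+`, pc$breakdown))
})

test_that("parameter count is invariant to configured input size", {
  a <- count_parameters(build_idsnet(tiny_cfg(), seed = 1))$total
  b <- count_parameters(build_idsnet(
    model_config(growth_rate = 4L, block_depths = c(2L, 2L, 2L, 2L),
                 reduction_ratio = 2L, input_size = 96L), seed = 1))$total
  expect_equal(a, b)
})

test_that("SE weights affect trunk activations only with in-path placement", {
  set.seed(31)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  probe <- function(placement) {
    m <- build_idsnet(tiny_cfg(se_placement = placement), seed = 6)
    m_zero <- m
    for (i in seq_along(m_zero$se)) {
      m_zero$se[[i]]$W1[] <- 0
      m_zero$se[[i]]$W2[] <- 0
      m_zero$se[[i]]$b1[] <- 0
      m_zero$se[[i]]$b2[] <- 0
    }
    # the SE cache's x field is the trunk tensor feeding the last tap
    r1 <- idsnet:::idsnet_fc(m, x, want_cache = TRUE)$cache$se[[4]]$x
    r2 <- idsnet:::idsnet_fc(m_zero, x, want_cache = TRUE)$cache$se[[4]]$x
    list(same_trunk = isTRUE(all.equal(r1, r2)),
         same_probs = isTRUE(all.equal(idsnet_forward(m, x)$probs,
                                       idsnet_forward(m_zero, x)$probs)))
  }
  off_path <- probe("branch")
  expect_true(off_path$same_trunk)      # trunk untouched by SE weights
  expect_false(off_path$same_probs)     # but the branches see them
  in_path <- probe("in_path")
  expect_false(in_path$same_trunk)      # trunk activations change too
})

test_that("classification branch is a batch-normalized global average", {
  set.seed(32)
  br <- class_branch_init(5L)
  # inference with fresh running stats (mean 0, var 1) is near-identity
  x <- array(1.75, c(6, 6, 5))
  v <- classification_branch_forward(x, br)
  expect_equal(v, rep(1.75, 5), tolerance = 1e-4)
  expect_length(v, 5L)
  # BN affine law in training mode: gamma * normalized + beta
  br$bn$gamma <- rep(2, 5)
  br$bn$beta <- rep(1, 5)
  xb <- rand_fmap(4, 4, 5, B = 3)
  got <- classification_branch_forward(xb, br, training = TRUE)
  g <- t(apply(xb, 4, function(a) colMeans(matrix(a, 16, 5))))
  vhat <- scale(g, center = TRUE,
                scale = sqrt(apply(g, 2, function(c) mean((c - mean(c))^2)) + 1e-5))
  expect_equal(got, 2 * unclass(vhat)[, ] + 1, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("checkpoints round-trip and trunk loading validates layout", {
  m <- build_idsnet(tiny_cfg(), seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(count_parameters(m2)$total, count_parameters(m)$total)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  expect_equal(idsnet_forward(m2, x)$probs, idsnet_forward(m, x)$probs)

  fresh <- build_idsnet(tiny_cfg(), seed = 8)
  loaded <- load_pretrained_trunk(fresh, path)
  expect_equal(loaded$blocks[[1]]$layers[[1]]$conv2$W,
               m$blocks[[1]]$layers[[1]]$conv2$W)
  expect_equal(loaded$fc$W, fresh$fc$W)    # head stays freshly initialized
  expect_false(isTRUE(all.equal(loaded$se[[1]]$W1, m$se[[1]]$W1)))

  other <- build_idsnet(model_config(growth_rate = 8L,
                                     block_depths = c(2L, 2L, 2L, 2L),
                                     reduction_ratio = 2L, input_size = 64L),
                        seed = 9)
  expect_error(load_pretrained_trunk(other, path), "mismatch at tensor")
})
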