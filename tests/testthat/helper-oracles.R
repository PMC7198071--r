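# Shared fixtures and independent oracles used across test files.
# Oracles are deliberately naive (explicit loops, textbook formulas) and
# share no code with the implementation they check.

rand_fmap <- function(H, W, C, B = NULL, sd = 1) {
  if (is.null(B)) array(stats::rnorm(H * W * C, sd = sd), dim = c(H, W, C))
  else array(stats::rnorm(H * W * C * B, sd = sd), dim = c(H, W, C, B))
}

# direct nested-loop 2-d convolution on an (H, W, Cin, B) array
naive_conv <- function(x, W, b, stride, pad) {
  d <- dim(x)
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  Hp <- d[1] + 2 * pad; Wp <- d[2] + 2 * pad
  xp <- array(0, c(Hp, Wp, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  Ho <- (Hp - kh) %/% stride + 1
  Wo <- (Wp - kw) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout, d[4]))
  for (bb in seq_len(d[4])) for (co in seq_len(Cout)) {
    for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) {
      r0 <- (oi - 1) * stride; c0 <- (oj - 1) * stride
      patch <- xp[r0 + seq_len(kh), c0 + seq_len(kw), , bb, drop = FALSE]
      dim(patch) <- c(kh, kw, d[3])
      out[oi, oj, co, bb] <- sum(patch * array(W[, , , co], c(kh, kw, d[3]))) +
        (if (is.null(b)) 0 else b[co])
    }
  }
  out
}

# batch normalization with batch statistics (biased variance), per channel
naive_bn <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  out <- x
  for (c_ in seq_len(d[3])) {
    v <- x[, , c_, ]
    mu <- mean(v)
    s2 <- mean((v - mu)^2)
    out[, , c_, ] <- gamma[c_] * (v - mu) / sqrt(s2 + eps) + beta[c_]
  }
  out
}

# textbook squeeze -> excite -> scale with explicit loops
naive_se <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  C <- d[3]
  z <- numeric(C)
  for (k in seq_len(C)) {
    acc <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) acc <- acc + x[i, j, k]
    z[k] <- acc / (d[1] * d[2])
  }
  h <- as.vector(W1 %*% z) + (if (is.null(b1)) 0 else b1)
  h <- pmax(h, 0)
  s <- as.vector(W2 %*% h) + (if (is.null(b2)) 0 else b2)
  s <- 1 / (1 + exp(-s))
  out <- x
  for (k in seq_len(C)) out[, , k] <- x[, , k] * s[k]
  out
}

# central finite difference of f at x (works for vectors and arrays)
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# synthetic image-record data frame (no files behind the paths)
make_records <- function(n_patients = 6L, images_per = 4L,
                         mags = c(40L, 100L, 200L, 400L), seed = 1L) {
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_patients)) {
      lb <- if (p <= n_patients / 2) "benign" else "malignant"
      pid <- sprintf("%02d-%04d", p, 1000 + p)
      for (i in seq_len(images_per)) {
        mag <- sample(mags, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          path = sprintf("img_%s_%03d.png", pid, i), label = lb,
          patient_id = pid, magnification = mag, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# the standing worked example: patient A 3/4 correct, patient B 1/2 correct
two_patient_fixture <- function() {
  data.frame(
    path = sprintf("p%d.png", 1:6),
    label = rep("malignant", 6),
    patient_id = c(rep("A", 4), rep("B", 2)),
    magnification = rep(40L, 6),
    pred_label = c("malignant", "malignant", "malignant", "benign",
                   "malignant", "benign"),
    p_malignant = c(0.9, 0.9, 0.9, 0.1, 0.9, 0.1),
    stringsAsFactors = FALSE
  )
}
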