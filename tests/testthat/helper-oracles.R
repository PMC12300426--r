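# Independent oracles and small shared fixtures for the test suite.

# Brute-force Euclidean distance transform: distance of every pixel to the
# nearest foreground pixel, by exhaustive search.
brute_edt <- function(mask) {
  fg <- which(mask > 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- sqrt(min((i - fg[, 1])^2 + (j - fg[, 2])^2))
    }
  }
  out
}

# Brute-force mean-min pairwise-distance Hausdorff term on foreground sets:
# mean over p in P of min over g in G of ||p - g||, both directions, summed.
brute_hausdorff <- function(p_mask, g_mask) {
  p <- which(p_mask > 0, arr.ind = TRUE)
  g <- which(g_mask > 0, arr.ind = TRUE)
  directed <- function(a, b) {
    mean(vapply(seq_len(nrow(a)), function(i) {
      sqrt(min((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2))
    }, numeric(1)))
  }
  directed(p, g) + directed(g, p)
}

# Literal step-by-step transcription of the controller equations (pooled
# grid, Q/K/V projection, scaled dot-product softmax attention, spatial
# mean, two dense layers, softmax), written with plain loops and
# independent of the package's graph engine.
aac_reference <- function(x, params) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  hp <- params$downsample
  wq <- params$wq$value; wk <- params$wk$value; wv <- params$wv$value
  w1 <- params$fc1$w$value; b1 <- as.vector(params$fc1$b$value)
  w2 <- params$fc2$w$value; b2 <- as.vector(params$fc2$b$value)
  out <- matrix(0, B, 2)
  for (b in seq_len(B)) {
    # Step 1: adaptive average pooling to hp x hp
    pooled <- array(0, dim = c(hp, hp, C))
    for (c_i in seq_len(C)) {
      for (oh in seq_len(hp)) {
        for (ow in seq_len(hp)) {
          h0 <- floor((oh - 1) * H / hp) + 1
          h1 <- ceiling(oh * H / hp)
          w0 <- floor((ow - 1) * W / hp) + 1
          w1r <- ceiling(ow * W / hp)
          pooled[oh, ow, c_i] <- mean(x[h0:h1, w0:w1r, c_i, b])
        }
      }
    }
    # Step 2: sequence of N = hp^2 C-vectors
    n <- hp * hp
    f_seq <- matrix(0, n, C)
    for (c_i in seq_len(C)) f_seq[, c_i] <- as.vector(pooled[, , c_i])
    # Steps 3-5: self-attention
    q <- f_seq %*% wq; k <- f_seq %*% wk; v <- f_seq %*% wv
    scores <- q %*% t(k) / sqrt(C)
    a <- matrix(0, n, n)
    for (i in seq_len(n)) {
      e <- exp(scores[i, ] - max(scores[i, ]))
      a[i, ] <- e / sum(e)
    }
    f_sa <- a %*% v
    # Step 6: spatial mean
    f_global <- colMeans(f_sa)
    # Steps 7-9: dense -> ReLU -> dense -> softmax
    h <- pmax(as.vector(f_global %*% w1) + b1, 0)
    z <- as.vector(h %*% w2) + b2
    e <- exp(z - max(z))
    out[b, ] <- e / sum(e)
  }
  out
}

# A deliberately small network configuration for fast pipeline tests.
tiny_config <- function(input_size = 16L, aac_enabled = TRUE) {
  network_config(input_size = input_size,
                 stage_channels = c(4L, 6L, 8L, 12L),
                 aspp_dilations = c(1L),
                 aac_enabled = aac_enabled,
                 final_aspp = FALSE)
}

# random soft blob mask pair used by loss property tests
random_blob_mask <- function(n, seed, density = 0.25) {
  set.seed(seed)
  (matrix(runif(n * n), n, n) < density) * 1
}
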