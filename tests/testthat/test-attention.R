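# Adaptive Attention Controller, channel/position attention, and fusion.

test_that("controller weights always lie on the 1-simplex", {
  set.seed(21)
  ap <- aac_params(6)
  for (i in 1:10) {
    x <- array(rnorm(12 * 12 * 6 * 3, sd = runif(1, 0.1, 5)),
               c(12, 12, 6, 3))
    w <- aac_forward(x, ap)
    expect_equal(dim(w), c(3L, 2L))
    expect_true(all(w >= 0))
    expect_equal(rowSums(w), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("a zeroed output layer yields the (0.5, 0.5) fixed point", {
  set.seed(22)
  ap <- aac_params(8)
  ap$fc2$w$value[] <- 0
  ap$fc2$b$value[] <- 0
  x <- array(rnorm(16 * 16 * 8 * 4), c(16, 16, 8, 4))
  w <- aac_forward(x, ap)
  expect_equal(w, matrix(0.5, 4, 2), tolerance = 1e-12)
})

test_that("controller forward matches a literal step-by-step reference", {
  set.seed(23)
  ap <- aac_params(6, downsample = 4L)
  x <- array(rnorm(10 * 14 * 6 * 3), c(10, 14, 6, 3))
  expect_equal(aac_forward(x, ap), aac_reference(x, ap), tolerance = 1e-6)
  # and at the default 8x8 grid
  ap8 <- aac_params(4)
  x8 <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  expect_equal(aac_forward(x8, ap8), aac_reference(x8, ap8),
               tolerance = 1e-6)
})

test_that("controller output is pooling-invariant to upsampled inputs", {
  set.seed(24)
  ap <- aac_params(5)
  x <- array(rnorm(8 * 8 * 5 * 2), c(8, 8, 5, 2))
  up <- array(0, c(16, 16, 5, 2))
  for (i in 1:16) for (j in 1:16) {
    up[i, j, , ] <- x[ceiling(i / 2), ceiling(j / 2), , ]
  }
  expect_equal(aac_forward(x, ap), aac_forward(up, ap), tolerance = 1e-9)
})

test_that("controller rejects single-channel features", {
  expect_error(aac_params(1), "at least 2")
})

test_that("channel attention preserves shape and channel symmetry", {
  set.seed(25)
  x <- array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2))
  cp <- ca_params(5)
  cp$gamma$value <- 0.7   # make the attention path active
  y <- channel_attention(x, cp)
  expect_equal(dim(y), dim(x))
  # permuting channels and inverse-permuting the output is a no-op
  perm <- c(3, 1, 5, 2, 4)
  yp <- channel_attention(x[, , perm, , drop = FALSE], cp)
  expect_equal(yp[, , order(perm), , drop = FALSE], y, tolerance = 1e-6)
})

test_that("channel attention is the identity on one channel at init", {
  x <- array(runif(7 * 7), c(7, 7, 1, 1))
  expect_equal(channel_attention(x, ca_params(1)), x, tolerance = 1e-12)
})

test_that("position attention preserves shape and spatial structure", {
  set.seed(26)
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  pp <- pa_params(8)
  pp$gamma$value <- 0.5
  y <- position_attention(x, pp)
  expect_equal(dim(y), dim(x))
  # spatially constant input stays spatially constant
  xc <- array(rep(rnorm(8), each = 36), c(6, 6, 8, 1))
  yc <- position_attention(xc, pp)
  for (ch in 1:8) {
    expect_lt(diff(range(yc[, , ch, 1])), 1e-5)
  }
})

test_that("position attention commutes with toroidal translation", {
  set.seed(27)
  x <- array(rnorm(7 * 7 * 8), c(7, 7, 8, 1))
  pp <- pa_params(8)
  pp$gamma$value <- 0.9
  roll <- function(a, dr, dc) {
    a[((seq_len(7) - 1 - dr) %% 7) + 1, ((seq_len(7) - 1 - dc) %% 7) + 1, ,
      , drop = FALSE]
  }
  y <- position_attention(x, pp)
  y_shift <- position_attention(roll(x, 2, 3), pp)
  expect_equal(y_shift, roll(y, 2, 3), tolerance = 1e-6)
})

test_that("fusion is the convex combination it claims to be", {
  set.seed(28)
  a <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  b <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  w10 <- matrix(c(1, 1, 0, 0), 2)
  expect_identical(aaf_fuse(a, b, w10), a)
  expect_equal(aaf_fuse(a, b, matrix(0.5, 2, 2)), (a + b) / 2,
               tolerance = 1e-12)
  for (i in 1:10) {
    w1 <- runif(2)
    w <- cbind(w1, 1 - w1)
    y <- aaf_fuse(a, b, w)
    expect_true(all(y >= pmin(a, b) - 1e-12 & y <= pmax(a, b) + 1e-12))
  }
  # identical branches are a fixed point for any simplex weights
  expect_equal(aaf_fuse(a, a, cbind(c(0.3, 0.8), c(0.7, 0.2))), a,
               tolerance = 1e-12)
  expect_error(aaf_fuse(a, b, matrix(0.5, 3, 2)), "batch")
  expect_error(aaf_fuse(a, b, matrix(c(0.9, 0.9, 0.4, 0.4), 2)), "sum to 1")
})
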