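# Residual blocks, ASPP, and the assembled encoder-decoder network.

test_that("residual block preserves spatial size and supports striding", {
  set.seed(31)
  x <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  y <- residual_block(x, out_channels = 6)
  expect_equal(dim(y), c(16L, 16L, 6L, 2L))
  y2 <- residual_block(x, out_channels = 6, stride = 2)
  expect_equal(dim(y2), c(8L, 8L, 6L, 2L))
})

test_that("residual block with zeroed conv path is the identity", {
  set.seed(32)
  blk <- caafseg:::new_resblock(3, 3, 1L)
  for (p in caafseg:::collect_params(blk)) {
    if (length(dim(p$value)) == 4L) p$value[] <- 0   # conv weights only
  }
  x <- array(runif(10 * 10 * 3 * 2), c(10, 10, 3, 2))  # non-negative input
  y <- residual_block(x, 3, block = blk, training = TRUE)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("gradient reaches the input through the shortcut", {
  set.seed(33)
  blk <- caafseg:::new_resblock(2, 2, 1L)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  xt <- caafseg:::ag_tensor(x, requires_grad = TRUE)
  caafseg:::ag_reset_tape()
  out <- caafseg:::resblock_fwd(blk, xt, training = TRUE)
  caafseg:::ag_backward(caafseg:::ag_mean_all(out))
  expect_false(is.null(xt$grad))
  expect_gt(sum(xt$grad != 0), 0)
})

test_that("ASPP preserves shape and spatial constancy", {
  set.seed(34)
  x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  expect_warning(y <- aspp(x, dilations = c(6, 12, 18)),
                 "dilation")
  expect_equal(dim(y), dim(x))
  mod <- caafseg:::new_aspp(6L, c(1L, 2L))
  xc <- array(rep(rnorm(6), each = 64), c(8, 8, 6, 1))
  yc <- aspp(xc, module = mod, training = TRUE)
  for (ch in 1:6) expect_lt(diff(range(yc[, , ch, 1])), 1e-6)
})

test_that("the pooled global branch of ASPP is live", {
  set.seed(35)
  mod <- caafseg:::new_aspp(4L, c(1L, 2L))
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  y0 <- aspp(x, module = mod)
  mod$glob$conv$w$value <- mod$glob$conv$w$value + 0.5
  y1 <- aspp(x, module = mod)
  expect_gt(max(abs(y1 - y0)), 1e-8)
})

test_that("forward pass follows the published feature-map schedule", {
  set.seed(36)
  model <- caaf_resunet()
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  out <- suppressWarnings(caafseg:::ag_no_grad(
    caafseg:::model_forward(model, x)))
  shapes <- out$stages
  spatial <- t(vapply(shapes, function(d) d[1:2], numeric(2)))
  chans <- vapply(shapes, function(d) d[3], numeric(1))
  # encoder 64 -> 32 -> 16 -> 8, bridge 8, decoder 16 -> 32 -> 64
  expect_equal(spatial[, 1], c(64, 32, 16, 8, 8, 16, 32, 64))
  expect_equal(chans, c(32, 64, 128, 256, 256, 128, 64, 32))
  expect_equal(dim(out$prob$value), c(64L, 64L, 1L, 2L))
  expect_true(all(out$prob$value >= 0 & out$prob$value <= 1))
})

test_that("indivisible input sizes are rejected with the divisor named", {
  model <- caaf_resunet(tiny_config())
  x <- array(runif(20 * 20), c(20, 20, 1, 1))
  expect_error(suppressWarnings(predict(model, x)), "divisible by 8")
})

test_that("identical seeds give bitwise-identical parameters", {
  m1 <- caaf_resunet(tiny_config(), seed = 99)
  m2 <- caaf_resunet(tiny_config(), seed = 99)
  p1 <- caafseg:::collect_params(m1$modules)
  p2 <- caafseg:::collect_params(m2$modules)
  expect_identical(names(p1), names(p2))
  for (nm in names(p1)) expect_identical(p1[[nm]]$value, p2[[nm]]$value)
  m3 <- caaf_resunet(tiny_config(), seed = 100)
  p3 <- caafseg:::collect_params(m3$modules)
  expect_gt(max(abs(p1[["head.w"]]$value - p3[["head.w"]]$value)), 0)
})

test_that("one backward pass reaches every trainable parameter", {
  set.seed(37)
  model <- caaf_resunet(tiny_config())
  params <- caafseg:::collect_params(model$modules)
  # open the attention gates: at their zero init the attention branches are
  # exact identities and their internal projections legitimately receive
  # zero gradient, so connectivity is asserted with the gates active
  for (nm in grep("\\.(pa|ca)\\.gamma$", names(params), value = TRUE)) {
    params[[nm]]$value <- 0.3
  }
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array((matrix(runif(16 * 16 * 2), 16) > 0.6) * 1, c(16, 16, 1, 2))
  caafseg:::ag_reset_tape()
  out <- caafseg:::model_forward(model, x, training = TRUE)
  loss <- caafseg:::ag_boundary_aware_loss(out$prob, y, "sobel")
  caafseg:::ag_zero_grad(params)
  caafseg:::ag_backward(loss)
  for (nm in names(params)) {
    expect_false(is.null(params[[nm]]$grad), label = paste("grad of", nm))
    expect_gt(sum(params[[nm]]$grad != 0), 0,
              label = paste("nonzero grad of", nm))
  }
})

test_that("fixed-weight fusion path is deterministic and uses 0.5/0.5", {
  set.seed(38)
  model <- caaf_resunet(tiny_config(aac_enabled = FALSE))
  x <- array(runif(16 * 16 * 3), c(16, 16, 1, 3))
  o1 <- predict(model, x)
  o2 <- predict(model, x)
  expect_identical(o1$prob, o2$prob)
  expect_equal(o1$weights, matrix(0.5, 3, 2))
})

test_that("config guards reject malformed settings", {
  expect_error(network_config(stage_channels = c(32, 32, 64, 128)),
               "strictly increasing")
  expect_error(network_config(input_size = 60), "divisible")
})
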