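# Synthetic nodule-morphology generator.

test_that("fixtures are bitwise deterministic per spec and seed", {
  for (m in c("clear", "small", "adherent", "cavitary", "spiculated")) {
    f1 <- generate_fixture(nodule_spec(m, seed = 7))
    f2 <- generate_fixture(nodule_spec(m, seed = 7))
    expect_identical(f1$image, f2$image)
    expect_identical(f1$mask, f2$mask)
    f3 <- generate_fixture(nodule_spec(m, seed = 8))
    expect_false(identical(f1$image, f3$image))
  }
})

test_that("fixture generation leaves the session RNG untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_fixture(nodule_spec("clear", seed = 50)))
  expect_identical(.Random.seed, before)
})

test_that("masks are valid binary foregrounds within bounds", {
  fx <- generate_dataset(10, seed = 3)
  for (f in fx) {
    expect_true(all(f$mask %in% c(0, 1)))
    expect_gt(sum(f$mask), 0)
    expect_true(all(f$image >= 0 & f$image <= 1))
  }
})

test_that("cavitary nodules have exactly one interior hole and a dark core", {
  f <- generate_fixture(nodule_spec("cavitary", seed = 11))
  comp <- EBImage::bwlabel(1 - f$mask)
  border_labels <- unique(c(comp[1, ], comp[nrow(comp), ],
                            comp[, 1], comp[, ncol(comp)]))
  holes <- setdiff(setdiff(unique(as.vector(comp)), 0), border_labels)
  expect_length(holes, 1)
  hole_px <- comp == holes[1]
  rim_px <- f$mask == 1
  expect_lt(mean(f$image[hole_px]), mean(f$image[rim_px]))
})

test_that("small nodules respect the sub-5-pixel bound", {
  f <- generate_fixture(nodule_spec("small", seed = 13))
  expect_lt(sum(f$mask), pi * (5 / 2)^2 + 1)
  expect_error(nodule_spec("small", diameter_px = 6), "diameter_px < 5")
})

test_that("spiculated masks are star-shaped with radiating spikes", {
  f <- generate_fixture(nodule_spec("spiculated", seed = 17))
  # the radial support must be substantially non-circular: compare the
  # mask area with the disk of its maximum radius
  idx <- which(f$mask == 1, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  expect_lt(sum(f$mask), 0.8 * pi * max(r)^2)
})

test_that("dataset allocation follows the requested mix exactly", {
  fx <- generate_dataset(100, seed = 5)
  counts <- table(vapply(fx, function(f) f$spec$morphology, character(1)))
  expect_true(all(counts == 20))
  fx2 <- generate_dataset(10, morphology_mix = c(clear = 0.5, small = 0.5),
                          seed = 5)
  counts2 <- table(vapply(fx2, function(f) f$spec$morphology, character(1)))
  expect_equal(as.vector(counts2[c("clear", "small")]), c(5L, 5L))
  expect_error(generate_dataset(10, morphology_mix = c(clear = 0.6),
                                seed = 1), "sum to 1")
})

test_that("distinct master seeds yield disjoint fixture streams", {
  a <- generate_dataset(6, seed = 101)
  b <- generate_dataset(6, seed = 202)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      expect_false(identical(a[[i]]$image, b[[j]]$image))
    }
  }
})

test_that("specs validate their geometric invariants", {
  expect_error(nodule_spec("clear", diameter_px = 0.5), ">= 1")
  expect_error(nodule_spec("clear", center = c(70, 10), size = 64),
               "inside")
})

test_that("fixtures flow through the forward/loss/metrics path", {
  set.seed(41)
  model <- caaf_resunet(tiny_config())
  f <- generate_fixture(nodule_spec("clear", seed = 19, size = 16,
                                    diameter_px = 5))
  out <- predict(model, f$image)
  expect_equal(dim(out$prob)[1:2], dim(f$image))
  l <- boundary_aware_loss(out$prob[, , 1, 1], f$mask, "hausdorff")
  expect_true(is.finite(l) && l >= 0)
  m <- compute_metrics(confusion_counts(out$prob[, , 1, 1], f$mask))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("PNG round trip preserves images and masks", {
  dir <- tempfile("fixtures")
  fx <- generate_dataset(4, seed = 9, image_size = 32)
  manifest <- write_fixtures(fx, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(read.csv(file.path(dir, "manifest.csv"))), 4)
  back <- read_fixtures(dir)
  for (i in 1:4) {
    expect_identical(back[[i]]$mask, fx[[i]]$mask)
    # 16-bit PNG quantization
    expect_lt(max(abs(back[[i]]$image - fx[[i]]$image)), 1 / 255)
  }
})

test_that("clear nodules are easier to segment than sub-5-px ones", {
  # a fixed small network, trained identically on a mixed set, should rank
  # the morphologies: held-out Dice on clear nodules above small ones
  train_fx <- c(
    lapply(1:14, function(i) generate_fixture(
      nodule_spec("clear", seed = 3000 + i, size = 32))),
    lapply(1:14, function(i) generate_fixture(
      nodule_spec("small", seed = 4000 + i, size = 32)))
  )
  test_c1 <- lapply(1:6, function(i) generate_fixture(
    nodule_spec("clear", seed = 5000 + i, size = 32)))
  test_c2 <- lapply(1:6, function(i) generate_fixture(
    nodule_spec("small", seed = 6000 + i, size = 32)))
  cfg <- train_config(epochs = 12, batch_size = 8, lr = 1e-3,
                      lr_step_epochs = 100L, loss_variant = "sobel",
                      seed = 33, network = tiny_config(input_size = 32L))
  rec <- train_model(cfg, train_fx)
  dice_c1 <- mean(evaluate_model(rec, test_c1)$table$dice)
  dice_c2 <- mean(evaluate_model(rec, test_c2)$table$dice)
  expect_gt(dice_c1, dice_c2)
})
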