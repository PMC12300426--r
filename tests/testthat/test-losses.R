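# Boundary-aware loss formulations: worked values, symmetries, oracles,
# and gradient consistency.

test_that("soft Dice matches hand-computed values and identities", {
  g <- matrix(0, 4, 4); g[2:3, 2:3] <- 1
  expect_lt(dice_loss(g, g), 1e-6)
  expect_gt(dice_loss(matrix(0, 4, 4), g), 1 - 1e-5)
  # uniform 0.5 prediction against 4 foreground pixels on 4x4
  expect_equal(dice_loss(matrix(0.5, 4, 4), g), 2 / 3, tolerance = 1e-6)
  # both empty is a perfect (vacuous) overlap
  expect_lt(dice_loss(matrix(0, 4, 4), matrix(0, 4, 4)), 1e-6)
  expect_error(dice_loss(matrix(0.5, 4, 4), matrix(0, 5, 5)), "mismatch")
  expect_error(dice_loss(matrix(0.5, 4, 4), matrix(0.5, 4, 4)), "binary")
  expect_error(dice_loss(matrix(2, 4, 4), g), "probabilities")
})

test_that("Sobel magnitude is zero on constants and 4 at a unit step", {
  expect_true(all(abs(sobel_magnitude(matrix(0.7, 6, 6))) < 1e-5))
  step <- matrix(0, 6, 6); step[, 4:6] <- 1
  m <- sobel_magnitude(step)
  # interior pixels adjacent to the step edge
  expect_equal(m[3, 3], 4, tolerance = 1e-6)
  expect_equal(m[3, 4], 4, tolerance = 1e-6)
  expect_lt(m[3, 2], 1e-5)
  expect_error(sobel_magnitude(matrix(1, 2, 2)), "kernel")
})

test_that("Sobel magnitude commutes with 90-degree rotation (interior)", {
  set.seed(11)
  x <- matrix(runif(64), 8, 8)
  rot <- function(m) t(m)[, rev(seq_len(nrow(m)))] # 90-degree rotation
  m1 <- rot(sobel_magnitude(x))
  m2 <- sobel_magnitude(rot(x))
  expect_equal(m1[3:6, 3:6], m2[3:6, 3:6], tolerance = 1e-6)
})

test_that("Sobel boundary loss is symmetric and zero on identity", {
  g <- matrix(0, 7, 7); g[3:5, 3:5] <- 1
  expect_lt(sobel_boundary_loss(g, g), 1e-6)
  p <- matrix(0, 7, 7)
  expect_equal(sobel_boundary_loss(p, g), mean(sobel_magnitude(g)),
               tolerance = 1e-6)
  set.seed(3)
  a <- random_blob_mask(9, 31); b <- random_blob_mask(9, 32)
  expect_equal(sobel_boundary_loss(a, b), sobel_boundary_loss(b, a),
               tolerance = 1e-9)
})

test_that("Laplacian transform reproduces the 5-point stencil responses", {
  expect_true(all(abs(laplacian_transform(matrix(2, 5, 5))) < 1e-5))
  z <- matrix(0, 5, 5); z[3, 3] <- 1
  l <- laplacian_transform(z)
  expect_equal(l[3, 3], -4, tolerance = 1e-6)
  expect_equal(l[2, 3], 1, tolerance = 1e-6)
  expect_equal(l[4, 3], 1, tolerance = 1e-6)
  expect_equal(l[3, 2], 1, tolerance = 1e-6)
  expect_equal(l[3, 4], 1, tolerance = 1e-6)
  expect_lt(abs(l[2, 2]), 1e-6)
  # linear ramp has zero second derivative in the interior
  ramp <- matrix(rep(seq_len(8), each = 8) / 8, 8, 8)
  expect_true(all(abs(laplacian_transform(ramp)[3:6, 3:6]) < 1e-5))
})

test_that("Laplacian boundary loss matches the disjoint-impulse value", {
  z <- matrix(0, 7, 7); z[3, 3] <- 1
  expect_lt(laplacian_boundary_loss(z, z), 1e-6)
  # interior impulses with disjoint 4-neighbourhoods: each transform holds
  # one -4 and four +1 entries, so the L1 difference is 2*(4 + 4)/49
  p <- matrix(0, 7, 7); p[3, 3] <- 1
  g <- matrix(0, 7, 7); g[5, 5] <- 1
  expect_equal(laplacian_boundary_loss(p, g), 16 / 49, tolerance = 1e-6)
})

test_that("EDT is exact against brute force and handles degenerate masks", {
  expect_true(all(edt(matrix(1, 5, 5)) == 0))
  m <- matrix(0, 3, 3); m[1, 1] <- 1
  ref <- outer(0:2, 0:2, function(i, j) sqrt(i^2 + j^2))
  expect_equal(edt(m), ref, tolerance = 1e-9)
  for (s in 1:5) {
    r <- random_blob_mask(12, 400 + s, density = 0.15)
    if (!any(r > 0)) next
    expect_equal(edt(r), brute_edt(r), tolerance = 1e-9)
  }
  # empty mask: bounded constant fallback, no exception
  e <- edt(matrix(0, 6, 8))
  expect_true(all(is.finite(e)))
  expect_equal(max(e), min(e))
  expect_equal(e[1, 1], sqrt(5^2 + 7^2))
})

test_that("EDT-Hausdorff loss matches the pairwise oracle", {
  g <- matrix(0, 8, 8); g[3:5, 3:5] <- 1
  expect_lt(edt_hausdorff_loss(g, g), 1e-9)
  p <- matrix(0, 5, 5); p[1, 1] <- 1
  q <- matrix(0, 5, 5); q[1, 4] <- 1
  expect_equal(edt_hausdorff_loss(p, q), 6, tolerance = 1e-9)
  for (s in 1:12) {
    a <- random_blob_mask(16, 900 + s, density = 0.1)
    b <- random_blob_mask(16, 950 + s, density = 0.1)
    if (!any(a > 0) || !any(b > 0)) next
    expect_equal(edt_hausdorff_loss(a, b), brute_hausdorff(a, b),
                 tolerance = 1e-6)
  }
})

test_that("EDT-Hausdorff grows as 2k for single pixels k apart", {
  prev <- 0
  for (k in 1:6) {
    p <- matrix(0, 10, 10); p[2, 2] <- 1
    g <- matrix(0, 10, 10); g[2, 2 + k] <- 1
    val <- edt_hausdorff_loss(p, g)
    expect_equal(val, 2 * k, tolerance = 1e-9)
    expect_gt(val, prev)
    prev <- val
  }
})

test_that("EDT-Hausdorff empty-mask fallbacks are defined and bounded", {
  empty <- matrix(0, 8, 8)
  g <- matrix(0, 8, 8); g[4, 4] <- 1
  expect_equal(edt_hausdorff_loss(empty, empty), 0)
  v <- edt_hausdorff_loss(empty, g)
  expect_true(is.finite(v) && v > 0)
  expect_equal(v, 2 * mean(edt(g)), tolerance = 1e-9)
})

test_that("edge-pair oracle agrees with the EDT loss where it should", {
  p <- matrix(0, 6, 6); p[2, 2] <- 1
  g <- matrix(0, 6, 6); g[2, 5] <- 1
  expect_equal(edge_hausdorff_oracle(p, g), edt_hausdorff_loss(p, g),
               tolerance = 1e-9)
  sq <- matrix(0, 8, 8); sq[3:6, 3:6] <- 1
  expect_equal(edge_hausdorff_oracle(sq, sq), 0)
  expect_error(edge_hausdorff_oracle(matrix(0, 6, 6), g), "empty")
})

test_that("composite loss reduces to its parts and sums them", {
  g <- matrix(0, 8, 8); g[3:5, 4:6] <- 1
  for (v in c("sobel", "laplacian", "hausdorff")) {
    expect_lt(boundary_aware_loss(g, g, v), 1e-6)
  }
  p <- matrix(runif(64), 8, 8)
  set.seed(5)
  expect_equal(boundary_aware_loss(p, g, "sobel", boundary_weight = 0),
               dice_loss(p, g), tolerance = 1e-12)
  # single-pixel disjoint masks: dice ~ 1, hausdorff term 6
  pp <- matrix(0, 5, 5); pp[1, 1] <- 1
  gg <- matrix(0, 5, 5); gg[1, 4] <- 1
  expect_equal(boundary_aware_loss(pp, gg, "hausdorff"), 7,
               tolerance = 1e-5)
  expect_error(boundary_aware_loss(p, g, "fourier"))
})

test_that("losses are translation invariant away from borders", {
  base <- matrix(0, 12, 12); base[4:6, 4:6] <- 1
  pred <- matrix(0, 12, 12); pred[4:6, 5:7] <- 1
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    idx <- which(m > 0, arr.ind = TRUE)
    out[cbind(idx[, 1] + dr, idx[, 2] + dc)] <- 1
    out
  }
  for (fn in list(dice_loss, sobel_boundary_loss, laplacian_boundary_loss,
                  edt_hausdorff_loss)) {
    expect_equal(fn(shift(pred, 2, 3), shift(base, 2, 3)),
                 fn(pred, base), tolerance = 1e-6)
  }
})

test_that("differentiable losses pass finite-difference gradient checks", {
  set.seed(77)
  n <- 9
  pred <- array(0.2 + 0.6 * runif(n * n), c(n, n, 1, 1))
  targ <- array(random_blob_mask(n, 78, 0.3), c(n, n, 1, 1))
  variants <- list(
    dice = function(p) caafseg:::ag_dice_loss(p, targ),
    sobel = function(p) caafseg:::ag_sobel_boundary_loss(p, targ),
    laplacian = function(p) caafseg:::ag_laplacian_boundary_loss(p, targ)
  )
  numeric_of <- function(fn, x) {
    caafseg:::ag_no_grad(fn(caafseg:::ag_tensor(x)))$value
  }
  for (nm in names(variants)) {
    fn <- variants[[nm]]
    caafseg:::ag_reset_tape()
    pt <- caafseg:::ag_tensor(pred, requires_grad = TRUE)
    caafseg:::ag_backward(fn(pt))
    g <- pt$grad
    h <- 1e-5
    coords <- sample(n * n, 20)
    for (i in coords) {
      xp <- pred; xp[i] <- xp[i] + h
      xm <- pred; xm[i] <- xm[i] - h
      fd <- (numeric_of(fn, xp) - numeric_of(fn, xm)) / (2 * h)
      denom <- max(abs(fd), abs(g[i]), 1e-4)
      expect_lt(abs(fd - g[i]) / denom, 1e-3,
                label = sprintf("%s gradient at %d", nm, i))
    }
  }
})

test_that("kernel set matches the standard stencils", {
  k <- edge_kernels()
  expect_equal(k$sobel_x,
               matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE))
  expect_equal(k$sobel_y, t(k$sobel_x))
  expect_equal(sum(k$sobel_x), 0)
  expect_equal(sum(k$sobel_y), 0)
  expect_equal(sum(k$laplacian), 0)
  expect_equal(k$laplacian[2, 2], -4)
})
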