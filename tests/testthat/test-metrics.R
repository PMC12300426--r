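# Confusion counts, the five evaluation metrics, and the paired t-test.

test_that("confusion counts match direct enumeration", {
  g <- matrix(0, 4, 4); g[1, 1:4] <- 1
  expect_equal(unname(confusion_counts(g, g)[c("fp", "fn")]), c(0, 0))
  inv <- 1 - g
  cc <- confusion_counts(inv, g)
  expect_equal(unname(cc[c("tp", "tn")]), c(0, 0))
  # 3 of 4 foreground covered plus one background pixel
  p <- matrix(0, 4, 4); p[1, 1:3] <- 1; p[2, 1] <- 1
  cc <- confusion_counts(p, g)
  expect_equal(unname(cc[c("tp", "fp", "fn", "tn")]), c(3, 1, 1, 11))
  expect_error(confusion_counts(matrix(0, 3, 3), g), "mismatch")
})

test_that("metric formulas reproduce the worked example and extremes", {
  m <- compute_metrics(c(tp = 3, fp = 1, fn = 1, tn = 11))
  expect_equal(unname(m["dice"]), 0.75)
  expect_equal(unname(m["iou"]), 0.6)
  expect_equal(unname(m["sensitivity"]), 0.75)
  expect_equal(unname(m["miss_rate"]), 0.25)
  expect_equal(unname(m["specificity"]), 11 / 12)
  perfect <- compute_metrics(c(tp = 10, fp = 0, fn = 0, tn = 6))
  expect_equal(unname(perfect), c(1, 1, 1, 0, 1))
  # empty prediction on a non-empty target
  missed <- compute_metrics(c(tp = 0, fp = 0, fn = 5, tn = 11))
  expect_equal(unname(missed[c("dice", "sensitivity", "miss_rate")]),
               c(0, 0, 1))
  # both empty: vacuous success
  vac <- compute_metrics(c(tp = 0, fp = 0, fn = 0, tn = 16))
  expect_equal(unname(vac[c("dice", "iou", "miss_rate")]), c(1, 1, 0))
})

test_that("metric identities hold over random confusion counts", {
  set.seed(99)
  for (i in 1:200) {
    cc <- c(tp = rpois(1, 20) + 1, fp = rpois(1, 5), fn = rpois(1, 5),
            tn = rpois(1, 50))
    m <- compute_metrics(cc)
    expect_equal(unname(m["dice"]),
                 2 * m[["iou"]] / (1 + m[["iou"]]), tolerance = 1e-12)
    expect_equal(m[["sensitivity"]] + m[["miss_rate"]], 1,
                 tolerance = 1e-12)
    expect_gte(m[["dice"]], m[["iou"]])
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("1 - dice_loss equals the confusion-count Dice on binary pairs", {
  set.seed(12)
  for (i in 1:5) {
    p <- random_blob_mask(10, 500 + i, 0.3)
    g <- random_blob_mask(10, 600 + i, 0.3)
    m <- compute_metrics(confusion_counts(p, g))
    expect_equal(1 - dice_loss(p, g), m[["dice"]], tolerance = 1e-5)
  }
})

test_that("paired t-test matches the closed form and the reference", {
  r <- paired_t_test(c(2, 3, 4, 5), c(1, 1, 1, 1))
  expect_equal(r$t_statistic, 2.5 / (sqrt(5 / 3) / 2), tolerance = 1e-9)
  expect_equal(r$p_value, 0.03047, tolerance = 1e-3)
  expect_equal(r$n, 4)
  set.seed(2024)
  for (i in 1:100) {
    a <- rnorm(sample(5:40, 1))
    b <- a + rnorm(length(a), 0.2, 0.7)
    ours <- paired_t_test(a, b)
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$mean_difference, unname(ref$estimate),
                 tolerance = 1e-9)
  }
})

test_that("paired t-test handles identical and constant-shift scores", {
  a <- c(0.8, 0.9, 0.7)
  same <- paired_t_test(a, a)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  shifted <- paired_t_test(a + 0.1, a)
  expect_equal(shifted$p_value, 0)
  expect_true(shifted$degenerate)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 2), "at least two")
})

test_that("metrics table carries fixed columns and consistent summary", {
  g1 <- matrix(0, 6, 6); g1[2:4, 2:4] <- 1
  g2 <- matrix(0, 6, 6); g2[3:5, 3:5] <- 1
  tab <- metrics_table(list(g1, g2), list(g1, g1),
                       weights = list(c(0.3, 0.7), c(0.6, 0.4)))
  expect_identical(names(tab), c("case_id", "dice", "iou", "sensitivity",
                                 "miss_rate", "specificity", "w1", "w2"))
  s <- attr(tab, "summary")
  expect_equal(s$dice[1], mean(tab$dice), tolerance = 1e-12)
  expect_equal(s$dice[2], sd(tab$dice), tolerance = 1e-12)
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(tab, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 4)   # 2 cases + mean + sd rows
  expect_equal(back$dice[1:2], tab$dice, tolerance = 1e-9)
})
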