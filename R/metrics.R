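# Pixel-level evaluation metrics and the paired t-test used for the
# attention-controller ablation.

#' Pixel confusion counts
#'
#' Binarizes the prediction at `threshold` and tallies true/false
#' positives/negatives against a binary target.
#'
#' @inheritParams dice_loss
#' @param threshold foreground threshold for the prediction (default 0.5).
#' @return named integer vector with elements `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, target, threshold = 0.5) {
  pred <- as_nchw(pred, "pred"); target <- as_nchw(target, "target")
  check_same_shape(pred, target)
  check_binarymask(target)
  pb <- pred >= threshold
  gb <- target > 0
  c(tp = sum(pb & gb), fp = sum(pb & !gb),
    fn = sum(!pb & gb), tn = sum(!pb & !gb))
}

#' Segmentation metrics from confusion counts
#'
#' Dice `2TP/(2TP+FN+FP)`, IoU `TP/(TP+FN+FP)`, sensitivity `TP/(TP+FN)`,
#' Miss Rate `FN/(TP+FN)`, and specificity `TN/(TN+FP)`, each in `[0, 1]`.
#' Degenerate denominators are defined rather than thrown: when prediction
#' and target are both empty the overlap metrics score 1 (vacuous success,
#' Miss Rate 0); an image with no true background scores specificity 1 when
#' no false positives were possible.
#'
#' @param counts named vector as returned by [confusion_counts()] (elements
#'   `tp`, `fp`, `fn`, `tn`).
#' @return named numeric vector `dice`, `iou`, `sensitivity`, `miss_rate`,
#'   `specificity`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be >= 0")
  safe <- function(num, den, empty_value) {
    if (den == 0) empty_value else num / den
  }
  dice <- safe(2 * tp, 2 * tp + fn + fp, 1)
  iou <- safe(tp, tp + fn + fp, 1)
  sens <- safe(tp, tp + fn, 1)
  miss <- safe(fn, tp + fn, 0)
  spec <- safe(tn, tn + fp, 1)
  c(dice = dice, iou = iou, sensitivity = sens,
    miss_rate = miss, specificity = spec)
}

#' Two-tailed paired t-test
#'
#' Closed-form paired t-test on per-case score differences `d = a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-tailed p-value. Used to compare matched model variants on the same
#' test cases. Zero-variance differences are handled explicitly: p is 1
#' when the scores are identical and 0 when the difference is constant and
#' non-zero, with `degenerate = TRUE` flagged.
#'
#' @param scores_a,scores_b equal-length numeric vectors, paired by case.
#' @return list with `t_statistic`, `p_value`, `mean_difference`, `n`,
#'   `degenerate`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired scores must have equal length")
  }
  n <- length(scores_a)
  if (n < 2) stop("need at least two paired cases")
  d <- scores_a - scores_b
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t_statistic = if (md == 0) 0 else sign(md) * Inf,
                p_value = if (md == 0) 1 else 0,
                mean_difference = md, n = n, degenerate = TRUE))
  }
  t_stat <- md / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  list(t_statistic = t_stat, p_value = p, mean_difference = md, n = n,
       degenerate = FALSE)
}

#' Per-case metrics table
#'
#' Evaluates a list of (prediction, target) pairs and returns one row per
#' case plus a `summary` attribute with column means and standard
#' deviations. Column order is fixed: `case_id`, `dice`, `iou`,
#' `sensitivity`, `miss_rate`, `specificity`, `w1`, `w2`.
#'
#' @param preds list of probability masks.
#' @param targets list of binary masks.
#' @param weights optional list/matrix of per-case fusion weight pairs.
#' @param case_ids optional case identifiers.
#' @param threshold binarization threshold.
#' @return data.frame of per-case metrics.
#' @export
metrics_table <- function(preds, targets, weights = NULL, case_ids = NULL,
                          threshold = 0.5) {
  n <- length(preds)
  stopifnot(length(targets) == n)
  if (is.null(case_ids)) case_ids <- seq_len(n)
  rows <- lapply(seq_len(n), function(i) {
    m <- compute_metrics(confusion_counts(preds[[i]], targets[[i]], threshold))
    w <- if (is.null(weights)) c(NA_real_, NA_real_) else as.numeric(weights[[i]])
    data.frame(case_id = case_ids[i], dice = m[["dice"]], iou = m[["iou"]],
               sensitivity = m[["sensitivity"]],
               miss_rate = m[["miss_rate"]],
               specificity = m[["specificity"]], w1 = w[1], w2 = w[2])
  })
  out <- do.call(rbind, rows)
  num <- out[, -1, drop = FALSE]
  attr(out, "summary") <- data.frame(
    statistic = c("mean", "sd"),
    rbind(colMeans(num), apply(num, 2, stats::sd))
  )
  out
}

#' Write a metrics CSV report
#'
#' One row per case in the fixed column order of [metrics_table()], followed
#' by summary rows (`mean`, `sd`) with `case_id` set to the statistic name.
#'
#' @param tab data.frame from [metrics_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(tab, path) {
  s <- attr(tab, "summary")
  srows <- data.frame(case_id = s$statistic, s[, -1, drop = FALSE])
  utils::write.csv(rbind(tab, srows), path, row.names = FALSE)
  invisible(path)
}
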