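# Training, evaluation, prediction, and the attention-controller ablation
# harness.

#' Training configuration
#'
#' Reference settings: AdamW with initial learning rate 1e-4 and a step
#' scheduler that multiplies the rate by 0.1 every 30 epochs. Batch size,
#' weight decay and the split proportions are exposed here.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param lr_decay_factor multiplicative decay (default 0.1).
#' @param lr_step_epochs epochs between decays (default 30).
#' @param weight_decay decoupled AdamW weight decay.
#' @param loss_variant boundary term: `"sobel"`, `"laplacian"`,
#'   `"hausdorff"`.
#' @param boundary_weight multiplier on the boundary term (reference
#'   configuration: 1).
#' @param seed master seed controlling initialization, shuffling and
#'   splits.
#' @param network a [network_config()]; `aac_enabled` there switches the
#'   adaptive-vs-fixed fusion arms.
#' @return list of class `caaf_train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 8L, lr = 1e-4,
                         lr_decay_factor = 0.1, lr_step_epochs = 30L,
                         weight_decay = 1e-2,
                         loss_variant = c("sobel", "laplacian", "hausdorff"),
                         boundary_weight = 1,
                         seed = 1L,
                         network = network_config()) {
  loss_variant <- match.arg(loss_variant)
  if (lr <= 0) stop("lr must be > 0")
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1) {
    stop("lr_decay_factor must lie in (0, 1)")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_step_epochs = as.integer(lr_step_epochs),
                 weight_decay = weight_decay, loss_variant = loss_variant,
                 boundary_weight = boundary_weight, seed = as.integer(seed),
                 network = network),
            class = "caaf_train_config")
}

#' Learning rate at a given epoch under the step schedule
#'
#' `lr * factor^floor(epoch / step)`, epochs counted from 0.
#'
#' @param config a [train_config()].
#' @param epoch 0-based epoch index.
#' @return numeric learning rate.
#' @export
scheduled_lr <- function(config, epoch) {
  config$lr * config$lr_decay_factor^(epoch %/% config$lr_step_epochs)
}

# --- AdamW ------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adamw_step <- function(opt, params, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-2) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    p$value <- p$value - lr * (mhat / (sqrt(vhat) + eps) +
                                 weight_decay * p$value)
  }
  opt
}

# --- data plumbing ----------------------------------------------------------

fixtures_to_batch <- function(fixtures, idx = seq_along(fixtures)) {
  h <- nrow(fixtures[[idx[1]]]$image)
  w <- ncol(fixtures[[idx[1]]]$image)
  x <- array(0, dim = c(h, w, 1L, length(idx)))
  y <- array(0, dim = c(h, w, 1L, length(idx)))
  for (j in seq_along(idx)) {
    x[, , 1L, j] <- fixtures[[idx[j]]]$image
    y[, , 1L, j] <- fixtures[[idx[j]]]$mask
  }
  list(x = x, y = y)
}

#' Seeded train/validation/test split
#'
#' 70/15/15 split by a seeded shuffle of case indices.
#'
#' @param n number of cases.
#' @param seed split seed.
#' @param prop length-3 proportions.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, seed = 1L, prop = c(0.7, 0.15, 0.15)) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  idx <- sample(n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  n_tr <- floor(prop[1] * n)
  n_va <- floor(prop[2] * n)
  list(train = idx[seq_len(n_tr)],
       val = idx[n_tr + seq_len(n_va)],
       test = idx[(n_tr + n_va + 1):n])
}

# snapshot / restore parameter values and batch-norm buffers
.snapshot_state <- function(model) {
  params <- collect_params(model$modules)
  bns <- collect_bn_states(model$modules)
  list(params = lapply(params, function(p) p$value),
       bn = lapply(bns, function(s) list(mean = s$running_mean,
                                         var = s$running_var)))
}

.restore_state <- function(model, state) {
  params <- collect_params(model$modules)
  stopifnot(identical(names(params), names(state$params)))
  for (nm in names(params)) params[[nm]]$value <- state$params[[nm]]
  bns <- collect_bn_states(model$modules)
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- state$bn[[i]]$mean
    bns[[i]]$running_var <- state$bn[[i]]$var
  }
  invisible(model)
}

# name the loss component that produced a non-finite value
.diagnose_nonfinite <- function(prob, y, variant, bw) {
  parts <- c(dice = dice_loss(pmin(pmax(prob, 0), 1), y))
  bnd <- switch(variant,
    sobel = sobel_boundary_loss(pmin(pmax(prob, 0), 1), y),
    laplacian = laplacian_boundary_loss(pmin(pmax(prob, 0), 1), y),
    hausdorff = edt_hausdorff_loss(pmin(pmax(prob, 0), 1), y))
  parts[paste0(variant, "_boundary")] <- bnd
  bad <- names(parts)[!is.finite(parts)]
  if (length(bad) == 0) bad <- "combined"
  paste(bad, collapse = ", ")
}

#' Train a CAAF-ResUNet model
#'
#' Runs AdamW under the step learning-rate schedule on the configured
#' boundary-aware loss, logging the per-epoch mean training loss and (when
#' validation fixtures are supplied) the per-epoch validation Dice. The
#' best-validation-Dice parameter state is kept as the checkpoint (final
#' state when no validation set is given). Fully reproducible: the master
#' seed drives initialization and shuffling.
#'
#' @param config a [train_config()].
#' @param data list of fixtures (`image`/`mask` pairs).
#' @param val_data optional validation fixtures.
#' @param verbose print one line per epoch.
#' @return list of class `caaf_record` with the trained `model`, `config`,
#'   `trajectory` (per-epoch mean loss), `val_dice`, `best_state`,
#'   `best_epoch`.
#' @export
train_model <- function(config, data, val_data = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "caaf_train_config"), length(data) >= 1)
  set.seed(config$seed)
  model <- caaf_resunet(config$network)
  params <- collect_params(model$modules)
  opt <- adamw_init(params)
  trajectory <- numeric(0)
  val_dice <- numeric(0)
  best_state <- .snapshot_state(model)
  best_dice <- -Inf
  best_epoch <- 0L

  if (config$epochs > 0) {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- scheduled_lr(config, epoch)
      idx <- sample(length(data))
      batch_losses <- numeric(0)
      for (start in seq(1, length(idx), by = config$batch_size)) {
        bi <- idx[start:min(start + config$batch_size - 1, length(idx))]
        batch <- fixtures_to_batch(data, bi)
        ag_reset_tape()
        out <- model_forward(model, batch$x, training = TRUE)
        loss <- ag_boundary_aware_loss(out$prob, batch$y,
                                       variant = config$loss_variant,
                                       boundary_weight = config$boundary_weight)
        if (!is.finite(loss$value)) {
          stop(sprintf(
            "training diverged at epoch %d: non-finite loss in component(s): %s",
            epoch, .diagnose_nonfinite(out$prob$value, batch$y,
                                       config$loss_variant,
                                       config$boundary_weight)))
        }
        batch_losses <- c(batch_losses, loss$value)
        ag_zero_grad(params)
        ag_backward(loss)
        opt <- adamw_step(opt, params, lr,
                          weight_decay = config$weight_decay)
      }
      trajectory <- c(trajectory, mean(batch_losses))
      if (!is.null(val_data)) {
        ev <- evaluate_model(model, val_data)
        vd <- mean(ev$table$dice)
        val_dice <- c(val_dice, vd)
        if (vd > best_dice) {
          best_dice <- vd
          best_state <- .snapshot_state(model)
          best_epoch <- epoch + 1L
        }
      }
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f%s", epoch, lr,
                        mean(batch_losses),
                        if (!is.null(val_data))
                          sprintf("  val dice %.4f", val_dice[length(val_dice)])
                        else ""))
      }
    }
  }
  if (is.null(val_data) && config$epochs > 0) {
    best_state <- .snapshot_state(model)
    best_epoch <- config$epochs
  }
  structure(list(model = model, config = config, trajectory = trajectory,
                 val_dice = val_dice, best_state = best_state,
                 best_epoch = best_epoch),
            class = "caaf_record")
}

#' Evaluate a model on a set of fixtures
#'
#' Per-case confusion-count metrics (threshold 0.5) plus the fusion weights
#' the controller assigned to each case, with a mean +/- sd summary.
#'
#' @param model a `caaf_resunet` (or a `caaf_record`, whose best state is
#'   used).
#' @param data list of fixtures.
#' @param batch_size evaluation batch size.
#' @param csv optional path for a CSV report.
#' @return list with `table` (per-case data.frame), `summary`
#'   (mean/sd rows), `mean_weights` (named w1/w2 means).
#' @export
evaluate_model <- function(model, data, batch_size = 8L, csv = NULL) {
  if (inherits(model, "caaf_record")) {
    .restore_state(model$model, model$best_state)
    model <- model$model
  }
  preds <- list(); targets <- list(); weights <- list()
  for (start in seq(1, length(data), by = batch_size)) {
    bi <- start:min(start + batch_size - 1, length(data))
    batch <- fixtures_to_batch(data, bi)
    out <- predict(model, batch$x)
    for (j in seq_along(bi)) {
      preds[[bi[j]]] <- out$prob[, , 1L, j]
      targets[[bi[j]]] <- batch$y[, , 1L, j]
      weights[[bi[j]]] <- out$weights[j, ]
    }
  }
  tab <- metrics_table(preds, targets, weights)
  if (!is.null(csv)) write_metrics_csv(tab, csv)
  list(table = tab, summary = attr(tab, "summary"),
       mean_weights = c(w1 = mean(tab$w1), w2 = mean(tab$w2)))
}

#' Adaptive-vs-fixed attention ablation with a paired t-test
#'
#' Trains two matched variants on the same seeded 70/15/15 split -- one
#' with the Adaptive Attention Controller, one with fixed (0.5, 0.5) fusion
#' weights -- and compares their per-case test Dice scores with a
#' two-tailed paired t-test.
#'
#' @param config a [train_config()]; its `network$aac_enabled` is
#'   overridden per arm.
#' @param data list of fixtures.
#' @param verbose print per-epoch progress.
#' @return list with `test` (the [paired_t_test()] result), `dice_aac`,
#'   `dice_fixed`, `summary_aac`, `summary_fixed`, `mean_weights_aac`,
#'   `mean_weights_fixed`, `n`.
#' @export
ablation_aac <- function(config, data, verbose = FALSE) {
  sp <- split_indices(length(data), seed = config$seed)
  train_set <- data[sp$train]; val_set <- data[sp$val]
  test_set <- data[sp$test]
  cfg_on <- config; cfg_on$network$aac_enabled <- TRUE
  cfg_off <- config; cfg_off$network$aac_enabled <- FALSE
  rec_on <- train_model(cfg_on, train_set, val_set, verbose = verbose)
  rec_off <- train_model(cfg_off, train_set, val_set, verbose = verbose)
  ev_on <- evaluate_model(rec_on, test_set)
  ev_off <- evaluate_model(rec_off, test_set)
  list(test = paired_t_test(ev_on$table$dice, ev_off$table$dice),
       dice_aac = ev_on$table$dice, dice_fixed = ev_off$table$dice,
       summary_aac = ev_on$summary, summary_fixed = ev_off$summary,
       mean_weights_aac = ev_on$mean_weights,
       mean_weights_fixed = ev_off$mean_weights,
       n = length(test_set))
}

# --- prediction output ------------------------------------------------------

#' Color-coded prediction/ground-truth difference map
#'
#' Green marks true positives, blue true negatives, red false positives,
#' yellow false negatives.
#'
#' @param pred probability or binary mask.
#' @param target binary ground truth.
#' @param threshold binarization threshold for the prediction.
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
difference_map <- function(pred, target, threshold = 0.5) {
  p <- as_nchw(pred, "pred"); g <- as_nchw(target, "target")
  check_same_shape(p, g)
  pb <- matrix(p[, , 1L, 1L] >= threshold, dim(p)[1], dim(p)[2])
  gb <- matrix(g[, , 1L, 1L] > 0, dim(g)[1], dim(g)[2])
  rgb <- array(0, dim = c(dim(pb), 3L))
  tp <- pb & gb; tn <- !pb & !gb; fp <- pb & !gb; fn <- !pb & gb
  rgb[, , 1] <- fp + fn            # red channel: FP red, FN yellow
  rgb[, , 2] <- tp + fn            # green channel: TP green, FN yellow
  rgb[, , 3] <- tn                 # blue channel: TN blue
  rgb
}

#' Predict binary masks (and optional difference maps) for images
#'
#' Runs the model, binarizes at `threshold`, and -- when ground truth is
#' supplied -- builds the four-color difference maps. With `out_dir` set,
#' masks (`pred_%04d.png`) and difference maps (`diff_%04d.png`) are written
#' as PNGs.
#'
#' @param model a `caaf_resunet` or `caaf_record`.
#' @param images list of H x W matrices (or a single matrix).
#' @param gt optional list of binary ground-truth masks.
#' @param out_dir optional output directory.
#' @param threshold binarization threshold.
#' @return list with `masks`, `prob`, `weights`, and (if `gt` given)
#'   `diff_maps`.
#' @export
predict_masks <- function(model, images, gt = NULL, out_dir = NULL,
                          threshold = 0.5) {
  if (inherits(model, "caaf_record")) {
    .restore_state(model$model, model$best_state)
    model <- model$model
  }
  if (is.matrix(images)) images <- list(images)
  if (!is.null(gt) && is.matrix(gt)) gt <- list(gt)
  sz <- model$config$input_size
  for (im in images) {
    if (nrow(im) != sz || ncol(im) != sz) {
      stop(sprintf("image is %dx%d but the model expects %dx%d",
                   nrow(im), ncol(im), sz, sz))
    }
  }
  x <- array(0, dim = c(sz, sz, 1L, length(images)))
  for (j in seq_along(images)) x[, , 1L, j] <- images[[j]]
  out <- predict(model, x)
  masks <- lapply(seq_along(images), function(j) {
    (out$prob[, , 1L, j] >= threshold) * 1
  })
  diff_maps <- NULL
  if (!is.null(gt)) {
    diff_maps <- lapply(seq_along(images), function(j) {
      difference_map(out$prob[, , 1L, j], gt[[j]], threshold)
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (j in seq_along(masks)) {
      EBImage::writeImage(t(masks[[j]]),
                          file.path(out_dir, sprintf("pred_%04d.png", j)))
      if (!is.null(diff_maps)) {
        EBImage::writeImage(EBImage::Image(aperm(diff_maps[[j]], c(2, 1, 3)),
                                           colormode = "Color"),
                            file.path(out_dir, sprintf("diff_%04d.png", j)))
      }
    }
  }
  list(masks = masks, prob = out$prob, weights = out$weights,
       diff_maps = diff_maps)
}

# --- checkpointing ----------------------------------------------------------

# deterministic FNV-1a hash of the YAML rendering of a config
config_hash <- function(config) {
  s <- yaml::as.yaml(config)
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Save a trained model checkpoint
#'
#' Writes one archive holding the parameter values, batch-norm buffers, the
#' network config, and a config hash validated on reload, plus a sidecar
#' YAML rendering of the config.
#'
#' @param model a `caaf_resunet` or `caaf_record`.
#' @param path checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "caaf_record")) {
    .restore_state(model$model, model$best_state)
    model <- model$model
  }
  obj <- list(config = model$config, state = .snapshot_state(model),
              hash = config_hash(model$config))
  saveRDS(obj, path)
  yaml::write_yaml(unclass(model$config),
                   paste0(sub("\\.[^.]+$", "", path), ".yaml"))
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the network from the stored config and restores parameters;
#' fails if the stored config hash does not validate.
#'
#' @param path checkpoint path written by [save_checkpoint()].
#' @return a `caaf_resunet`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(config_hash(obj$config), obj$hash)) {
    stop("checkpoint config hash mismatch: archive is corrupt or was edited")
  }
  model <- caaf_resunet(obj$config)
  .restore_state(model, obj$state)
  model
}

#' Write an experiment record as JSON
#'
#' Serializes the bookkeeping of a training run (config snapshot, per-epoch
#' loss trajectory, validation Dice, best epoch) losslessly to JSON. Model
#' parameters live in the checkpoint archive, not here.
#'
#' @param record a `caaf_record` from [train_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  cfg <- unclass(record$config)
  cfg$network <- unclass(cfg$network)
  jsonlite::write_json(
    list(config = cfg, trajectory = record$trajectory,
         val_dice = record$val_dice, best_epoch = record$best_epoch),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read an experiment record written by [write_record()]
#'
#' @param path JSON path.
#' @return list with `config`, `trajectory`, `val_dice`, `best_epoch`.
#' @export
read_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$trajectory <- as.numeric(obj$trajectory)
  obj$val_dice <- as.numeric(obj$val_dice)
  obj
}
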