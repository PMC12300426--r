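# CAAF-ResUNet: residual encoder, ASPP bridge, attention-fused decoder.
#
# Default schedule for 64x64 single-channel patches with stage channels
# (32, 64, 128, 256): encoder 64 -> 32 -> 16 -> 8, decoder mirrors back to
# 64. One shared AAC reads the stem features and its per-sample weight pair
# drives every AAF block in the network.

#' Network configuration
#'
#' @param input_size input patch side in pixels; must be divisible by
#'   `2^(length(stage_channels) - 1)`.
#' @param stage_channels strictly increasing channel widths per encoder
#'   stage.
#' @param aspp_dilations dilation rates of the parallel atrous branches in
#'   the bridge.
#' @param aac_enabled use the Adaptive Attention Controller; when `FALSE`
#'   every AAF block uses `fixed_weights`.
#' @param fixed_weights weight pair for the fixed-fusion baseline.
#' @param aac_downsample pooled grid side for the AAC.
#' @param final_aspp include the lightweight full-resolution ASPP before the
#'   sigmoid head.
#' @param kv_cap pooled key/value grid cap for position attention.
#' @param normalize_input min-max normalize each input patch to `[0, 1]`.
#' @return list of class `caaf_config`.
#' @export
network_config <- function(input_size = 64L,
                           stage_channels = c(32L, 64L, 128L, 256L),
                           aspp_dilations = c(6L, 12L, 18L),
                           aac_enabled = TRUE,
                           fixed_weights = c(0.5, 0.5),
                           aac_downsample = 8L,
                           final_aspp = TRUE,
                           kv_cap = 8L,
                           normalize_input = TRUE) {
  if (any(diff(stage_channels) <= 0)) {
    stop("stage_channels must be strictly increasing")
  }
  div <- 2^(length(stage_channels) - 1L)
  if (input_size %% div != 0) {
    stop(sprintf("input_size %d must be divisible by %d (one halving per stage after the first)",
                 input_size, div))
  }
  structure(list(input_size = as.integer(input_size),
                 stage_channels = as.integer(stage_channels),
                 aspp_dilations = as.integer(aspp_dilations),
                 aac_enabled = isTRUE(aac_enabled),
                 fixed_weights = as.numeric(fixed_weights),
                 aac_downsample = as.integer(aac_downsample),
                 final_aspp = isTRUE(final_aspp),
                 kv_cap = as.integer(kv_cap),
                 normalize_input = isTRUE(normalize_input)),
            class = "caaf_config")
}

# --- residual block ---------------------------------------------------------

new_resblock <- function(in_ch, out_ch, stride = 1L) {
  proj <- (in_ch != out_ch) || stride > 1L
  structure(list(
    conv1 = new_conv(in_ch, out_ch, 3L, stride = stride),
    bn1 = new_bn(out_ch),
    conv2 = new_conv(out_ch, out_ch, 3L),
    bn2 = new_bn(out_ch),
    proj = if (proj) new_conv(in_ch, out_ch, 1L, stride = stride, pad = 0L)
           else NULL,
    bn_proj = if (proj) new_bn(out_ch) else NULL
  ), class = "cf_resblock")
}

resblock_fwd <- function(m, x, training) {
  h <- ag_relu(bn_fwd(m$bn1, conv_fwd(m$conv1, x), training))
  h <- bn_fwd(m$bn2, conv_fwd(m$conv2, h), training)
  s <- if (is.null(m$proj)) x
       else bn_fwd(m$bn_proj, conv_fwd(m$proj, x), training)
  ag_relu(ag_add(h, s))
}

#' Residual convolutional block
#'
#' Two 3x3 convolution + batch-norm + ReLU layers with an identity (or
#' 1x1-projected) shortcut. Functional front end: builds a block with
#' weights drawn from the session RNG unless one is supplied, and applies
#' it. Spatial size is preserved at `stride = 1`.
#'
#' @param x feature map (matrix or `[H, W, C, B]` array).
#' @param out_channels output channel count.
#' @param stride stride of the first convolution (2 halves the resolution).
#' @param block optional prebuilt block from [new_resblock()].
#' @param training batch-norm mode.
#' @return feature array `[H/stride, W/stride, out_channels, B]`.
#' @export
residual_block <- function(x, out_channels, stride = 1L, block = NULL,
                           training = FALSE) {
  xa <- as_nchw(x, "x")
  if (is.null(block)) block <- new_resblock(dim(xa)[3], out_channels, stride)
  ag_no_grad(resblock_fwd(block, ag_tensor(xa), training))$value
}

# --- ASPP -------------------------------------------------------------------

new_aspp <- function(channels, dilations = c(6L, 12L, 18L),
                     branch_channels = NULL, global_branch = TRUE,
                     out_channels = NULL) {
  if (is.null(branch_channels)) branch_channels <- max(4L, channels %/% 4L)
  if (is.null(out_channels)) out_channels <- channels
  n_branch <- 1L + length(dilations) + as.integer(global_branch)
  atrous <- lapply(dilations, function(d) {
    list(conv = new_conv(channels, branch_channels, 3L, dilation = d,
                         pad_mode = "reflect"),
         bn = new_bn(branch_channels))
  })
  warned <- new.env(parent = emptyenv()); warned$done <- FALSE
  structure(list(
    one = list(conv = new_conv(channels, branch_channels, 1L, pad = 0L),
               bn = new_bn(branch_channels)),
    atrous = atrous,
    glob = if (global_branch)
      list(conv = new_conv(channels, branch_channels, 1L, pad = 0L),
           bn = new_bn(branch_channels)) else NULL,
    fuse = list(conv = new_conv(n_branch * branch_channels, out_channels,
                                1L, pad = 0L),
                bn = new_bn(out_channels)),
    dilations = dilations, warned = warned
  ), class = "cf_aspp")
}

aspp_fwd <- function(m, x, training) {
  d <- dim(x$value)
  if (!m$warned$done && any(m$dilations >= min(d[1], d[2]))) {
    warning(sprintf(
      "ASPP dilation (%s) >= spatial size %dx%d: atrous branches degenerate to heavily padded convolutions",
      paste(m$dilations[m$dilations >= min(d[1], d[2])], collapse = ", "),
      d[1], d[2]), call. = FALSE)
    m$warned$done <- TRUE
  }
  branches <- list(ag_relu(bn_fwd(m$one$bn, conv_fwd(m$one$conv, x), training)))
  for (br in m$atrous) {
    branches <- c(branches,
                  list(ag_relu(bn_fwd(br$bn, conv_fwd(br$conv, x), training))))
  }
  if (!is.null(m$glob)) {
    g <- ag_adaptive_avgpool(x, 1L, 1L)
    g <- ag_relu(bn_fwd(m$glob$bn, conv_fwd(m$glob$conv, g), training))
    branches <- c(branches, list(ag_broadcast_hw(g, d[1], d[2])))
  }
  cat_t <- Reduce(ag_concat_ch, branches)
  ag_relu(bn_fwd(m$fuse$bn, conv_fwd(m$fuse$conv, cat_t), training))
}

#' Atrous Spatial Pyramid Pooling
#'
#' Parallel 3x3 atrous convolutions at the requested dilation rates plus a
#' 1x1 branch and (optionally) a global-average-pooling branch, concatenated
#' and fused by a 1x1 convolution back to the input channel count. Output
#' shape equals input shape. Reflect padding keeps all branches
#' constancy-preserving; a dilation at or beyond the spatial size triggers a
#' one-time warning and proceeds with the (heavily padded) convolution.
#'
#' @param x feature map array.
#' @param dilations dilation rates (default `c(6, 12, 18)`).
#' @param module optional prebuilt module from [new_aspp()].
#' @param global_branch include the pooled global-context branch.
#' @param training batch-norm mode.
#' @return array with the same shape as the input.
#' @export
aspp <- function(x, dilations = c(6L, 12L, 18L), module = NULL,
                 global_branch = TRUE, training = FALSE) {
  xa <- as_nchw(x, "x")
  if (is.null(module)) {
    module <- new_aspp(dim(xa)[3], dilations, global_branch = global_branch)
  }
  ag_no_grad(aspp_fwd(module, ag_tensor(xa), training))$value
}

# --- AAF stage block --------------------------------------------------------

new_aaf_block <- function(channels, kv_cap) {
  structure(list(pa = pa_params(channels, kv_cap), ca = ca_params(channels)),
            class = "cf_aaf")
}

aaf_block_fwd <- function(m, x, w) {
  aaf_fwd(pa_fwd(m$pa, x), ca_fwd(m$ca, x), w)
}

# --- full model -------------------------------------------------------------

#' Build a CAAF-ResUNet model
#'
#' Assembles stem, four residual encoder stages with AAF blocks, ASPP
#' bridge, three decoder stages (bilinear 2x upsampling, skip concatenation,
#' 1x1 reduction, residual block, AAF), an optional lightweight
#' full-resolution ASPP, and a 1x1 sigmoid head. All weights draw from the
#' session RNG; call `set.seed()` first (or pass `seed`) for reproducible
#' initialization.
#'
#' @param config list from [network_config()].
#' @param seed optional integer passed to `set.seed()` before
#'   initialization.
#' @return object of class `caaf_resunet`.
#' @export
caaf_resunet <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- config$stage_channels
  kv <- config$kv_cap
  m <- list(
    stem_conv = new_conv(1L, ch[1], 3L),
    stem_bn = new_bn(ch[1]),
    aac = if (config$aac_enabled) aac_params(ch[1], config$aac_downsample)
          else NULL,
    enc = list(
      list(rb = new_resblock(ch[1], ch[1], 1L), aaf = new_aaf_block(ch[1], kv)),
      list(rb = new_resblock(ch[1], ch[2], 2L), aaf = new_aaf_block(ch[2], kv)),
      list(rb = new_resblock(ch[2], ch[3], 2L), aaf = new_aaf_block(ch[3], kv)),
      list(rb = new_resblock(ch[3], ch[4], 2L), aaf = new_aaf_block(ch[4], kv))
    ),
    bridge = new_aspp(ch[4], config$aspp_dilations),
    dec = list(
      list(red = new_conv(ch[4] + ch[3], ch[3], 1L, pad = 0L),
           red_bn = new_bn(ch[3]),
           rb = new_resblock(ch[3], ch[3], 1L), aaf = new_aaf_block(ch[3], kv)),
      list(red = new_conv(ch[3] + ch[2], ch[2], 1L, pad = 0L),
           red_bn = new_bn(ch[2]),
           rb = new_resblock(ch[2], ch[2], 1L), aaf = new_aaf_block(ch[2], kv)),
      list(red = new_conv(ch[2] + ch[1], ch[1], 1L, pad = 0L),
           red_bn = new_bn(ch[1]),
           rb = new_resblock(ch[1], ch[1], 1L), aaf = new_aaf_block(ch[1], kv))
    ),
    final_aspp = if (config$final_aspp)
      new_aspp(ch[1], config$aspp_dilations,
               branch_channels = max(2L, ch[1] %/% 8L)) else NULL,
    head = new_conv(ch[1], 1L, 1L, pad = 0L)
  )
  structure(list(config = config, modules = m), class = "caaf_resunet")
}

#' @export
print.caaf_resunet <- function(x, ...) {
  np <- sum(vapply(collect_params(x$modules),
                   function(p) length(p$value), numeric(1)))
  cat(sprintf("<caaf_resunet: %dx%d input, stages [%s], %s fusion weights, %d parameters>\n",
              x$config$input_size, x$config$input_size,
              paste(x$config$stage_channels, collapse = ", "),
              if (x$config$aac_enabled) "adaptive" else "fixed",
              np))
  invisible(x)
}

.minmax_normalize <- function(x) {
  # per-sample min-max to [0, 1]; constant patches map to 0
  d <- dim(x)
  n <- prod(d[1:3])
  m <- matrix(x, nrow = n)
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  sc <- ifelse(hi > lo, 1 / (hi - lo), 0)
  array(sweep(sweep(m, 2, lo), 2, sc, `*`), dim = d)
}

# Internal graph forward. Returns list(prob = ag_tensor [H,W,1,B],
# weights = ag_tensor [2,B], stages = list of spatial shapes).
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  m <- model$modules
  if (!is.array(x) || length(dim(x)) != 4L) x <- as_nchw(x, "image")
  d <- dim(x)
  div <- 2^(length(cfg$stage_channels) - 1L)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("input %dx%d not divisible by %d as required by the %d-stage encoder",
                 d[1], d[2], div, length(cfg$stage_channels)))
  }
  if (cfg$normalize_input) x <- .minmax_normalize(x)
  xt <- ag_tensor(x)
  stages <- list()

  f0 <- ag_relu(bn_fwd(m$stem_bn, conv_fwd(m$stem_conv, xt), training))
  w <- if (cfg$aac_enabled) {
    aac_fwd(m$aac, f0)
  } else {
    ag_tensor(matrix(cfg$fixed_weights, nrow = 2, ncol = d[4]))
  }

  skips <- list()
  h <- f0
  for (i in seq_along(m$enc)) {
    h <- resblock_fwd(m$enc[[i]]$rb, h, training)
    h <- aaf_block_fwd(m$enc[[i]]$aaf, h, w)
    skips[[i]] <- h
    stages[[length(stages) + 1L]] <- dim(h$value)
  }

  h <- aspp_fwd(m$bridge, h, training)
  stages[[length(stages) + 1L]] <- dim(h$value)

  for (j in seq_along(m$dec)) {
    h <- ag_upsample2x(h)
    skip <- skips[[length(skips) - j]]
    h <- ag_concat_ch(h, skip)
    dj <- m$dec[[j]]
    h <- ag_relu(bn_fwd(dj$red_bn, conv_fwd(dj$red, h), training))
    h <- resblock_fwd(dj$rb, h, training)
    h <- aaf_block_fwd(dj$aaf, h, w)
    stages[[length(stages) + 1L]] <- dim(h$value)
  }

  if (!is.null(m$final_aspp)) h <- aspp_fwd(m$final_aspp, h, training)
  logits <- conv_fwd(m$head, h)
  prob <- ag_sigmoid(logits)
  list(prob = prob, weights = w, stages = stages)
}

#' Segment images with a CAAF-ResUNet model
#'
#' Forward pass in evaluation mode. Returns the probability masks together
#' with the per-sample fusion weights the network used.
#'
#' @param object a `caaf_resunet` model.
#' @param images matrix, `H x W x B` array, or `[H, W, 1, B]` array of
#'   grayscale patches.
#' @param ... unused.
#' @return list with `prob` (`[H, W, 1, B]` array in `[0, 1]`) and
#'   `weights` (`B x 2` matrix on the simplex).
#' @export
predict.caaf_resunet <- function(object, images, ...) {
  x <- as_nchw(images, "images")
  out <- ag_no_grad(model_forward(object, x, training = FALSE))
  list(prob = out$prob$value, weights = t(out$weights$value))
}
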