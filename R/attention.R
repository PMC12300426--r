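# Attention components: channel attention (CA), position attention (PA),
# the Adaptive Attention Controller (AAC) that emits per-sample fusion
# weights from self-attention over a pooled grid, and the Adaptive Attention
# Fusion (AAF) convex combination of the two branches.

# --- Adaptive Attention Controller ------------------------------------------

#' Create parameters for the Adaptive Attention Controller
#'
#' The AAC pools a feature map to a small `downsample x downsample` grid,
#' runs single-head scaled dot-product self-attention over the pooled
#' positions (`C x C` query/key/value projections, scaling by `sqrt(C)`),
#' averages spatially, and maps the global descriptor through a two-layer
#' perceptron (hidden width `floor(C/2)`, minimum 1) to two logits whose
#' softmax is the fusion weight pair `(w1, w2)`. Weights are drawn from the
#' session RNG (Kaiming-uniform).
#'
#' @param channels number of input feature channels `C` (>= 2).
#' @param downsample pooled grid side `H' = W'` (default 8).
#' @return an object of class `caaf_aac`.
#' @export
aac_params <- function(channels, downsample = 8L) {
  if (channels < 2) stop("AAC requires at least 2 channels (hidden width C/2)")
  hidden <- max(1L, channels %/% 2L)
  structure(list(
    wq = new_seq_proj(channels, channels),
    wk = new_seq_proj(channels, channels),
    wv = new_seq_proj(channels, channels),
    fc1 = new_dense(channels, hidden),
    fc2 = new_dense(hidden, 2L),
    downsample = as.integer(downsample),
    channels = as.integer(channels)
  ), class = "caaf_aac")
}

aac_fwd <- function(m, x) {
  d <- dim(x$value)
  C <- d[3]; B <- d[4]
  if (C != m$channels) stop("AAC channel mismatch")
  hp <- m$downsample
  f_ds <- ag_adaptive_avgpool(x, hp, hp)              # [H',W',C,B]
  n <- hp * hp
  f_seq <- ag_reshape(f_ds, c(n, C, B))               # [N,C,B]
  q <- ag_seq_matmul(f_seq, m$wq)
  k <- ag_seq_matmul(f_seq, m$wk)
  v <- ag_seq_matmul(f_seq, m$wv)
  att <- ag_softmax_rows(ag_scale(ag_bmm(q, k, tb = TRUE), 1 / sqrt(C)))
  f_sa <- ag_bmm(att, v)                              # [N,C,B]
  f_global <- ag_seq_mean(f_sa)                       # [C,B]
  h <- ag_relu(ag_dense(f_global, m$fc1$w, m$fc1$b))  # [C/2,B]
  z <- ag_dense(h, m$fc2$w, m$fc2$b)                  # [2,B]
  ag_softmax_cols(z)                                  # [2,B], columns on simplex
}

#' Compute adaptive fusion weights
#'
#' Runs the Adaptive Attention Controller forward pass and returns one
#' non-negative weight pair per sample, each summing to 1.
#'
#' @param features feature map (H x W matrix is promoted; usually an
#'   `[H, W, C, B]` array with `C >= 2`).
#' @param params object from [aac_params()].
#' @return numeric matrix `B x 2` of fusion weights `(w1, w2)`.
#' @export
aac_forward <- function(features, params) {
  x <- as_nchw(features, "features")
  w <- ag_no_grad(aac_fwd(params, ag_tensor(x)))$value
  t(w)
}

# --- channel / position attention -------------------------------------------

#' Create a channel-attention block
#'
#' Channel attention reweights feature channels by the softmax of the
#' channel-affinity matrix `X %*% t(X)` (computed over flattened spatial
#' positions) applied back to the channels, added to the input through a
#' learnable scalar gate initialized at 0 (identity at initialization).
#'
#' @param channels number of feature channels.
#' @return object of class `caaf_ca`.
#' @export
ca_params <- function(channels) {
  structure(list(gamma = new_gate(), channels = as.integer(channels)),
            class = "caaf_ca")
}

ca_fwd <- function(m, x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  xs <- ag_reshape(x, c(n, d[3], d[4]))          # [N,C,B]
  energy <- ag_bmm(xs, xs, ta = TRUE)            # [C,C,B]
  att <- ag_softmax_rows(energy)
  out <- ag_bmm(xs, att, tb = TRUE)              # [N,C,B]
  ag_add(x, ag_mul_scalar_t(ag_reshape(out, d), m$gamma))
}

#' Apply channel attention
#'
#' @inheritParams aac_forward
#' @param params object from [ca_params()]; created on the fly (gate at 0,
#'   i.e. identity) when `NULL`.
#' @return array with the same shape as the input.
#' @export
channel_attention <- function(features, params = NULL) {
  x <- as_nchw(features, "features")
  if (is.null(params)) params <- ca_params(dim(x)[3])
  out <- ag_no_grad(ca_fwd(params, ag_tensor(x)))$value
  if (is.matrix(features)) dim(out) <- dim(features)
  out
}

#' Create a position-attention block
#'
#' Position attention reweights spatial locations: queries and keys are
#' linear projections to `max(1, C/8)` channels, the affinity
#' `softmax(Q %*% t(K) / sqrt(dk))` over positions is applied to a `C`-channel
#' value projection, and the result is added to the input through a
#' learnable scalar gate initialized at 0. For maps larger than
#' `kv_cap x kv_cap` the key/value grid is average-pooled to the cap so the
#' affinity stays `O(N * cap^2)`; smaller maps use exact full attention.
#' The default cap matches the 8x8 semantic-filter grid the fusion
#' controller attends over.
#'
#' @param channels number of feature channels.
#' @param kv_cap side of the pooled key/value grid (default 8).
#' @return object of class `caaf_pa`.
#' @export
pa_params <- function(channels, kv_cap = 8L) {
  dk <- max(1L, channels %/% 8L)
  structure(list(
    wq = new_seq_proj(channels, dk),
    wk = new_seq_proj(channels, dk),
    wv = new_seq_proj(channels, channels),
    gamma = new_gate(),
    dk = dk, kv_cap = as.integer(kv_cap),
    channels = as.integer(channels)
  ), class = "caaf_pa")
}

pa_fwd <- function(m, x) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  xs <- ag_reshape(x, c(n, d[3], d[4]))
  if (max(d[1], d[2]) > m$kv_cap) {
    kvmap <- ag_adaptive_avgpool(x, min(d[1], m$kv_cap),
                                 min(d[2], m$kv_cap))
    kd <- dim(kvmap$value)
    kvs <- ag_reshape(kvmap, c(kd[1] * kd[2], d[3], d[4]))
  } else {
    kvs <- xs
  }
  q <- ag_seq_matmul(xs, m$wq)
  k <- ag_seq_matmul(kvs, m$wk)
  v <- ag_seq_matmul(kvs, m$wv)
  att <- ag_softmax_rows(ag_scale(ag_bmm(q, k, tb = TRUE), 1 / sqrt(m$dk)))
  out <- ag_bmm(att, v)                          # [N,C,B]
  ag_add(x, ag_mul_scalar_t(ag_reshape(out, d), m$gamma))
}

#' Apply position attention
#'
#' @inheritParams channel_attention
#' @param params object from [pa_params()]; created on the fly when `NULL`
#'   (projections drawn from the session RNG, gate at 0).
#' @return array with the same shape as the input.
#' @export
position_attention <- function(features, params = NULL) {
  x <- as_nchw(features, "features")
  if (is.null(params)) params <- pa_params(dim(x)[3])
  out <- ag_no_grad(pa_fwd(params, ag_tensor(x)))$value
  if (is.matrix(features)) dim(out) <- dim(features)
  out
}

# --- fusion -----------------------------------------------------------------

# internal graph form; w is a [2, B] tensor with columns on the simplex
aaf_fwd <- function(x_pa, x_ca, w) {
  ag_add(ag_scale_per_sample(x_pa, ag_row(w, 1L)),
         ag_scale_per_sample(x_ca, ag_row(w, 2L)))
}

#' Adaptive Attention Fusion
#'
#' Per-sample convex combination of the position-attention and
#' channel-attention branches, `w1 * X_PA + w2 * X_CA`, broadcasting each
#' sample's scalar weight pair over its feature map.
#'
#' @param x_pa,x_ca feature maps of identical shape.
#' @param weights `B x 2` matrix of non-negative rows summing to 1 (a single
#'   pair is recycled for a batch of 1).
#' @return fused array with the shape of the inputs.
#' @export
aaf_fuse <- function(x_pa, x_ca, weights) {
  a <- as_nchw(x_pa, "x_pa"); b <- as_nchw(x_ca, "x_ca")
  check_same_shape(a, b)
  w <- if (is.null(dim(weights))) matrix(weights, nrow = 1) else as.matrix(weights)
  if (nrow(w) != dim(a)[4]) {
    stop(sprintf("weights have %d rows but the batch holds %d samples",
                 nrow(w), dim(a)[4]))
  }
  if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-6)) {
    stop("fusion weights must be non-negative and sum to 1 per sample")
  }
  out <- ag_no_grad(aaf_fwd(ag_tensor(a), ag_tensor(b),
                            ag_tensor(t(w))))$value
  if (is.matrix(x_pa)) dim(out) <- dim(x_pa)
  out
}
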