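# Trainable layer constructors. Parameter initialization draws from the
# session RNG (Kaiming-uniform fan-in bounds for weights, zeros for biases),
# so a model built under set.seed() is bitwise reproducible.

kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

new_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, dilation = 1L,
                     pad = NULL, pad_mode = "zero", bias = TRUE) {
  if (is.null(pad)) pad <- ((k - 1L) %/% 2L) * dilation
  w <- ag_tensor(kaiming_uniform(c(k, k, in_ch, out_ch), k * k * in_ch),
                 requires_grad = TRUE)
  b <- if (bias) ag_tensor(numeric(out_ch), requires_grad = TRUE) else NULL
  structure(list(w = w, b = b, stride = stride, dilation = dilation,
                 pad = pad, pad_mode = pad_mode), class = "cf_conv")
}

conv_fwd <- function(m, x) {
  ag_conv2d(x, m$w, m$b, stride = m$stride, dilation = m$dilation,
            pad = m$pad, pad_mode = m$pad_mode)
}

new_bn <- function(ch) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- numeric(ch)
  state$running_var <- rep(1, ch)
  structure(list(gamma = ag_tensor(rep(1, ch), requires_grad = TRUE),
                 beta = ag_tensor(numeric(ch), requires_grad = TRUE),
                 state = state), class = "cf_bn")
}

bn_fwd <- function(m, x, training) {
  ag_batchnorm(x, m$gamma, m$beta, m$state, training = training)
}

new_dense <- function(in_dim, out_dim, zero_init = FALSE) {
  w <- if (zero_init) array(0, dim = c(in_dim, out_dim))
       else kaiming_uniform(c(in_dim, out_dim), in_dim)
  structure(list(w = ag_tensor(w, requires_grad = TRUE),
                 b = ag_tensor(numeric(out_dim), requires_grad = TRUE)),
            class = "cf_dense")
}

new_seq_proj <- function(in_dim, out_dim) {
  ag_tensor(kaiming_uniform(c(in_dim, out_dim), in_dim),
            requires_grad = TRUE)
}

# scalar residual gate, initialized at 0 so attention blocks start as identity
new_gate <- function(init = 0) {
  ag_tensor(init, requires_grad = TRUE)
}

# multiply an array tensor by a scalar tensor
ag_mul_scalar_t <- function(x, s) {
  sv <- as.numeric(s$value)
  xv <- x$value
  ag_node(xv * sv, list(x, s), function(g) {
    list(g * sv, sum(g * xv))
  })
}

# extract row i of a [K, B] matrix tensor as a length-B vector
ag_row <- function(x, i) {
  d <- dim(x$value)
  ag_node(x$value[i, ], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[i, ] <- g
    list(gx)
  })
}

# --- parameter collection ---------------------------------------------------

# Walk a nested module structure and return every trainable ag_tensor,
# named by its path, in a deterministic order.
collect_params <- function(x, prefix = "") {
  out <- list()
  if (is_ag(x)) {
    if (x$requires_grad) out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      p <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      out <- c(out, collect_params(x[[i]], p))
    }
  }
  out
}

# Walk a module structure and return every batch-norm state environment.
collect_bn_states <- function(x) {
  out <- list()
  if (is.list(x)) {
    if (inherits(x, "cf_bn")) return(list(x$state))
    for (el in x) out <- c(out, collect_bn_states(el))
  }
  out
}
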