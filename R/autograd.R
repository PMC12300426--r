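#' @useDynLib caafseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# A small reverse-mode automatic differentiation engine.
#
# Tensors are environments holding a dense numeric array (`value`), an
# accumulated gradient (`grad`), and -- for non-leaf nodes -- the list of
# parent tensors plus a closure mapping the node's output gradient to parent
# gradients. The tape is the creation-order list of non-leaf nodes; reverse
# iteration over it is a valid reverse topological order.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$enabled <- TRUE

#' Create an autodiff tensor
#'
#' Wraps a numeric array (or scalar) as a node of the computation graph.
#' Leaf tensors created with `requires_grad = TRUE` are trainable parameters;
#' everything else records gradients only while some ancestor requires them.
#'
#' @param value numeric vector/matrix/array.
#' @param requires_grad logical, mark as trainable leaf.
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$requires_grad <- requires_grad
  t$is_leaf <- TRUE
  class(t) <- "ag_tensor"
  t
}

is_ag <- function(x) inherits(x, "ag_tensor")

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$requires_grad) "(grad)" else "", ">\n")
  invisible(x)
}

ag_reset_tape <- function() {
  .ag$tape <- list()
  invisible(NULL)
}

#' Evaluate an expression with gradient recording disabled
#' @param expr expression to evaluate.
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$enabled
  .ag$enabled <- FALSE
  on.exit(.ag$enabled <- old)
  expr
}

# Record a new graph node. `backward` receives the output gradient and must
# return a list of gradients aligned with `parents` (NULL entries allowed).
ag_node <- function(value, parents, backward) {
  rg <- any(vapply(parents, function(p) p$requires_grad, logical(1)))
  t <- ag_tensor(value, requires_grad = rg)
  if (rg && .ag$enabled) {
    t$is_leaf <- FALSE
    t$parents <- parents
    t$backward_fn <- backward
    .ag$tape[[length(.ag$tape) + 1L]] <- t
  }
  t
}

ag_accumulate <- function(t, g) {
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss tensor
#'
#' Seeds the loss gradient with 1, sweeps the tape in reverse creation order,
#' and accumulates gradients into every tensor with `requires_grad`. The tape
#' is cleared afterwards.
#' @param loss scalar `ag_tensor`.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  loss$grad <- 1
  tape <- .ag$tape
  for (i in rev(seq_along(tape))) {
    node <- tape[[i]]
    if (is.null(node$grad)) next
    gs <- node$backward_fn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (p$requires_grad && !is.null(gs[[j]])) ag_accumulate(p, gs[[j]])
    }
    # free intermediate gradient memory eagerly
    if (!identical(node, loss)) node$grad <- NULL
  }
  ag_reset_tape()
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- basic elementwise ops --------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, k) {
  ag_node(a$value * k, list(a), function(g) list(g * k))
}

ag_add_const <- function(a, k) {
  ag_node(a$value + k, list(a), function(g) list(g))
}

ag_relu <- function(a) {
  y <- .cpp_relu_fwd(a$value)
  ag_node(y, list(a), function(g) list(.cpp_relu_bwd(y, g)))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_abs <- function(a) {
  v <- a$value
  s <- sign(v)
  ag_node(abs(v), list(a), function(g) list(g * s))
}

# sqrt(x + eps) -- eps guards the derivative at 0 (edge-magnitude maps).
ag_sqrt_eps <- function(a, eps = 1e-12) {
  r <- sqrt(a$value + eps)
  ag_node(r, list(a), function(g) list(g * 0.5 / r))
}

ag_mean_all <- function(a) {
  n <- length(a$value)
  ag_node(mean(a$value), list(a), function(g) {
    gv <- array(g / n, dim = if (is.null(dim(a$value))) NULL else dim(a$value))
    if (is.null(dim(a$value))) gv <- rep(g / n, n)
    list(gv)
  })
}

ag_sum_all <- function(a) {
  n <- length(a$value)
  d <- dim(a$value)
  ag_node(sum(a$value), list(a), function(g) {
    gv <- if (is.null(d)) rep(g, n) else array(g, dim = d)
    list(gv)
  })
}

ag_reshape <- function(a, dims) {
  old <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  ag_node(v, list(a), function(g) {
    dim(g) <- old
    list(g)
  })
}

ag_aperm <- function(a, perm) {
  inv <- order(perm)
  ag_node(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

# --- shape/structure ops on [H, W, C, B] tensors ----------------------------

# concatenate along the channel axis (dim 3)
ag_concat_ch <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  ia <- seq_len(da[3])
  ib <- da[3] + seq_len(db[3])
  out[, , ia, ] <- a$value
  out[, , ib, ] <- b$value
  ag_node(out, list(a, b), function(g) {
    list(g[, , ia, , drop = FALSE], g[, , ib, , drop = FALSE])
  })
}

# broadcast a [1, 1, C, B] tensor over spatial size H x W
ag_broadcast_hw <- function(a, H, W) {
  d <- dim(a$value)
  stopifnot(d[1] == 1L, d[2] == 1L)
  C <- d[3]; B <- d[4]
  v <- array(rep(as.vector(a$value), each = H * W), dim = c(H, W, C, B))
  ag_node(v, list(a), function(g) {
    gs <- colSums(matrix(g, nrow = H * W))
    list(array(gs, dim = d))
  })
}

# multiply sample b's map by scalar w[b]: x [H,W,C,B], w ag vector length B
ag_scale_per_sample <- function(x, w) {
  wv <- as.vector(w$value)
  xv <- x$value
  v <- .cpp_scale_sample_fwd(xv, wv)
  ag_node(v, list(x, w), function(g) {
    r <- .cpp_scale_sample_bwd(xv, wv, g)
    list(r$gx, r$gw)
  })
}

# --- compiled-kernel ops ----------------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L,
                      pad = 1L, pad_mode = c("zero", "reflect")) {
  pad_mode <- match.arg(pad_mode)
  pm <- if (pad_mode == "reflect") 1L else 0L
  bias <- if (is.null(b)) numeric(0) else as.vector(b$value)
  keep <- .ag$enabled &&
    (w$requires_grad || x$requires_grad || !x$is_leaf)
  res <- .cpp_conv2d_fwd(x$value, w$value, bias,
                         as.integer(stride), as.integer(dilation),
                         as.integer(pad), pm, keep)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  xv <- x$value; wv <- w$value
  need_gx <- x$requires_grad || !x$is_leaf
  cache <- res$cache
  ag_node(res$y, parents, function(g) {
    gr <- .cpp_conv2d_bwd(xv, wv, g, as.integer(stride),
                          as.integer(dilation), as.integer(pad), pm,
                          need_gx, cache)
    if (is.null(b)) list(gr$gx, gr$gw) else list(gr$gx, gr$gw, gr$gb)
  })
}

ag_adaptive_avgpool <- function(x, oh, ow) {
  d <- dim(x$value)
  y <- .cpp_adaptive_avgpool_fwd(x$value, as.integer(oh), as.integer(ow))
  ag_node(y, list(x), function(g) {
    list(.cpp_adaptive_avgpool_bwd(g, d[1], d[2]))
  })
}

ag_upsample2x <- function(x) {
  y <- .cpp_upsample2x_fwd(x$value)
  ag_node(y, list(x), function(g) list(.cpp_upsample2x_bwd(g)))
}

# --- batch normalization ----------------------------------------------------

# Training-mode batch norm over (H, W, B) per channel with running-stat
# update; eval mode uses the stored running statistics. Channel statistics
# are taken through an HW x (C*B) matrix view of the [H,W,C,B] array, which
# avoids any transposition of the large tensors.
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv)
  n <- d[1] * d[2] * d[4]
  if (training) {
    st <- .cpp_chan_stats(xv)
    mu <- st$mean
    var_b <- pmax(st$ex2 - mu * mu, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    # unbiased variance in the running estimate, biased in normalization
    ub <- if (n > 1) var_b * n / (n - 1) else var_b
    state$running_var <- (1 - momentum) * state$running_var + momentum * ub
  } else {
    mu <- state$running_mean
    var_b <- state$running_var
  }
  inv_sd <- 1 / sqrt(var_b + eps)
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  xhat <- .cpp_chan_affine(xv, inv_sd, -mu * inv_sd)
  y <- .cpp_chan_affine(xhat, gv, bv)
  ag_node(y, list(x, gamma, beta), function(g) {
    dots <- .cpp_chan_dots(g, xhat)
    ggamma <- dots$sum_gx
    gbeta <- dots$sum_g
    if (training) {
      gx <- .cpp_chan_axpby(g, xhat, gv * inv_sd,
                            -gv * inv_sd * ggamma / n,
                            -gv * inv_sd * gbeta / n)
    } else {
      gx <- .cpp_chan_affine(g, gv * inv_sd, numeric(length(gv)))
    }
    list(gx, ggamma, gbeta)
  })
}

# --- sequence ops for attention ---------------------------------------------
# Sequences are [N, C, B] arrays (N spatial positions, C channels).

# right-multiply every sample by a shared matrix: out[,,b] = x[,,b] %*% W
ag_seq_matmul <- function(x, W) {
  xv <- x$value
  d <- dim(xv)
  N <- d[1]; C <- d[2]; B <- d[3]
  Wv <- W$value
  Co <- ncol(Wv)
  y <- array(0, dim = c(N, Co, B))
  for (b in seq_len(B)) {
    y[, , b] <- matrix(xv[, , b], N, C) %*% Wv
  }
  ag_node(y, list(x, W), function(g) {
    gx <- array(0, dim = d)
    gW <- matrix(0, C, Co)
    for (b in seq_len(B)) {
      gb <- matrix(g[, , b], N, Co)
      xb <- matrix(xv[, , b], N, C)
      gx[, , b] <- gb %*% t(Wv)
      gW <- gW + crossprod(xb, gb)
    }
    list(gx, gW)
  })
}

# per-sample matmul of two [.,.,B] arrays, with optional transposes
ag_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  av0 <- a$value; bv0 <- b$value
  out <- .cpp_bmm_fwd(av0, bv0, ta, tb)
  ag_node(out, list(a, b), function(g) {
    r <- .cpp_bmm_bwd(av0, bv0, g, ta, tb)
    list(r$ga, r$gb)
  })
}

# softmax over the second index of an [N, M, B] array (each row of each
# sample's N x M matrix becomes a probability distribution)
ag_softmax_rows <- function(x) {
  p <- .cpp_softmax3_fwd(x$value)
  ag_node(p, list(x), function(g) list(.cpp_softmax3_bwd(p, g)))
}

# mean over the first index: [N, C, B] -> [C, B]
ag_seq_mean <- function(x) {
  d <- dim(x$value)
  N <- d[1]
  v <- apply(x$value, c(2, 3), mean)
  ag_node(v, list(x), function(g) {
    gx <- array(rep(as.vector(g) / N, each = N), dim = d)
    list(gx)
  })
}

# dense layer on [C, B] feature matrix: out = t(W) %*% x + b
ag_dense <- function(x, W, b) {
  v <- t(W$value) %*% x$value + as.vector(b$value)
  ag_node(v, list(x, W, b), function(g) {
    list(W$value %*% g, x$value %*% t(g), rowSums(g))
  })
}

# softmax over columns of a [K, B] matrix (per-sample distribution)
ag_softmax_cols <- function(x) {
  v <- x$value
  e <- exp(sweep(v, 2, apply(v, 2, max)))
  p <- sweep(e, 2, colSums(e), `/`)
  ag_node(p, list(x), function(g) {
    dot <- colSums(g * p)
    list(p * sweep(g, 2, dot))
  })
}
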