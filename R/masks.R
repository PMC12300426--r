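# Mask containers and coercion.
#
# All spatial tensors in this package are column-major arrays laid out as
# [H, W, C, B] (rows, columns, channels, batch). Public mask functions also
# accept an H x W matrix (one image) or an H x W x B array (batch of
# single-channel images) and promote them.

#' Coerce an image/mask argument to the internal [H, W, C, B] layout
#'
#' @param x matrix, 3-D array (H x W x B) or 4-D array (H x W x C x B).
#' @param name argument name used in error messages.
#' @return a 4-D numeric array.
#' @export
as_nchw <- function(x, name = "x") {
  if (is_ag(x)) x <- x$value
  if (is.matrix(x)) {
    dim(x) <- c(nrow(x), ncol(x), 1L, 1L)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    dim(x) <- c(d[1], d[2], 1L, d[3])
  } else if (!(is.array(x) && length(dim(x)) == 4L)) {
    stop(sprintf("`%s` must be a matrix or a 3-D/4-D array", name))
  }
  storage.mode(x) <- "double"
  x
}

check_same_shape <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) {
    stop(sprintf("shape mismatch: prediction is [%s], target is [%s]",
                 paste(dim(pred), collapse = ","),
                 paste(dim(target), collapse = ",")))
  }
  invisible(NULL)
}

check_probmask <- function(x, name = "pred", min_hw = 1L) {
  d <- dim(x)
  if (d[1] < min_hw || d[2] < min_hw) {
    stop(sprintf("`%s` must be at least %dx%d pixels", name, min_hw, min_hw))
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    stop(sprintf("`%s` must hold probabilities in [0, 1]", name))
  }
  invisible(NULL)
}

check_binarymask <- function(x, name = "target") {
  if (anyNA(x) || !all(x == 0 | x == 1)) {
    stop(sprintf("`%s` must be strictly binary (values in {0, 1})", name))
  }
  invisible(NULL)
}
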