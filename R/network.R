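#' @useDynLib gpdnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

relu <- function(a) {
  a[a < 0] <- 0
  a
}

no_bias <- numeric(0)

# Concatenate two (H, W, C, N) activation blocks along the channel axis,
# first block first (the fixed fire-module convention).
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L)
    stop("image batch must be an (H, W, C) or (H, W, C, N) array")
  x
}

check_input_shape <- function(spec, x) {
  d <- dim(x)
  if (d[3] != 3L)
    stop(sprintf("expected 3 (RGB) channels, got %d", d[3]))
  fully_conv <- !any(vapply(spec$layers, function(l) l$type == "dense",
                            logical(1)))
  if (fully_conv) {
    if (min(d[1], d[2]) < spec$input_size)
      stop(sprintf("input spatial size %dx%d below the minimum %d",
                   d[1], d[2], spec$input_size))
  } else if (d[1] != spec$input_size || d[2] != spec$input_size) {
    stop(sprintf("the dense-head network requires exactly %dx%d inputs",
                 spec$input_size, spec$input_size))
  }
  invisible(TRUE)
}

# Full forward pass. Returns list(post = N x L posterior matrix,
# logits = L x N, cache = per-layer activations when keep_cache).
nn_forward <- function(spec, weights, x, keep_cache = FALSE) {
  x <- as_batch(x)
  check_input_shape(spec, x)
  x <- x - 0.5   # fixed input centering (in place of a mean image)
  cache <- if (keep_cache) vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "conv") {
      w <- weights[[ly$name]]
      y <- conv_forward_cpp(x, w$W, if (ly$bias) w$b else no_bias,
                            ly$stride, ly$pad, ly$relu)
      if (keep_cache) cache[[i]] <- list(x = x, y = y)
    } else if (ly$type == "fire") {
      w <- weights[[ly$name]]
      s <- conv_forward_cpp(x, w$W_squeeze, w$b_squeeze, 1L, 0L, TRUE)
      e1 <- conv_forward_cpp(s, w$W_expand1, w$b_expand1, 1L, 0L, TRUE)
      e3 <- conv_forward_cpp(s, w$W_expand3, w$b_expand3, 1L, 1L, TRUE)
      y <- concat_channels(e1, e3)
      if (keep_cache) cache[[i]] <- list(x = x, s = s, e1 = e1, e3 = e3)
    } else if (ly$type == "pool") {
      pf <- pool_forward_cpp(x, ly$window, ly$stride,
                             if (ly$kind == "max") 0L else 1L)
      y <- pf$y
      if (keep_cache) cache[[i]] <- list(xdim = dim(x), idx = pf$idx)
    } else if (ly$type == "gap") {
      d <- dim(x)
      xm <- x
      dim(xm) <- c(d[1] * d[2], d[3] * d[4])
      y <- matrix(colMeans(xm), d[3], d[4])   # C x N
      if (keep_cache) cache[[i]] <- list(xdim = d)
    } else if (ly$type == "flatten") {
      d <- dim(x)
      y <- x
      dim(y) <- c(d[1] * d[2] * d[3], d[4])   # features x N
      if (keep_cache) cache[[i]] <- list(xdim = d)
    } else if (ly$type == "dense") {
      w <- weights[[ly$name]]
      y <- crossprod(w$W, x) + w$b            # out x N
      if (ly$relu) y <- relu(y)
      if (keep_cache) cache[[i]] <- list(x = x, y = y)
    } else if (ly$type == "softmax") {
      logits <- x
      m <- apply(logits, 2, max)
      e <- exp(sweep(logits, 2, m))
      y <- sweep(e, 2, colSums(e), "/")       # L x N
    }
    x <- y
  }
  list(post = t(x), logits = NULL, cache = cache)
}

#' Run a network forward
#'
#' Computes the class posterior for a batch of RGB images. The fire
#' variant is fully convolutional and accepts any spatial size of at
#' least 32 pixels; the dense-head baseline requires exactly 32x32.
#'
#' @param spec A `"gpdnet_spec"`.
#' @param weights A matching `"weight_store"`.
#' @param batch An `(H, W, 3)` image or `(H, W, 3, N)` batch with values
#'   in `[0, 1]`, or a [image_set()].
#' @return An `N x num_classes` matrix of posteriors; rows sum to 1.
#' @export
forward <- function(spec, weights, batch) {
  if (inherits(batch, "gpd_image_set")) batch <- batch$images
  nn_forward(spec, weights, batch)$post
}

# Backward pass. dpost_logits is the gradient at the softmax INPUT
# (i.e. (P - Y) / n for mean cross-entropy), an L x N matrix.
# Returns gradients shaped exactly like the weight store.
nn_backward <- function(spec, weights, cache, dpost_logits) {
  grads <- list()
  dy <- dpost_logits
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    if (ly$type == "softmax") {
      next   # folded into dpost_logits
    } else if (ly$type == "dense") {
      w <- weights[[ly$name]]
      cc <- cache[[i]]
      if (ly$relu) dy <- dy * (cc$y > 0)
      grads[[ly$name]] <- list(W = cc$x %*% t(dy), b = rowSums(dy))
      dy <- w$W %*% dy
    } else if (ly$type == "flatten") {
      dim(dy) <- cache[[i]]$xdim
    } else if (ly$type == "gap") {
      d <- cache[[i]]$xdim
      dx <- array(0, d)
      scale <- 1 / (d[1] * d[2])
      for (n in seq_len(d[4]))
        dx[, , , n] <- rep(dy[, n] * scale, each = d[1] * d[2])
      dy <- dx
    } else if (ly$type == "pool") {
      cc <- cache[[i]]
      dy <- pool_backward_cpp(dy, cc$idx, cc$xdim, ly$window, ly$stride,
                              if (ly$kind == "max") 0L else 1L)
    } else if (ly$type == "conv") {
      w <- weights[[ly$name]]
      cc <- cache[[i]]
      bk <- conv_backward_cpp(cc$x, w$W, cc$y, dy, ly$stride, ly$pad,
                              ly$relu)
      grads[[ly$name]] <- if (ly$bias) list(W = bk$dw, b = bk$db)
                          else list(W = bk$dw)
      dy <- bk$dx
    } else if (ly$type == "fire") {
      w <- weights[[ly$name]]
      cc <- cache[[i]]
      c1 <- ly$expand1x1_channels
      dy1 <- dy[, , seq_len(c1), , drop = FALSE]
      dy3 <- dy[, , c1 + seq_len(ly$expand3x3_channels), , drop = FALSE]
      b1 <- conv_backward_cpp(cc$s, w$W_expand1, cc$e1, dy1, 1L, 0L, TRUE)
      b3 <- conv_backward_cpp(cc$s, w$W_expand3, cc$e3, dy3, 1L, 1L, TRUE)
      ds <- b1$dx + b3$dx
      bs <- conv_backward_cpp(cc$x, w$W_squeeze, cc$s, ds, 1L, 0L, TRUE)
      grads[[ly$name]] <- list(W_squeeze = bs$dw, b_squeeze = bs$db,
                               W_expand1 = b1$dw, b_expand1 = b1$db,
                               W_expand3 = b3$dw, b_expand3 = b3$db)
      dy <- bs$dx
    }
  }
  grads
}
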