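# Convolutional backbone adapter.
#
# The classifier, attribution and embedding stages only require a backbone
# exposing (a) last-convolutional-layer activations and their gradients,
# (b) a global-average-pooled feature vector of declared dimension and
# (c) gradients of any pooled-feature functional with respect to the input.
# This file implements that contract for plain feed-forward CNNs
# (same-padded convolutions, ReLU, 2x2 average pooling) in base R via
# im2col matrix products, including the reverse-mode pass. All primitives
# operate on image batches (H x W x C x N arrays) so each layer is a single
# BLAS product. The reference backbone is a fixed-seed random-weight
# 3-block CNN: it is never trained (weights stay frozen; only the
# classification head is learned), which is exactly the role a large
# pretrained feature extractor plays at full scale.

# --- batched primitive ops -------------------------------------------------
#
# Internal batch layout is (H, W, N, C): with channels as the slowest
# dimension, every im2col tap block flattens to an (H*W*N) x C matrix by a
# dim<- re-interpretation alone (no transposition, no copy), which keeps the
# whole layer at one BLAS product plus strided slices.

# im2col in (H, W, N, C) layout: rows (pixel, image), columns (tap, channel)
im2col_same_batch <- function(x, kh, kw) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + 2 * ph, W + 2 * pw, N, C))
  xp[(ph + 1):(ph + H), (pw + 1):(pw + W), , ] <- x
  out <- matrix(0, H * W * N, kh * kw * C)
  m <- 0L
  for (ki in seq_len(kh)) {
    for (kj in seq_len(kw)) {
      block <- xp[ki:(ki + H - 1), kj:(kj + W - 1), , , drop = FALSE]
      dim(block) <- c(H * W * N, C)
      out[, m + seq_len(C)] <- block
      m <- m + C
    }
  }
  out
}

# kernel array (kh, kw, Cin, Cout) -> matrix (kh*kw*Cin, Cout) in im2col order
kernel_matrix <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(3, 2, 1, 4)), d[1] * d[2] * d[3], d[4])
}

conv_same_batch <- function(x, W, b = NULL) {
  if (is.null(b)) b <- numeric(dim(W)[4])
  conv_same_cpp(x, dim(x), W, dim(W), b)
}

# reference pure-R path, kept for cross-checking the compiled kernel
conv_same_batch_r <- function(x, W, b = NULL) {
  d <- dim(W); dx <- dim(x)
  y <- im2col_same_batch(x, d[1], d[2]) %*% kernel_matrix(W)
  if (!is.null(b) && any(b != 0)) {
    y <- y + rep(b, each = nrow(y))
  }
  dim(y) <- c(dx[1], dx[2], dx[3], d[4])
  y
}

# gradient of a same-padded convolution w.r.t. its input: convolution of the
# upstream gradient with the spatially flipped, channel-transposed kernels
conv_same_input_grad_batch <- function(dy, W) {
  kh <- dim(W)[1]; kw <- dim(W)[2]
  Wf <- aperm(W[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
  conv_same_batch(dy, Wf)
}

pool2_batch <- function(x) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  (x[seq(1, H, 2), seq(1, Wd, 2), , , drop = FALSE] +
   x[seq(2, H, 2), seq(1, Wd, 2), , , drop = FALSE] +
   x[seq(1, H, 2), seq(2, Wd, 2), , , drop = FALSE] +
   x[seq(2, H, 2), seq(2, Wd, 2), , , drop = FALSE]) / 4
}

unpool2_batch <- function(dy) {
  d <- dim(dy)
  dy[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE] / 4
}

# user-facing batches are (H, W, C, N); internally channels go last
to_internal_batch <- function(x) {
  if (length(dim(x)) == 3) {
    d <- dim(x)
    array(x, c(d[1], d[2], 1L, d[3]))
  } else {
    aperm(x, c(1, 2, 4, 3))
  }
}

# --- backbone construction -------------------------------------------------

#' Build a CNN backbone from a layer list
#'
#' @param layers list of layers; each is `list(type = "conv", W = <kh x kw x
#'   Cin x Cout array>, b = <length-Cout bias>)`, `list(type = "relu")` or
#'   `list(type = "pool")` (2x2 average pooling).
#' @param input_size expected square input side.
#' @param in_channels expected input channel count.
#' @param pool_taps layer indices whose (post-layer) activations are read
#'   out by global average pooling and concatenated into the pooled
#'   feature vector. Default: the last layer only. Multi-scale taps keep
#'   fine, pre-pooling detail (e.g. contour texture) visible to the head;
#'   the last tap is always the final layer, whose activations define the
#'   Grad-CAM map.
#' @return a `cnn_backbone` with declared `pooled_dim`.
#' @export
cnn_backbone <- function(layers, input_size, in_channels = 3L,
                         pool_taps = NULL) {
  convs <- Filter(function(l) l$type == "conv", layers)
  if (!length(convs)) stop("backbone needs at least one conv layer", call. = FALSE)
  pool_taps <- as.integer(pool_taps %||% length(layers))
  if (max(pool_taps) != length(layers)) {
    stop("the last layer must be a pool tap", call. = FALSE)
  }
  layer_channels <- function(i) {
    # channel count of the activation after layer i
    for (j in rev(seq_len(i))) {
      if (layers[[j]]$type == "conv") return(dim(layers[[j]]$W)[4])
    }
    in_channels
  }
  tap_dims <- vapply(pool_taps, layer_channels, 0L)
  slices <- list(); off <- 0L
  for (i in seq_along(pool_taps)) {
    slices[[i]] <- off + seq_len(tap_dims[i])
    off <- off + tap_dims[i]
  }
  structure(
    list(layers = layers, input_size = as.integer(input_size),
         in_channels = as.integer(in_channels), pooled_dim = off,
         pool_taps = pool_taps, pooled_slices = slices),
    class = "cnn_backbone"
  )
}

#' Reference tiny backbone
#'
#' A frozen, fixed-seed, He-initialized random-weight CNN of
#' conv3x3-ReLU blocks separated by 2x2 average pooling (default three
#' blocks). The pooled feature vector concatenates global average
#' pooling taken after each block's ReLU (multi-scale), so full-resolution
#' edge statistics survive next to the coarser deep features; the pooled
#' dimension is `sum(channels)`. Random convolutional features read out
#' area, color, contour and background statistics well enough for a linear
#' head at desk scale.
#'
#' @param input_size square input side (multiple of `2^(length(channels)-1)`).
#' @param channels channel widths of the blocks.
#' @param seed weight-initialization seed (part of the backbone identity).
#' @return a `cnn_backbone`.
#' @export
tiny_backbone <- function(input_size = 64, channels = c(12, 24, 48),
                          seed = 42) {
  n_blocks <- length(channels)
  stride <- 2^(n_blocks - 1)
  if (input_size %% stride != 0) {
    stop("input_size must be a multiple of ", stride, call. = FALSE)
  }
  cin <- c(3L, channels[-n_blocks])
  layers <- with_private_rng(seed, {
    out <- list()
    for (i in seq_len(n_blocks)) {
      W <- array(stats::rnorm(9 * cin[i] * channels[i], sd = sqrt(2 / (9 * cin[i]))),
                 c(3, 3, cin[i], channels[i]))
      out <- c(out, list(list(type = "conv", W = W, b = rep(0, channels[i])),
                         list(type = "relu")))
      if (i < n_blocks) out <- c(out, list(list(type = "pool")))
    }
    out
  })
  taps <- cumsum(c(2L, rep(3L, n_blocks - 1L)))
  bb <- cnn_backbone(layers, input_size = input_size, in_channels = 3L,
                     pool_taps = taps)
  bb$seed <- seed
  bb
}

#' @export
print.cnn_backbone <- function(x, ...) {
  cat(sprintf("<cnn_backbone> input %d px, pooled dim %d, %d layers\n",
              x$input_size, x$pooled_dim, length(x$layers)))
  invisible(x)
}

#' Serialize-and-hash a backbone's weights
#'
#' Used to verify the frozen-backbone guarantee: the hash must be identical
#' before and after head training.
#'
#' @param backbone a `cnn_backbone`.
#' @return character hash.
#' @export
backbone_weight_hash <- function(backbone) {
  if (!requireNamespace("digest", quietly = TRUE)) {
    stop("backbone_weight_hash requires the 'digest' package", call. = FALSE)
  }
  digest::digest(lapply(backbone$layers, function(l) l[c("W", "b")]), algo = "sha256")
}

# --- forward / backward ----------------------------------------------------

check_backbone_input <- function(backbone, x) {
  d <- dim(x)
  if (d[1] != backbone$input_size || d[2] != backbone$input_size ||
      d[3] != backbone$in_channels) {
    stop(sprintf("backbone expects %d x %d x %d input, got %s",
                 backbone$input_size, backbone$input_size, backbone$in_channels,
                 paste(d[1:3], collapse = " x ")), call. = FALSE)
  }
}

gap_batch <- function(a) {
  d <- dim(a)
  matrix(colMeans(matrix(a, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

# gradient injected at an activation by GAP readout: g (N x C) -> (H, W, N, C)
gap_grad_batch <- function(g, d) {
  aperm(array(as.vector(g) / (d[1] * d[2]), c(d[3], d[4], d[1], d[2])),
        c(3, 4, 1, 2))
}

# Forward pass over an internal-layout batch (H, W, N, C). `pooled` comes
# back as an N x pooled_dim matrix (concatenated GAP taps), `last_conv` in
# internal layout.
bb_forward_batch <- function(backbone, x, cache = FALSE) {
  check_backbone_input(backbone, x)
  x <- to_internal_batch(x)
  acts <- if (cache) vector("list", length(backbone$layers) + 1L) else NULL
  a <- x
  if (cache) acts[[1]] <- a
  taps <- list()
  for (i in seq_along(backbone$layers)) {
    l <- backbone$layers[[i]]
    a <- switch(l$type,
      conv = conv_same_batch(a, l$W, l$b),
      relu = pmax(a, 0),
      pool = pool2_batch(a),
      stop("unknown layer type: ", l$type)
    )
    if (cache) acts[[i + 1L]] <- a
    if (i %in% backbone$pool_taps) taps[[length(taps) + 1L]] <- gap_batch(a)
  }
  out <- list(pooled = do.call(cbind, taps), last_conv = a)
  if (cache) out$cache <- acts
  out
}

# Reverse-mode pass for a batch: g is an N x pooled_dim matrix of gradients
# at the (concatenated) pooled features; returns the input gradient in
# internal layout (H, W, N, C).
bb_input_grad_batch <- function(backbone, cache, g) {
  final <- cache[[length(cache)]]
  da <- array(0, dim(final))
  for (i in rev(seq_along(backbone$layers))) {
    tap <- match(i, backbone$pool_taps)
    if (!is.na(tap)) {
      gi <- g[, backbone$pooled_slices[[tap]], drop = FALSE]
      da <- da + gap_grad_batch(gi, dim(cache[[i + 1L]]))
    }
    l <- backbone$layers[[i]]
    da <- switch(l$type,
      conv = conv_same_input_grad_batch(da, l$W),
      relu = da * (cache[[i]] > 0),
      pool = unpool2_batch(da)
    )
  }
  da
}

#' Backbone forward pass (single image)
#'
#' @param backbone a `cnn_backbone`.
#' @param x input array (size and channels per the backbone contract).
#' @param cache keep intermediate activations for a subsequent backward
#'   pass.
#' @return list with `pooled` (feature vector), `last_conv` (final spatial
#'   activation, post-ReLU) and, if requested, `cache`.
#' @export
backbone_forward <- function(backbone, x, cache = FALSE) {
  out <- bb_forward_batch(backbone, unclass(x), cache = cache)
  d <- dim(out$last_conv)  # internal layout (H, W, 1, C)
  list(pooled = out$pooled[1, ],
       last_conv = array(out$last_conv, c(d[1], d[2], d[4])),
       cache = out$cache)
}

#' Gradient of a pooled-feature functional w.r.t. the input (single image)
#'
#' @param backbone a `cnn_backbone`.
#' @param cache forward cache from `backbone_forward(..., cache = TRUE)`.
#' @param g gradient vector at the pooled features (for a linear head and
#'   target class c this is the head weight column).
#' @return H x W x C array.
#' @export
backbone_input_grad <- function(backbone, cache, g) {
  da <- bb_input_grad_batch(backbone, cache, matrix(g, nrow = 1))
  d <- dim(da)  # internal layout (H, W, 1, C)
  array(da, c(d[1], d[2], d[4]))
}

#' Extract pooled features for a set of preprocessed images
#'
#' @param backbone a `cnn_backbone`.
#' @param images list of preprocessed arrays (or a single array).
#' @param batch_size images per forward batch.
#' @return matrix with one row per image and `pooled_dim` columns; row names
#'   taken from the list names.
#' @export
extract_features <- function(backbone, images, batch_size = 64L) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  n <- length(images)
  out <- matrix(0, n, backbone$pooled_dim)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- array(0, c(backbone$input_size, backbone$input_size,
                    backbone$in_channels, j - i + 1L))
    for (k in i:j) {
      check_backbone_input(backbone, unclass(images[[k]]))
      x[, , , k - i + 1L] <- unclass(images[[k]])
    }
    out[i:j, ] <- bb_forward_batch(backbone, x)$pooled
    i <- j + 1L
  }
  rownames(out) <- names(images)
  out
}
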