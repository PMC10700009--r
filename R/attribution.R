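# Class-discriminative attribution maps.
#
# Grad-CAM is computed from its definition: channel weights are the spatial
# means of the target-logit gradients at the last convolutional layer, the
# weighted activation sum is rectified after summation, bilinearly
# upsampled and min-max normalized. Integrated gradients averages input
# gradients along the straight path from a baseline; the XRAI-style method
# aggregates integrated gradients (black and white baselines) over a
# multi-scale oversegmentation and greedily ranks regions by attribution
# gain.

new_attribution_map <- function(values, method, target_class, logit, id = NULL) {
  structure(
    list(values = values, method = method, target_class = target_class,
         logit = logit, id = id),
    class = "attribution_map"
  )
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %s for class '%s' (logit %.3f), %d x %d\n",
              x$method, x$target_class, x$logit, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# min-max normalize to [0, 1]; identically-zero maps stay zero (with a
# warning at the call sites that care)
minmax01 <- function(v) {
  hi <- max(v); lo <- min(v)
  if (hi == lo) return(v * 0)
  (v - lo) / (hi - lo)
}

classifier_backbone <- function(classifier) {
  bb <- classifier$backbone
  if (is.null(bb)) {
    stop("classifier has no attached backbone (train with `backbone = `)",
         call. = FALSE)
  }
  bb
}

target_index <- function(classifier, target_class) {
  k <- match(target_class, classifier$classes)
  if (is.na(k)) stop("unknown target class: ", target_class, call. = FALSE)
  k
}

#' Grad-CAM heatmap
#'
#' @param classifier a `trained_classifier` with an attached backbone.
#' @param image preprocessed image (backbone input size).
#' @param target_class class whose logit is explained; default the
#'   predicted class.
#' @return an `attribution_map` at image resolution, values in \[0, 1\].
#' @export
grad_cam <- function(classifier, image, target_class = NULL) {
  bb <- classifier_backbone(classifier)
  x <- unclass(image)
  f <- backbone_forward(bb, x)
  logits <- as.numeric(classifier_logits(classifier, matrix(f$pooled, 1)))
  if (is.null(target_class)) {
    target_class <- classifier$classes[which.max(logits)]
  }
  k <- target_index(classifier, target_class)
  A <- f$last_conv
  d <- dim(A)
  # d y_c / d A^k is constant over space for a linear head on global average
  # pooling: head weight / cell count; its spatial mean equals itself. Only
  # the head weights reading the last-conv tap contribute.
  last_slice <- bb$pooled_slices[[length(bb$pooled_slices)]]
  alpha <- pooled_gradient(classifier, k)[last_slice] / (d[1] * d[2])
  raw <- matrix(matrix(A, d[1] * d[2], d[3]) %*% alpha, d[1], d[2])
  raw <- pmax(raw, 0)
  up <- resize_array(raw, dim(x)[1], bilinear = TRUE)
  if (max(up) == 0) {
    warning("Grad-CAM map is identically zero for this image/class")
  }
  new_attribution_map(minmax01(up), "gradcam", target_class, logits[k])
}

#' Integrated gradients
#'
#' Signed per-pixel attribution: (image - baseline) times the mean of the
#' input gradients of the target logit along the straight-line path from
#' baseline to image, sampled at `steps` midpoints. Completeness (sum of
#' attributions equals the logit difference) holds as `steps` grows.
#'
#' @param classifier a `trained_classifier` with backbone.
#' @param image preprocessed image.
#' @param baseline array of the same shape.
#' @param steps path samples (>= 2).
#' @param target_class class whose logit is attributed; default predicted.
#' @return H x W x C signed attribution array.
#' @export
integrated_gradients <- function(classifier, image, baseline, steps = 25,
                                 target_class = NULL) {
  if (steps < 2) stop("steps must be >= 2", call. = FALSE)
  bb <- classifier_backbone(classifier)
  x <- unclass(image); b0 <- unclass(baseline)
  if (!all(dim(x) == dim(b0))) stop("baseline shape mismatch", call. = FALSE)
  if (is.null(target_class)) {
    p <- backbone_forward(bb, x)$pooled
    target_class <- classifier$classes[
      which.max(classifier_logits(classifier, matrix(p, 1)))]
  }
  k <- target_index(classifier, target_class)
  alphas <- (seq_len(steps) - 0.5) / steps
  d <- dim(x)
  xs <- array(0, c(d, steps))
  diff <- x - b0
  for (s in seq_len(steps)) xs[, , , s] <- b0 + alphas[s] * diff
  fwd <- bb_forward_batch(bb, xs, cache = TRUE)
  g <- matrix(pooled_gradient(classifier, k), steps, bb$pooled_dim, byrow = TRUE)
  grads <- bb_input_grad_batch(bb, fwd$cache, g)  # internal (H, W, N, C)
  avg <- apply(grads, c(1, 2, 4), mean)
  diff * avg
}

# SLIC-style oversegmentation: k-means on (row, col, R, G, B) with spatial
# coordinates scaled to balance color compactness
oversegment <- function(image_raw, n_segments, seed = 1, spatial_weight = 0.6) {
  d <- dim(image_raw)
  rows <- as.vector(matrix(seq_len(d[1]), d[1], d[2])) / d[1]
  cols <- as.vector(matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)) / d[2]
  feat <- cbind(spatial_weight * rows, spatial_weight * cols,
                as.vector(image_raw[, , 1]), as.vector(image_raw[, , 2]),
                as.vector(image_raw[, , 3]))
  km <- with_private_rng(seed, suppressWarnings(
    stats::kmeans(feat, centers = n_segments, iter.max = 30, nstart = 1)
  ))
  km$cluster
}

#' XRAI-style region-ranked attribution
#'
#' Pixel attributions are the channel sums of integrated gradients averaged
#' over black and white baselines. The image is oversegmented at several
#' scales; regions are greedily selected by mean attribution gain over the
#' pixels they add, and every pixel receives the gain at which it was first
#' covered. The result is min-max normalized.
#'
#' @param classifier a `trained_classifier` with backbone.
#' @param image preprocessed (`normalized_image`) input.
#' @param target_class class to explain; default predicted.
#' @param segment_scales segment counts for the oversegmentation scales.
#' @param steps integration steps per baseline.
#' @param seed seed for the k-means oversegmentation.
#' @return an `attribution_map` with method `"xrai"`.
#' @export
xrai <- function(classifier, image, target_class = NULL,
                 segment_scales = c(40, 100, 220), steps = 25, seed = 1) {
  bb <- classifier_backbone(classifier)
  x <- unclass(image)
  norm <- attr(image, "normalization") %||%
    list(mean = c(0, 0, 0), sd = c(1, 1, 1))
  f <- backbone_forward(bb, x)
  logits <- as.numeric(classifier_logits(classifier, matrix(f$pooled, 1)))
  if (is.null(target_class)) target_class <- classifier$classes[which.max(logits)]
  k <- target_index(classifier, target_class)

  # black and white baselines, expressed in the image's normalized scale
  make_baseline <- function(value) {
    b <- array(0, dim(x))
    for (ch in 1:3) b[, , ch] <- (value - norm$mean[ch]) / norm$sd[ch]
    b
  }
  attr_sum <- matrix(0, dim(x)[1], dim(x)[2])
  for (bl in list(make_baseline(0), make_baseline(1))) {
    ig <- integrated_gradients(classifier, x, bl, steps = steps,
                               target_class = target_class)
    attr_sum <- attr_sum + ig[, , 1] + ig[, , 2] + ig[, , 3]
  }
  a <- as.vector(attr_sum / 2)

  # denormalized image for segmentation
  raw <- x
  for (ch in 1:3) raw[, , ch] <- x[, , ch] * norm$sd[ch] + norm$mean[ch]
  regions <- list()
  for (i in seq_along(segment_scales)) {
    cl <- oversegment(raw, segment_scales[i], seed = derive_seed(seed, i))
    regions <- c(regions, split(seq_along(cl), cl))
  }
  if (length(regions) < 2) {
    stop("degenerate segmentation: need at least 2 regions", call. = FALSE)
  }

  npix <- length(a)
  covered <- logical(npix)
  out <- numeric(npix)
  gains <- vapply(regions, function(idx) mean(a[idx]), 0)
  active <- rep(TRUE, length(regions))
  while (any(active) && !all(covered)) {
    r <- which(active)[which.max(gains[active])]
    novel <- regions[[r]][!covered[regions[[r]]]]
    active[r] <- FALSE
    if (!length(novel)) next
    out[novel] <- gains[r]
    covered[novel] <- TRUE
    # refresh gains of still-active regions that overlap the newly covered set
    for (q in which(active)) {
      nv <- regions[[q]][!covered[regions[[q]]]]
      if (!length(nv)) {
        active[q] <- FALSE
      } else {
        gains[q] <- mean(a[nv])
      }
    }
  }
  vals <- minmax01(matrix(out, dim(x)[1], dim(x)[2]))
  new_attribution_map(vals, "xrai", target_class, logits[k])
}

#' Write an attribution map to disk
#'
#' Values as 32-bit single-channel TIFF plus an 8-bit grayscale PNG
#' overlay, with a JSON sidecar recording method, class, logit and
#' parameters.
#'
#' @param map an `attribution_map`.
#' @param path output path without extension.
#' @return invisibly, the sidecar list.
#' @export
write_attribution_map <- function(map, path) {
  if (requireNamespace("tiff", quietly = TRUE)) {
    tiff::writeTIFF(map$values, paste0(path, ".tif"), bits.per.sample = 32)
  }
  png::writePNG(map$values, paste0(path, ".png"))
  side <- list(method = map$method, target_class = map$target_class,
               logit = map$logit, id = map$id)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(side)
}
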