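# Deterministic preprocessing: center crop, scale-bar erasure, dihedral
# augmentation (training only), resize, [0,1] scaling and per-channel
# standardization with fixed constants.

#' Default preprocessing options
#'
#' The crop is expressed as a fraction of the long side (0.75, matching a
#' 1,200-px crop of a 1,200 x 1,600 frame) so that images of any resolution
#' follow the same geometry. Normalization uses the conventional
#' ImageNet channel statistics.
#'
#' @param crop_fraction center-crop side as a fraction of the long side.
#' @param target_size output side length in pixels.
#' @param normalization_mean,normalization_sd per-channel constants applied
#'   after scaling intensities to \[0, 1\].
#' @param scale_bar_box optional `(row1, row2, col1, col2)` rectangle erased
#'   before resizing.
#' @return list of options for [preprocess_image()].
#' @export
preprocess_options <- function(crop_fraction = 0.75, target_size = 300,
                               normalization_mean = c(0.485, 0.456, 0.406),
                               normalization_sd = c(0.229, 0.224, 0.225),
                               scale_bar_box = NULL) {
  list(crop_fraction = crop_fraction, target_size = as.integer(target_size),
       normalization_mean = normalization_mean,
       normalization_sd = normalization_sd, scale_bar_box = scale_bar_box)
}

center_crop <- function(x, crop_size) {
  d <- dim(x)
  if (crop_size > min(d[1], d[2])) {
    stop(sprintf("crop size %d exceeds image dimensions %d x %d",
                 crop_size, d[1], d[2]), call. = FALSE)
  }
  r0 <- floor((d[1] - crop_size) / 2) + 1
  c0 <- floor((d[2] - crop_size) / 2) + 1
  if (length(d) == 3) {
    x[r0:(r0 + crop_size - 1), c0:(c0 + crop_size - 1), , drop = FALSE]
  } else {
    x[r0:(r0 + crop_size - 1), c0:(c0 + crop_size - 1), drop = FALSE]
  }
}

# Fill the scale-bar rectangle with the median color of a 10-px ring around
# it, estimated per channel; boxes are (row1, row2, col1, col2) before crop.
erase_scale_bar <- function(image, box, ring = 10L) {
  d <- dim(image)
  box <- as.integer(box)
  if (box[1] < 1 || box[3] < 1 || box[2] > d[1] || box[4] > d[2]) {
    stop("scale_bar_box lies outside the image frame", call. = FALSE)
  }
  rr <- max(1, box[1] - ring):min(d[1], box[2] + ring)
  cc <- max(1, box[3] - ring):min(d[2], box[4] + ring)
  inner_r <- rr >= box[1] & rr <= box[2]
  inner_c <- cc >= box[3] & cc <= box[4]
  for (ch in 1:3) {
    patch <- image[rr, cc, ch]
    ringpix <- patch[!(outer(inner_r, inner_c, `&`))]
    image[box[1]:box[2], box[3]:box[4], ch] <- stats::median(ringpix)
  }
  image
}

# The 8-element dihedral orbit of a square array: rotations by 0/90/180/270
# degrees, each optionally composed with a horizontal flip.
dihedral_orbit <- function(x) {
  rot90 <- function(a) {
    if (length(dim(a)) == 3) {
      aperm(a, c(2, 1, 3))[rev(seq_len(dim(a)[2])), , , drop = FALSE]
    } else {
      t(a)[rev(seq_len(ncol(a))), , drop = FALSE]
    }
  }
  hflip <- function(a) {
    if (length(dim(a)) == 3) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
    else a[, rev(seq_len(ncol(a))), drop = FALSE]
  }
  r0 <- x; r1 <- rot90(x); r2 <- rot90(r1); r3 <- rot90(r2)
  list(r0 = r0, r90 = r1, r180 = r2, r270 = r3,
       f0 = hflip(r0), f90 = hflip(r1), f180 = hflip(r2), f270 = hflip(r3))
}

#' Dihedral augmentation
#'
#' Returns the orbit of a square image under the dihedral group of order 8
#' (right-angle rotations times optional horizontal flip), deduplicated for
#' symmetric inputs.
#'
#' @param image square matrix or H x W x C array.
#' @param dedupe drop bit-identical variants (default TRUE).
#' @return named list of variants.
#' @export
augment_dihedral <- function(image, dedupe = TRUE) {
  d <- dim(image)
  if (d[1] != d[2]) {
    stop("augmentation requires a square image (rotation would change the frame)",
         call. = FALSE)
  }
  orb <- dihedral_orbit(image)
  if (!dedupe) return(orb)
  keys <- vapply(orb, function(v) paste(format(v, digits = 17), collapse = ","), "")
  orb[!duplicated(keys)]
}

#' Preprocess an image for the classifier
#'
#' Center crop -> scale-bar erasure -> (train mode) dihedral augmentation ->
#' resize -> per-channel standardization. Eval mode is deterministic and
#' applies no flip or rotation.
#'
#' @param image numeric H x W x 3 array in \[0, 1\].
#' @param mode `"eval"` returns one normalized image; `"train"` returns the
#'   list of augmented variants.
#' @param options a [preprocess_options()] list.
#' @return a `normalized_image` array (attributes `normalization` record the
#'   constants), or a list of them in train mode.
#' @export
preprocess_image <- function(image, mode = c("eval", "train"),
                             options = preprocess_options()) {
  mode <- match.arg(mode)
  assert_rgb(image)
  d <- dim(image)
  crop_size <- round(options$crop_fraction * max(d[1], d[2]))
  x <- center_crop(image, crop_size)
  if (!is.null(options$scale_bar_box)) {
    # box coordinates are given in the original frame; shift into the crop
    r_off <- floor((d[1] - crop_size) / 2)
    c_off <- floor((d[2] - crop_size) / 2)
    box <- as.integer(options$scale_bar_box) - c(r_off, r_off, c_off, c_off)
    box[c(1, 3)] <- pmax(box[c(1, 3)], 1L)
    box[c(2, 4)] <- pmin(box[c(2, 4)], crop_size)
    if (box[1] <= box[2] && box[3] <= box[4]) x <- erase_scale_bar(x, box)
  }
  finish <- function(v) {
    v <- resize_array(clamp01(v), options$target_size, bilinear = TRUE)
    for (ch in 1:3) {
      v[, , ch] <- (v[, , ch] - options$normalization_mean[ch]) /
        options$normalization_sd[ch]
    }
    structure(v, normalization = list(mean = options$normalization_mean,
                                      sd = options$normalization_sd),
              class = "normalized_image")
  }
  if (mode == "eval") return(finish(x))
  lapply(dihedral_orbit(x), finish)
}

#' Preprocess a mask with the identical geometry
#'
#' Applies the same center crop and resize as [preprocess_image()] but with
#' nearest-neighbor resampling, preserving pixel-for-pixel correspondence
#' with the preprocessed image.
#'
#' @param mask silhouette mask or logical matrix.
#' @param options a [preprocess_options()] list.
#' @return logical matrix of side `target_size`.
#' @export
preprocess_mask <- function(mask, options = preprocess_options()) {
  m <- as_mask_matrix(mask)
  crop_size <- round(options$crop_fraction * max(dim(m)))
  m <- center_crop(m, crop_size)
  out <- resize_array(matrix(as.numeric(m), nrow(m)), options$target_size,
                      bilinear = FALSE)
  out > 0.5
}
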