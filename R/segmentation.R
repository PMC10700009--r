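# Silhouette segmentation and area morphometrics.
#
# The mask is produced by Gaussian blur -> grayscale -> global Otsu
# threshold -> binary dilation -> hole filling -> largest connected
# component. Filter bandwidths are quoted at a reference image width of
# 1,200 px and scaled proportionally to the image at hand, so the same
# defaults serve both full-resolution micrographs and desk-scale synthetic
# images.

scale_bandwidth <- function(bandwidth, image_long_side, reference_width = 1200) {
  bandwidth * image_long_side / reference_width
}

#' Segment the plant silhouette from an RGB image
#'
#' @param image numeric H x W x 3 array in \[0, 1\].
#' @param blur_bandwidth Gaussian sigma in pixels at the reference width
#'   (default 10; the severe-blur ablation uses 60).
#' @param dilation_radius disc radius in pixels at 256-px scale (default 1),
#'   scaled proportionally; set 0 to skip dilation. A small safety margin
#'   makes the mask cover the whole plant without inflating its area.
#' @param fill_holes fill enclosed background holes in the mask.
#' @param reference_width image width at which `blur_bandwidth` is quoted.
#' @param polarity `"auto"` picks the Otsu side that touches the image
#'   border least (tie: the smaller side); `"bright"`/`"dark"` force the
#'   side above/below the threshold.
#' @return a [silhouette_mask()] with provenance `"segmented"`.
#' @export
segment_plant <- function(image, blur_bandwidth = 10, dilation_radius = 1,
                          fill_holes = TRUE, reference_width = 1200,
                          polarity = c("auto", "bright", "dark")) {
  assert_rgb(image)
  polarity <- match.arg(polarity)
  if (blur_bandwidth <= 0) stop("blur_bandwidth must be positive", call. = FALSE)
  gray <- rgb_to_gray(image)
  if (diff(range(gray)) < 1e-8) {
    stop("degenerate intensity histogram: constant image has no Otsu threshold",
         call. = FALSE)
  }
  L <- max(dim(gray))
  sigma <- scale_bandwidth(blur_bandwidth, L, reference_width)
  blurred <- if (sigma >= 0.3) {
    matrix(EBImage::gblur(gray, sigma = sigma), nrow(gray), ncol(gray))
  } else {
    gray
  }
  blurred <- clamp01(blurred)
  if (diff(range(blurred)) < 1e-8) {
    stop("degenerate intensity histogram: constant image has no Otsu threshold",
         call. = FALSE)
  }
  th <- EBImage::otsu(EBImage::Image(blurred), range = range(blurred))
  bright <- blurred > th
  fg <- switch(polarity,
    bright = bright,
    dark = !bright,
    auto = {
      border <- function(m) mean(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
      b_bright <- border(bright); b_dark <- border(!bright)
      if (b_bright < b_dark) bright
      else if (b_dark < b_bright) !bright
      else if (sum(bright) <= sum(!bright)) bright else !bright
    }
  )
  if (!any(fg)) {
    warning("empty foreground after thresholding; returning empty mask")
    return(silhouette_mask(fg, "segmented"))
  }
  m <- EBImage::Image(matrix(as.numeric(fg), nrow(fg)))
  rad <- max(0L, round(dilation_radius * L / 256))
  if (rad >= 1) {
    m <- EBImage::dilate(m, EBImage::makeBrush(2 * rad + 1, shape = "disc"))
  }
  if (fill_holes) m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  labv <- as.integer(lab)
  if (max(labv) > 1) {
    keep <- which.max(tabulate(labv[labv > 0]))
    m <- lab == keep
  }
  silhouette_mask(matrix(as.logical(m), nrow(fg)), "segmented")
}

#' Foreground area of a mask
#'
#' @param mask a silhouette mask or logical matrix.
#' @param pixel_size physical side length of one pixel; if given, the area
#'   is returned in `pixel_size^2` units instead of px^2.
#' @return numeric scalar.
#' @export
measure_area <- function(mask, pixel_size = NULL) {
  m <- as_mask_matrix(mask)
  a <- sum(m)
  if (!is.null(pixel_size)) a <- a * pixel_size^2
  a
}

#' Unbiased standardized mean difference (Hedges' g)
#'
#' Cohen's d from the pooled two-sample SD, shrunk by the small-sample
#' correction J = 1 - 3 / (4 (n1 + n2) - 9).
#'
#' @param sample_a,sample_b numeric vectors with at least two values each.
#' @return an `effect_size_result` list: `g`, `d`, `n1`, `n2`, `mean1`,
#'   `mean2`, `sd_pooled`, `correction`.
#' @export
hedges_g <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least two values", call. = FALSE)
  m1 <- mean(a); m2 <- mean(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    if (isTRUE(all.equal(m1, m2))) {
      d <- 0
    } else {
      stop("degenerate variance: zero pooled variance with unequal means",
           call. = FALSE)
    }
  } else {
    d <- (m1 - m2) / sqrt(sp2)
  }
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  structure(
    list(g = J * d, d = d, n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
         sd_pooled = sqrt(max(sp2, 0)), correction = J),
    class = "effect_size_result"
  )
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("Hedges' g = %.4f (d = %.4f, J = %.4f; n = %d/%d)\n",
              x$g, x$d, x$correction, x$n1, x$n2))
  invisible(x)
}

#' Area table for a dataset
#'
#' Measures foreground area for every record using ground-truth masks when
#' present, otherwise by segmenting.
#'
#' @param dataset a `gemma_dataset`.
#' @param use per-record mask source: `"mask"` (ground truth) or `"segment"`.
#' @return tibble: id, label, line, day, area_px.
#' @export
dataset_areas <- function(dataset, use = c("mask", "segment")) {
  use <- match.arg(use)
  areas <- vapply(dataset$records, function(r) {
    m <- if (use == "mask" && !is.null(r$mask)) r$mask else segment_plant(r$image)
    measure_area(m)
  }, 0)
  dplyr::mutate(dataset$manifest, area_px = areas)
}
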