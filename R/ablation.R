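# Human-interpretable feature ablations.
#
# Three ablations attribute classification information to interpretable
# image properties by destroying them and re-training:
#   I   background_mask  - background painted black; removes background cues
#   II  binarize         - white silhouette on black; additionally removes
#                          foreground color/texture
#   III binarize_blur    - binarization followed by severe Gaussian blurring;
#                          additionally removes fine contour detail
# Ablations act on raw images, before preprocessing/normalization.

ablation_kinds <- function() c("none", "background_mask", "binarize", "binarize_blur")

#' Apply a feature ablation to one image
#'
#' @param image numeric H x W x 3 array in \[0, 1\].
#' @param mask silhouette mask matching the image (ground truth or
#'   segmented).
#' @param kind one of `"none"`, `"background_mask"`, `"binarize"`,
#'   `"binarize_blur"`.
#' @param blur_bandwidth Gaussian sigma for the severe blur, quoted at
#'   `reference_width` (default 60 at 1,200 px) and scaled to the image.
#' @param reference_width see [segment_plant()].
#' @return ablated H x W x 3 array. The severe blur is left gray-valued,
#'   not re-binarized, so no sharp contour is reintroduced.
#' @export
apply_ablation <- function(image, mask, kind = ablation_kinds(),
                           blur_bandwidth = 60, reference_width = 1200) {
  kind <- match.arg(kind)
  assert_rgb(image)
  if (kind == "none") return(image)
  m <- as_mask_matrix(mask)
  if (!mask_dims_match(m, image)) {
    stop("mask dimensions do not match image dimensions", call. = FALSE)
  }
  if (kind == "background_mask") {
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[!m] <- 0
      image[, , ch] <- plane
    }
    return(image)
  }
  bin <- array(rep(as.numeric(m), 3), dim = c(dim(m), 3))
  if (kind == "binarize") return(bin)
  sigma <- scale_bandwidth(blur_bandwidth, max(dim(m)), reference_width)
  plane <- matrix(EBImage::gblur(bin[, , 1], sigma = sigma), nrow(m))
  array(rep(clamp01(plane), 3), dim = c(dim(m), 3))
}

#' Apply one ablation to a whole dataset
#'
#' The identical ablation is applied to every record (hence to training,
#' validation and test partitions alike); the kind and the mask provenance
#' are recorded on the result.
#'
#' @param dataset a `gemma_dataset` whose records carry masks.
#' @param kind ablation kind, see [apply_ablation()].
#' @param blur_bandwidth,reference_width forwarded to [apply_ablation()].
#' @return a `gemma_dataset` with ablated images.
#' @export
ablate_dataset <- function(dataset, kind = ablation_kinds(),
                           blur_bandwidth = 60, reference_width = 1200) {
  kind <- match.arg(kind)
  if (kind == "none") {
    dataset$ablation <- "none"
    return(dataset)
  }
  missing <- vapply(dataset$records, function(r) is.null(r$mask), TRUE)
  if (any(missing)) {
    stop("records without masks: ",
         paste(vapply(dataset$records[missing], `[[`, "", "id"), collapse = ", "),
         call. = FALSE)
  }
  dataset$records <- lapply(dataset$records, function(r) {
    r$image <- apply_ablation(r$image, r$mask, kind, blur_bandwidth, reference_width)
    r
  })
  dataset$ablation <- kind
  dataset
}
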