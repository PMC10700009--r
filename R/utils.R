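# Internal helpers shared across modules.

#' Run code with a private RNG stream
#'
#' Saves and restores `.Random.seed` so that deterministic internals never
#' disturb the caller's random stream.
#'
#' @param seed integer seed for the private stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_private_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based splitting of one user-facing seed into independent per-item
# streams. Keeps every derived seed inside the 32-bit signed range.
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) + 1
  c0 <- as.double(counter) %% 2147483647
  as.integer((s * 48271 + c0 * 16807 + 12345) %% 2147483629)
}

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

assert_rgb <- function(image, arg = "image") {
  if (!is_rgb_image(image)) {
    stop(sprintf("`%s` must be a numeric H x W x 3 array", arg), call. = FALSE)
  }
  invisible(image)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Rec. 709 luma, the conventional grayscale projection for RGB imagery.
rgb_to_gray <- function(image) {
  assert_rgb(image)
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}

mask_dims_match <- function(mask, image) {
  all(dim(mask)[1:2] == dim(image)[1:2])
}

#' Construct a silhouette mask
#'
#' A silhouette mask is a logical H x W matrix flagging foreground pixels
#' (the aerial part of the plant), with a provenance tag recording whether
#' it came from the generator's ground truth or from segmentation.
#'
#' @param pixels logical matrix (TRUE = foreground).
#' @param provenance `"ground_truth"` or `"segmented"`.
#' @return a `silhouette_mask`: logical matrix with a `provenance` attribute.
#' @export
silhouette_mask <- function(pixels, provenance = c("segmented", "ground_truth")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  m <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  attr(m, "provenance") <- provenance
  class(m) <- c("silhouette_mask", class(m))
  m
}

as_mask_matrix <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  matrix(as.logical(mask), nrow(mask), ncol(mask))
}

#' @export
print.silhouette_mask <- function(x, ...) {
  cat(sprintf(
    "<silhouette_mask> %d x %d, area %d px (%s)\n",
    nrow(x), ncol(x), sum(x), attr(x, "provenance") %||% "unknown"
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear resize of a matrix or H x W x C array via EBImage. EBImage indexes
# images as (x, y); plain matrices pass through with dimensions preserved, so
# no transposition is needed for resizing.
resize_array <- function(x, target, bilinear = TRUE) {
  filt <- if (bilinear) "bilinear" else "none"
  if (is.matrix(x)) {
    out <- EBImage::resize(x, w = target, h = target, filter = filt)
    return(matrix(out, target, target))
  }
  ch <- lapply(seq_len(dim(x)[3]), function(k) {
    matrix(EBImage::resize(x[, , k], w = target, h = target, filter = filt),
           target, target)
  })
  array(unlist(ch), dim = c(target, target, length(ch)))
}
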