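# Pooled-feature extraction and 2-D embedding for visual inspection of
# class/day structure. Feature extraction lives in backbone.R
# (extract_features); this file adds the t-SNE projection and its
# bookkeeping.

#' 2-D t-SNE embedding of a feature matrix
#'
#' @param features numeric matrix, one row per image (row names = ids).
#' @param perplexity t-SNE perplexity (default 30).
#' @param iterations gradient-descent iterations (default 1000).
#' @param seed RNG seed (default 1e6).
#' @return tibble: id, x, y; run parameters attached as attribute
#'   `params`.
#' @export
embed_2d <- function(features, perplexity = 30, iterations = 1000,
                     seed = 1000000) {
  X <- as.matrix(features)
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  if (nrow(X) < 3 * perplexity) {
    stop(sprintf(
      "too few rows (%d) for perplexity %g; reduce perplexity below %g",
      nrow(X), perplexity, nrow(X) / 3
    ), call. = FALSE)
  }
  out <- with_private_rng(seed, {
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, max_iter = iterations,
                 check_duplicates = FALSE, pca = FALSE, verbose = FALSE)
  })
  res <- tibble::tibble(
    id = rownames(X) %||% as.character(seq_len(nrow(X))),
    x = out$Y[, 1], y = out$Y[, 2]
  )
  attr(res, "params") <- list(perplexity = perplexity,
                              iterations = iterations, seed = seed)
  res
}

#' Nearest-neighbor label agreement of an embedding
#'
#' Fraction of points whose nearest neighbor in the 2-D embedding shares
#' their label. Used to check which organizing variable (day vs class)
#' dominates the embedding.
#'
#' @param coords tibble/matrix with columns x, y.
#' @param labels vector aligned with rows.
#' @return numeric scalar in \[0, 1\].
#' @export
nn_label_agreement <- function(coords, labels) {
  P <- cbind(coords$x, coords$y)
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  mean(labels[nn] == labels)
}
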