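# Quantitative validation of attribution maps against plant silhouettes:
# 0.5-threshold binarization, intersection-over-union, heatmap-area
# fraction, logit-based representative selection and grouped summaries.

#' Binarize a normalized attribution map
#'
#' @param map an `attribution_map` (or numeric matrix in \[0, 1\]).
#' @param threshold foreground threshold (default 0.5).
#' @return a [silhouette_mask()] flagging pixels `>= threshold`.
#' @export
binarize_heatmap <- function(map, threshold = 0.5) {
  v <- if (inherits(map, "attribution_map")) map$values else map
  silhouette_mask(v >= threshold, "segmented")
}

#' Intersection over union (Jaccard coefficient)
#'
#' @param mask_a,mask_b binary masks of identical dimensions.
#' @return |A intersect B| / |A union B| in \[0, 1\]; two empty masks give
#'   0 with a warning.
#' @export
iou <- function(mask_a, mask_b) {
  a <- as_mask_matrix(mask_a); b <- as_mask_matrix(mask_b)
  if (!all(dim(a) == dim(b))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  un <- sum(a | b)
  if (un == 0) {
    warning("both masks empty; IoU defined as 0")
    return(0)
  }
  sum(a & b) / un
}

#' Heatmap area fraction
#'
#' @param mask binary mask (typically a binarized heatmap).
#' @return foreground pixels / total pixels.
#' @export
heatmap_area_fraction <- function(mask) {
  m <- as_mask_matrix(mask)
  mean(m)
}

#' Select the representative image per group by maximum logit
#'
#' Among correctly predicted images of each group, picks the id with the
#' highest predicted-class (unnormalized) logit as the representative whose
#' heatmap is displayed; ties break to the lexicographically smallest id.
#'
#' @param predictions tibble with columns `id`, `logit`, `correct`, plus
#'   grouping columns.
#' @param group_keys character vector of grouping column names.
#' @return tibble with one row per group that has at least one correct
#'   prediction; groups without one are skipped with a warning.
#' @export
select_representative <- function(predictions, group_keys) {
  df <- dplyr::as_tibble(predictions)
  groups <- dplyr::distinct(df[, group_keys, drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- df
    for (key in group_keys) sel <- sel[sel[[key]] == groups[[key]][i], ]
    sel <- sel[sel$correct, ]
    if (!nrow(sel)) {
      warning(sprintf("no correctly predicted image in group %s; skipped",
                      paste(unlist(groups[i, ]), collapse = "/")))
      next
    }
    sel <- sel[order(-sel$logit, sel$id), ]
    out[[length(out) + 1L]] <- sel[1, c("id", group_keys, "logit")]
  }
  dplyr::bind_rows(out)
}

#' Summarize IoU scores by group
#'
#' @param scores long-format tibble with columns `iou` and grouping columns
#'   (e.g. day, line, sex, method); rows should be restricted to correctly
#'   predicted test images.
#' @param group_keys character vector of grouping columns.
#' @return tibble with per-group n, median IoU and interquartile range;
#'   empty groups are omitted.
#' @export
summarize_iou <- function(scores, group_keys) {
  df <- dplyr::as_tibble(scores)
  dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(group_keys))),
    n = dplyr::n(),
    median_iou = stats::median(.data$iou),
    iqr_iou = stats::IQR(.data$iou),
    .groups = "drop"
  )
}

#' Heatmap/silhouette validation table for a fitted trial
#'
#' For every test image of a fitted split, computes the attribution map of
#' the predicted class, binarizes it at 0.5 and scores IoU against the
#' (geometry-matched) ground-truth silhouette plus the heatmap-area
#' fraction.
#'
#' @param fit one element of `run_trials()$fits` (classifier + split).
#' @param dataset the `gemma_dataset` the cache was built from.
#' @param cache the matching [prepare_features()] cache.
#' @param method `"gradcam"` or `"xrai"`.
#' @param options preprocessing options used for the cache (for mask
#'   geometry).
#' @return long-format tibble: id, day, line, sex, method, iou,
#'   area_fraction, logit, correct.
#' @export
validate_xai <- function(fit, dataset, cache, method = c("gradcam", "xrai"),
                         options = preprocess_options(
                           target_size = fit$classifier$backbone$input_size,
                           scale_bar_box =
                             if (isTRUE(dataset$config$scale_bar))
                               scale_bar_box(dataset$config$image_size)
                         )) {
  method <- match.arg(method)
  cls <- fit$classifier
  ids <- fit$split$test
  recs <- dataset$records[match(ids, dataset$manifest$id)]
  pred <- predict_classifier(cls, cache$eval[ids, , drop = FALSE])
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- recs[[i]]
    img <- preprocess_image(rec$image, mode = "eval", options = options)
    map <- if (method == "gradcam") {
      grad_cam(cls, img, target_class = pred$label[i])
    } else {
      xrai(cls, img, target_class = pred$label[i],
           seed = derive_seed(cls$seed %||% 1, i))
    }
    hm <- binarize_heatmap(map)
    gt <- preprocess_mask(rec$mask, options = options)
    rows[[i]] <- tibble::tibble(
      id = rec$id, day = rec$day, line = rec$line, sex = rec$label,
      method = method,
      iou = if (!any(hm) && !any(gt)) 0 else suppressWarnings(iou(hm, gt)),
      area_fraction = heatmap_area_fraction(hm),
      logit = pred$logit[i],
      correct = pred$label[i] == rec$label
    )
  }
  dplyr::bind_rows(rows)
}
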