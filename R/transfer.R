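# Cross-population transfer prediction: a classifier trained on one pair of
# lines is applied, without any retraining, to images of another pair whose
# class semantics are aligned by an explicit label map.

#' Transfer prediction onto a target population
#'
#' @param classifier a `trained_classifier` trained on the source pair.
#' @param target_cache [prepare_features()] cache of the target dataset
#'   (built with the same backbone and preprocessing).
#' @param label_map named character vector mapping target labels to the
#'   classifier's classes (e.g. `c(male = "male", female = "female")`).
#'   Every target label must be mapped.
#' @param target_split `"all"` evaluates every target image (no target
#'   training occurs, so nothing is held out); `"test"` restricts to the
#'   target's own test partition under `split_seed`.
#' @param split_seed seed for the target split when `target_split = "test"`.
#' @return a `transfer_report`: `eval_report` fields plus source/target
#'   bookkeeping.
#' @export
transfer_predict <- function(classifier, target_cache,
                             label_map = stats::setNames(classifier$classes,
                                                         classifier$classes),
                             target_split = c("all", "test"), split_seed = 1) {
  target_split <- match.arg(target_split)
  labs <- target_cache$labels
  if (!all(unique(labs) %in% names(label_map))) {
    stop("unmapped target labels: ",
         paste(setdiff(unique(labs), names(label_map)), collapse = ", "),
         call. = FALSE)
  }
  ids <- if (target_split == "all") {
    target_cache$ids
  } else {
    split_dataset(labs, ids = target_cache$ids, seed = split_seed)$test
  }
  truth <- unname(label_map[labs[ids]])
  pred <- predict_classifier(classifier, target_cache$eval[ids, , drop = FALSE])
  rep <- evaluate_predictions(pred$label, truth, classes = classifier$classes)
  rep$target_split <- target_split
  rep$n_target <- length(ids)
  class(rep) <- c("transfer_report", class(rep))
  rep
}
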