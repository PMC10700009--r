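# Experiment orchestration: ties generation, segmentation morphometrics,
# ablation, multi-trial training, attribution validation and optional
# transfer prediction into one reproducible run driven by a single config
# and seed.

#' Experiment configuration
#'
#' @param dataset a [synthetic_config()] describing the source population.
#' @param ablations ablation kinds to sweep (subset of
#'   `none`, `background_mask`, `binarize`, `binarize_blur`).
#' @param n_trials trials per ablation.
#' @param seed master seed; all stage seeds derive from it.
#' @param hyperparams [train_hyperparams()] for head training.
#' @param backbone a `cnn_backbone`; default [tiny_backbone()].
#' @param attribution attribution methods to validate on the first trial's
#'   test images (`"gradcam"`, `"xrai"`, or both; empty to skip).
#' @param transfer_to optional [synthetic_config()] of a target population
#'   for transfer prediction (first-trial classifier, all target images).
#' @param permutation_control also run a permuted-label negative control.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(dataset, ablations = "none", n_trials = 5,
                              seed = 1, hyperparams = train_hyperparams(),
                              backbone = NULL, attribution = "gradcam",
                              transfer_to = NULL, permutation_control = FALSE,
                              out_dir = NULL) {
  stopifnot(inherits(dataset, "synthetic_config"),
            all(ablations %in% ablation_kinds()))
  structure(
    list(dataset = dataset, ablations = ablations, n_trials = n_trials,
         seed = as.integer(seed), hyperparams = hyperparams,
         backbone = backbone, attribution = attribution,
         transfer_to = transfer_to,
         permutation_control = isTRUE(permutation_control),
         out_dir = out_dir),
    class = "experiment_config"
  )
}

#' Run a full experiment
#'
#' Generates the dataset, measures areas and the between-class effect size
#' of log area, sweeps the configured ablations through the multi-trial
#' training protocol, validates attributions against ground-truth
#' silhouettes, and optionally runs the permuted-label control and transfer
#' prediction. All outputs are returned and, when `out_dir` is set, written
#' as CSV/JSON.
#'
#' @param config an [experiment_config()].
#' @return an `experiment_result` list with `areas`, `effect_size`,
#'   `trials` (per ablation), `xai` (per method), optional `permutation`
#'   and `transfer`, and a serializable `summary`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  backbone <- config$backbone %||% tiny_backbone()
  ds <- generate_dataset(config$dataset)

  areas <- dataset_areas(ds)
  g_area <- hedges_g(
    log(pmax(areas$area_px[areas$label == "male"], 1)),
    log(pmax(areas$area_px[areas$label == "female"], 1))
  )

  trials <- list(); caches <- list()
  for (kind in config$ablations) {
    dsa <- ablate_dataset(ds, kind)
    fc <- prepare_features(dsa, backbone)
    trials[[kind]] <- run_trials(
      fc, n_trials = config$n_trials,
      base_seed = derive_seed(config$seed, match(kind, ablation_kinds())),
      hyperparams = config$hyperparams, backbone = backbone
    )
    caches[[kind]] <- fc
  }

  xai <- list()
  if (length(config$attribution) && "none" %in% names(trials)) {
    fit1 <- trials[["none"]]$fits[[1]]
    for (m in config$attribution) {
      xai[[m]] <- validate_xai(fit1, ds, caches[["none"]], method = m)
    }
  }

  permutation <- NULL
  if (config$permutation_control) {
    dsp <- permutation_control(ds, seed = derive_seed(config$seed, 555))
    fcp <- prepare_features(dsp, backbone)
    permutation <- run_trials(
      fcp, n_trials = config$n_trials,
      base_seed = derive_seed(config$seed, 556),
      hyperparams = config$hyperparams
    )
  }

  transfer <- NULL
  if (!is.null(config$transfer_to)) {
    target <- generate_dataset(config$transfer_to)
    fct <- prepare_features(target, backbone)
    transfer <- transfer_predict(trials[[1]]$fits[[1]]$classifier, fct)
  }

  summary <- list(
    seed = config$seed,
    n_images = nrow(ds$manifest),
    log_area_hedges_g = g_area$g,
    accuracy = lapply(trials, function(tr)
      list(mean = tr$mean_accuracy, sd = tr$sd_accuracy,
           per_trial = tr$trials$test_accuracy)),
    permutation_accuracy = if (!is.null(permutation))
      list(mean = permutation$mean_accuracy,
           per_trial = permutation$trials$test_accuracy),
    transfer = if (!is.null(transfer))
      list(accuracy = transfer$accuracy, mcc = transfer$mcc),
    xai_median_iou = lapply(xai, function(x)
      stats::median(x$iou[x$correct]))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(areas, file.path(config$out_dir, "areas.csv"))
    for (kind in names(trials)) {
      readr::write_csv(trials[[kind]]$trials,
                       file.path(config$out_dir, paste0("trials_", kind, ".csv")))
    }
    for (m in names(xai)) {
      readr::write_csv(xai[[m]], file.path(config$out_dir, paste0("xai_", m, ".csv")))
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(areas = areas, effect_size = g_area, trials = trials, xai = xai,
         permutation = permutation, transfer = transfer, summary = summary),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  cat(sprintf("  images: %d, log-area Hedges' g = %.3f\n",
              x$summary$n_images, x$summary$log_area_hedges_g))
  for (kind in names(x$trials)) {
    cat(sprintf("  %-16s accuracy %.3f +/- %.3f\n", kind,
                x$trials[[kind]]$mean_accuracy, x$trials[[kind]]$sd_accuracy))
  }
  invisible(x)
}
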