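# Last-layer transfer classifier.
#
# The backbone stays frozen; only an affine head (pooled features -> 2
# logits) is trained, by minibatch cross-entropy with Adam. The protocol
# follows the study recipe: stratified 64:16:20 split, checkpoint at the
# maximum validation accuracy (earliest epoch on ties), five independent
# trials with re-randomized splits, and a permuted-label negative control.

#' Training hyperparameters
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @return list of hyperparameters (optimizer is always Adam).
#' @export
train_hyperparams <- function(learning_rate = 0.001, batch_size = 32, epochs = 500) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  list(optimizer = "adam", learning_rate = learning_rate,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs))
}

#' Stratified random split into train/validation/test
#'
#' @param labels character vector of class labels (one per image id).
#' @param ids image ids; defaults to names or indices of `labels`.
#' @param fractions train/val/test fractions summing to 1 (default
#'   0.64/0.16/0.20).
#' @param seed split seed.
#' @return a `split_spec`: list with `train`, `val`, `test` id vectors.
#' @export
split_dataset <- function(labels, ids = NULL, fractions = c(0.64, 0.16, 0.20),
                          seed = 1) {
  if (is.null(ids)) ids <- names(labels) %||% as.character(seq_along(labels))
  stopifnot(length(ids) == length(labels), abs(sum(fractions) - 1) < 1e-9)
  classes <- unique(labels)
  if (any(table(labels) < 5)) {
    stop("need at least 5 records per class to split 64:16:20", call. = FALSE)
  }
  parts <- list(train = character(0), val = character(0), test = character(0))
  for (cl in classes) {
    cl_ids <- ids[labels == cl]
    cl_ids <- with_private_rng(derive_seed(seed, match(cl, classes)),
                               sample(cl_ids))
    n <- length(cl_ids)
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    n_te <- n - n_tr - n_va
    parts$train <- c(parts$train, cl_ids[seq_len(n_tr)])
    parts$val <- c(parts$val, cl_ids[n_tr + seq_len(n_va)])
    parts$test <- c(parts$test, cl_ids[n_tr + n_va + seq_len(n_te)])
  }
  structure(list(train = parts$train, val = parts$val, test = parts$test,
                 fractions = fractions, seed = seed),
            class = "split_spec")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Feature conditioning fitted on the training split: per-feature
# standardization followed by PCA whitening. Composed with the affine head
# this is still a single affine map of the pooled features, so the
# "train only the last layer" contract is preserved while gradient descent
# sees a well-conditioned problem.
fit_whitener <- function(X, shrink = 0.01, eps = 1e-8) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < eps] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  eg <- eigen(stats::cov(Z), symmetric = TRUE)
  keep <- eg$values > max(eg$values, 1) * 1e-9
  V <- eg$vectors[, keep, drop = FALSE]
  # shrinkage toward the mean eigenvalue damps near-noise directions that a
  # hard whitening would otherwise amplify into overfitting
  lam <- eg$values[keep]
  s <- 1 / sqrt(lam + shrink * mean(lam) + eps)
  list(center = center, scale = scale, V = V, s = s, dim = sum(keep))
}

apply_whitener <- function(transform, X) {
  if (is.null(transform)) return(as.matrix(X))
  Z <- sweep(sweep(as.matrix(X), 2, transform$center), 2, transform$scale, `/`)
  sweep(Z %*% transform$V, 2, transform$s, `*`)
}

# gradient of the target-class logit with respect to the raw pooled
# features (head weights pulled back through the whitening transform)
pooled_gradient <- function(classifier, k) {
  w <- classifier$W[, k]
  tr <- classifier$transform
  if (is.null(tr)) return(w)
  as.numeric(tr$V %*% (tr$s * w)) / tr$scale
}

# logits of raw pooled feature rows
classifier_logits <- function(classifier, pooled) {
  X <- apply_whitener(classifier$transform, pooled)
  X %*% classifier$W + rep(classifier$b, each = nrow(X))
}

# earliest epoch attaining the maximum validation accuracy
select_best_epoch <- function(val_acc) which.max(val_acc)

#' Train the classification head on frozen-backbone features
#'
#' @param features_train,features_val numeric matrices (rows = images,
#'   columns = pooled backbone features).
#' @param labels_train,labels_val class labels aligned with the rows.
#' @param hyperparams a [train_hyperparams()] list.
#' @param seed seed for head initialization and minibatch shuffling.
#' @param classes the two class labels in logit order; defaults to sorted
#'   unique training labels.
#' @param backbone optional `cnn_backbone` to attach (for attribution).
#' @param whiten standardize and PCA-whiten the pooled features using
#'   training-split statistics before the affine head (default TRUE). The
#'   whitening transform composed with the head is still one affine map of
#'   the pooled features.
#' @param whiten_shrink eigenvalue shrinkage toward the mean eigenvalue;
#'   larger values damp near-noise directions (tamer attribution
#'   gradients) at some cost in weak-signal reach.
#' @return a `trained_classifier`: head weights at the epoch of maximum
#'   validation accuracy (ties resolved to the earliest epoch), the
#'   per-epoch training log, and the frozen backbone reference.
#' @export
train_head <- function(features_train, labels_train, features_val, labels_val,
                       hyperparams = train_hyperparams(), seed = 1,
                       classes = NULL, backbone = NULL, whiten = TRUE,
                       whiten_shrink = 0.01) {
  X <- as.matrix(features_train)
  if (nrow(X) == 0 || length(labels_train) != nrow(X)) {
    stop("empty or misaligned training split", call. = FALSE)
  }
  if (length(labels_val) == 0) stop("empty validation split", call. = FALSE)
  classes <- classes %||% sort(unique(as.character(labels_train)))
  if (length(classes) != 2) stop("binary head needs exactly two classes", call. = FALSE)
  y <- match(labels_train, classes)
  yv <- match(labels_val, classes)
  if (anyNA(y) || anyNA(yv)) stop("labels outside the two classes", call. = FALSE)
  transform <- if (isTRUE(whiten)) fit_whitener(X, shrink = whiten_shrink) else NULL
  X <- apply_whitener(transform, X)
  Xv <- apply_whitener(transform, as.matrix(features_val))
  D <- ncol(X); n <- nrow(X)
  hp <- hyperparams

  with_private_rng(seed, {
    W <- matrix(stats::rnorm(D * 2, sd = 0.01), D, 2)
    b <- c(0, 0)
    mW <- vW <- matrix(0, D, 2); mb <- vb <- c(0, 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
    onehot <- matrix(0, n, 2); onehot[cbind(seq_len(n), y)] <- 1
    best <- list(acc = -Inf, epoch = NA_integer_, W = W, b = b)
    log_tr <- log_va <- numeric(hp$epochs)

    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = hp$batch_size)) {
        idx <- ord[start:min(start + hp$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        Z <- Xb %*% W + rep(b, each = length(idx))
        P <- softmax_rows(Z)
        if (!all(is.finite(P))) stop("NaN loss during head training", call. = FALSE)
        G <- (P - onehot[idx, , drop = FALSE]) / length(idx)
        gW <- crossprod(Xb, G)
        gb <- colSums(G)
        t_step <- t_step + 1
        mW <- beta1 * mW + (1 - beta1) * gW; vW <- beta2 * vW + (1 - beta2) * gW^2
        mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        W <- W - hp$learning_rate * (mW / corr1) / (sqrt(vW / corr2) + eps)
        b <- b - hp$learning_rate * (mb / corr1) / (sqrt(vb / corr2) + eps)
      }
      pred_tr <- max.col(X %*% W + rep(b, each = n), ties.method = "first")
      pred_va <- max.col(Xv %*% W + rep(b, each = nrow(Xv)), ties.method = "first")
      log_tr[epoch] <- mean(pred_tr == y)
      log_va[epoch] <- mean(pred_va == yv)
      if (log_va[epoch] > best$acc) {
        best <- list(acc = log_va[epoch], epoch = epoch, W = W, b = b)
      }
    }

    structure(
      list(
        W = best$W, b = best$b, classes = classes, backbone = backbone,
        transform = transform,
        selected_epoch = best$epoch,
        log = tibble::tibble(epoch = seq_len(hp$epochs),
                             train_acc = log_tr, val_acc = log_va),
        hyperparams = hp, seed = seed
      ),
      class = "trained_classifier"
    )
  })
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf(
    "<trained_classifier> classes %s | selected epoch %d (val acc %.3f)\n",
    paste(x$classes, collapse = "/"), x$selected_epoch,
    x$log$val_acc[x$selected_epoch]
  ))
  invisible(x)
}

#' Predict labels and unnormalized logits
#'
#' @param classifier a `trained_classifier`.
#' @param features feature matrix (rows = images).
#' @return tibble: id (row names or index), predicted label, logits for
#'   both classes, and the predicted-class logit used as a confidence
#'   score.
#' @export
predict_classifier <- function(classifier, features) {
  X <- as.matrix(features)
  Z <- classifier_logits(classifier, X)
  k <- max.col(Z, ties.method = "first")
  tibble::tibble(
    id = rownames(X) %||% as.character(seq_len(nrow(X))),
    label = classifier$classes[k],
    logit_1 = Z[, 1], logit_2 = Z[, 2],
    logit = Z[cbind(seq_len(nrow(Z)), k)]
  )
}

#' Confusion matrix, accuracy and Matthews correlation coefficient
#'
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); a zero
#' denominator yields MCC = 0.
#'
#' @param predicted,truth label vectors (exactly two classes).
#' @param classes class order for the matrix; defaults to sorted unique
#'   truth labels.
#' @return an `eval_report`: list with `confusion` (true x predicted),
#'   `accuracy`, `mcc`, `n`.
#' @export
evaluate_predictions <- function(predicted, truth, classes = NULL) {
  classes <- classes %||% sort(unique(as.character(truth)))
  if (length(classes) != 2 ||
      !all(predicted %in% classes) || !all(truth %in% classes)) {
    stop("labels outside the two expected classes", call. = FALSE)
  }
  cm <- table(factor(truth, classes), factor(predicted, classes))
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  structure(
    list(confusion = unclass(cm), accuracy = sum(diag(cm)) / sum(cm),
         mcc = mcc, n = sum(cm), classes = classes),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.3f, MCC = %.3f\n",
              x$n, x$accuracy, x$mcc))
  print(x$confusion)
  invisible(x)
}

#' Permute the class labels of a dataset (negative control)
#'
#' The label multiset is preserved while the assignment to images is
#' uniformly permuted; applied before splitting.
#'
#' @param dataset a `gemma_dataset`.
#' @param seed permutation seed.
#' @return the dataset with permuted labels.
#' @export
permutation_control <- function(dataset, seed = 1) {
  n <- length(dataset$records)
  if (n < 2) stop("need at least 2 records", call. = FALSE)
  perm <- with_private_rng(seed, sample.int(n))
  labs <- dataset$manifest$label[perm]
  dataset$manifest$label <- labs
  for (i in seq_len(n)) dataset$records[[i]]$label <- labs[i]
  dataset
}

# --- feature pipeline ------------------------------------------------------

#' Precompute backbone features for a dataset
#'
#' Preprocesses every record in eval mode and over the full 8-element
#' dihedral orbit, then extracts pooled backbone features once. Trials can
#' then reuse the cache: training rows are the augmented variants of the
#' training ids, validation/test rows the identity variant.
#'
#' @param dataset a `gemma_dataset` (optionally ablated).
#' @param backbone a `cnn_backbone`.
#' @param options preprocessing options; `target_size` must match the
#'   backbone input size.
#' @return a `feature_cache`: list with `eval` (n x D matrix, rownames =
#'   ids), `aug` (8n x D matrix, rownames = id), `labels`, `ids`.
#' @export
prepare_features <- function(dataset, backbone,
                             options = preprocess_options(
                               target_size = backbone$input_size,
                               scale_bar_box =
                                 if (isTRUE(dataset$config$scale_bar))
                                   scale_bar_box(dataset$config$image_size)
                             )) {
  if (options$target_size != backbone$input_size) {
    stop("preprocessing target_size must match the backbone input size",
         call. = FALSE)
  }
  ids <- dataset$manifest$id
  variants <- list(); vid <- character(0)
  for (rec in dataset$records) {
    orb <- preprocess_image(rec$image, mode = "train", options = options)
    variants <- c(variants, orb)
    vid <- c(vid, rep(rec$id, length(orb)))
  }
  F_aug <- extract_features(backbone, variants)
  rownames(F_aug) <- vid
  # the identity (unrotated, unflipped) variant leads each orbit and equals
  # the eval-mode preprocessing of the record
  first_idx <- which(!duplicated(vid))
  F_eval <- F_aug[first_idx, , drop = FALSE]
  rownames(F_eval) <- vid[first_idx]
  structure(
    list(eval = F_eval, aug = F_aug, labels = stats::setNames(
      dataset$manifest$label, ids), ids = ids),
    class = "feature_cache"
  )
}

#' Multi-trial training and evaluation protocol
#'
#' Runs `n_trials` independent trials, each with its own random split (and
#' head initialization), and aggregates test accuracy and MCC.
#'
#' @param cache a [prepare_features()] cache (compute it on the ablated
#'   dataset to evaluate an ablation).
#' @param n_trials number of independent trials (>= 2).
#' @param base_seed seed from which per-trial split/init seeds are derived.
#' @param hyperparams a [train_hyperparams()] list.
#' @param backbone optional backbone to attach to the returned classifiers.
#' @param whiten,whiten_shrink forwarded to [train_head()]; attribution
#'   studies prefer the plain head or strong shrinkage for smoother
#'   gradients.
#' @return a `trial_report`: tibble of per-trial metrics, aggregate mean
#'   and SD of test accuracy, and the trained classifiers with their
#'   splits.
#' @export
run_trials <- function(cache, n_trials = 5, base_seed = 1,
                       hyperparams = train_hyperparams(), backbone = NULL,
                       whiten = TRUE, whiten_shrink = 0.01) {
  stopifnot(inherits(cache, "feature_cache"), n_trials >= 2)
  rows <- list(); fits <- list()
  for (t in seq_len(n_trials)) {
    seed_t <- derive_seed(base_seed, t)
    sp <- split_dataset(cache$labels, ids = cache$ids, seed = seed_t)
    fit <- fit_on_split(cache, sp, hyperparams, seed = derive_seed(seed_t, 7919),
                        backbone = backbone, whiten = whiten,
                        whiten_shrink = whiten_shrink)
    rep <- evaluate_split(fit, cache, sp$test)
    rows[[t]] <- tibble::tibble(
      trial = t, seed = seed_t, selected_epoch = fit$selected_epoch,
      val_acc = fit$log$val_acc[fit$selected_epoch],
      test_accuracy = rep$accuracy, test_mcc = rep$mcc, n_test = rep$n
    )
    fits[[t]] <- list(classifier = fit, split = sp, report = rep)
  }
  trials <- dplyr::bind_rows(rows)
  structure(
    list(trials = trials, mean_accuracy = mean(trials$test_accuracy),
         sd_accuracy = stats::sd(trials$test_accuracy), fits = fits),
    class = "trial_report"
  )
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> %d trials: test accuracy %.3f +/- %.3f\n",
              nrow(x$trials), x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

# train a head on the augmented training rows of a cached split
fit_on_split <- function(cache, split, hyperparams = train_hyperparams(),
                         seed = 1, backbone = NULL, whiten = TRUE,
                         whiten_shrink = 0.01) {
  tr_rows <- rownames(cache$aug) %in% split$train
  train_head(
    cache$aug[tr_rows, , drop = FALSE],
    cache$labels[rownames(cache$aug)[tr_rows]],
    cache$eval[split$val, , drop = FALSE],
    cache$labels[split$val],
    hyperparams = hyperparams, seed = seed, backbone = backbone,
    whiten = whiten, whiten_shrink = whiten_shrink
  )
}

evaluate_split <- function(classifier, cache, ids) {
  pred <- predict_classifier(classifier, cache$eval[ids, , drop = FALSE])
  evaluate_predictions(pred$label, cache$labels[ids],
                       classes = classifier$classes)
}
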