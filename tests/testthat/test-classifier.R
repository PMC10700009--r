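# Split protocol, head training, evaluation metrics, trials, permutation.

test_that("stratified split follows 64:16:20 within each class", {
  labels <- rep(c("male", "female"), each = 100)
  ids <- sprintf("i%03d", 1:200)
  sp <- split_dataset(labels, ids, seed = 4)
  for (cl in c("male", "female")) {
    cl_ids <- ids[labels == cl]
    expect_length(intersect(sp$train, cl_ids), 64)
    expect_length(intersect(sp$val, cl_ids), 16)
    expect_length(intersect(sp$test, cl_ids), 20)
  }
  # partition laws
  all_ids <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0)
  # determinism
  sp2 <- split_dataset(labels, ids, seed = 4)
  expect_identical(sp[1:3], sp2[1:3])
  expect_false(identical(sp$train, split_dataset(labels, ids, seed = 5)$train))
})

test_that("splits require enough records per class", {
  expect_error(split_dataset(c("a", "a", "a", "b", "b", "b", "b", "b")),
               "at least 5")
})

test_that("checkpoint selection takes the earliest maximum", {
  expect_equal(gemmaclass:::select_best_epoch(c(0.6, 0.9, 0.9, 0.7)), 2)
  expect_equal(gemmaclass:::select_best_epoch(c(0.5)), 1)
})

test_that("a separable problem trains to perfect accuracy", {
  set.seed(9)
  n <- 60
  # strictly separated along the first coordinate
  X <- cbind(rep(c(-2, 2), each = n / 2) + runif(n, -1, 1),
             matrix(rnorm(n * 4), n))
  y <- rep(c("male", "female"), each = n / 2)
  fit <- train_head(X, y, X, y, train_hyperparams(epochs = 150), seed = 2)
  expect_equal(max(fit$log$train_acc), 1)
  pred <- predict_classifier(fit, X)
  expect_equal(mean(pred$label == y), 1)
  # deterministic: repeated prediction identical
  expect_identical(pred, predict_classifier(fit, X))
})

test_that("a zero-weight head predicts the constant bias argmax", {
  bb <- bb16()
  cls <- manual_classifier(bb, W = matrix(0, bb$pooled_dim, 2), b = c(0.3, -0.2))
  X <- matrix(rnorm(5 * bb$pooled_dim), 5)
  pred <- predict_classifier(cls, X)
  expect_true(all(pred$logit_1 == 0.3 & pred$logit_2 == -0.2))
  expect_true(all(pred$label == "male"))
})

test_that("evaluation reproduces closed-form confusion metrics", {
  r1 <- evaluate_predictions(rep(c("a", "b"), each = 10),
                             rep(c("a", "b"), each = 10))
  expect_equal(r1$accuracy, 1); expect_equal(r1$mcc, 1)

  truth <- rep(c("a", "b"), each = 10)
  pred <- c(rep("a", 5), rep("b", 5), rep("a", 5), rep("b", 5))
  r2 <- evaluate_predictions(pred, truth)
  expect_equal(r2$accuracy, 0.5); expect_equal(r2$mcc, 0)

  # confusion (true x predicted) = [[8,2],[4,6]]
  truth3 <- c(rep("a", 10), rep("b", 10))
  pred3 <- c(rep("a", 8), rep("b", 2), rep("a", 4), rep("b", 6))
  r3 <- evaluate_predictions(pred3, truth3)
  expect_equal(r3$accuracy, 0.7)
  expect_equal(r3$mcc, 40 / sqrt(12 * 10 * 10 * 8), tolerance = 1e-12)

  # zero denominator -> 0
  r4 <- evaluate_predictions(rep("a", 20), truth3, classes = c("a", "b"))
  expect_equal(r4$mcc, 0)
  expect_error(evaluate_predictions(c("a", "c"), c("a", "b")), "two expected")
})

test_that("NaN-safe guards reject empty splits", {
  X <- matrix(rnorm(20), 10)
  expect_error(train_head(X[0, ], character(0), X, rep("a", 10)), "empty")
})

test_that("permutation control preserves the label multiset deterministically", {
  ds <- area_fixture()$ds
  p1 <- permutation_control(ds, seed = 3)
  p2 <- permutation_control(ds, seed = 3)
  expect_identical(p1$manifest$label, p2$manifest$label)
  expect_equal(sort(p1$manifest$label), sort(ds$manifest$label))
  expect_false(identical(p1$manifest$label,
                         permutation_control(ds, seed = 4)$manifest$label))
  # record labels track the manifest
  expect_identical(vapply(p1$records, `[[`, "", "label"), p1$manifest$label)
})

test_that("the trial protocol aggregates per-trial metrics", {
  fx <- area_fixture()
  tr <- run_trials(fx$cache, n_trials = 2, base_seed = 3,
                   hyperparams = train_hyperparams(epochs = 40),
                   backbone = fx$bb)
  expect_equal(nrow(tr$trials), 2)
  expect_equal(tr$mean_accuracy, mean(tr$trials$test_accuracy))
  expect_true(all(tr$trials$n_test == 16))  # 20% of 2 x 40, stratified
  # augmented variants of one source stay in one partition by construction:
  # training rows are exactly the 8 variants of each training id
  sp <- tr$fits[[1]]$split
  aug_ids <- rownames(fx$cache$aug)
  expect_equal(sum(aug_ids %in% sp$train), 8 * length(sp$train))
  # reproducible
  tr2 <- run_trials(fx$cache, n_trials = 2, base_seed = 3,
                    hyperparams = train_hyperparams(epochs = 40),
                    backbone = fx$bb)
  expect_equal(tr$trials$test_accuracy, tr2$trials$test_accuracy)
})

test_that("a planted area difference is classified well above chance", {
  fx <- area_fixture()
  tr <- run_trials(fx$cache, n_trials = 2, base_seed = 11,
                   hyperparams = train_hyperparams(epochs = 80))
  expect_gt(tr$mean_accuracy, 0.7)
})
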