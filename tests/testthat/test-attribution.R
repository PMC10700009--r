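# Grad-CAM, integrated gradients and XRAI on hand-built backbones.

# 2-channel toy backbone: 1x1 convolutions (w1, w2) on a single input
# channel, ReLU, GAP. With a linear head the whole chain is analytic.
toy_backbone <- function(w = c(1.5, -0.8), size = 4) {
  W <- array(0, c(1, 1, 1, 2))
  W[1, 1, 1, 1] <- w[1]; W[1, 1, 1, 2] <- w[2]
  cnn_backbone(list(list(type = "conv", W = W, b = c(0, 0)),
                    list(type = "relu")),
               input_size = size, in_channels = 1)
}

test_that("Grad-CAM matches the hand-derived chain rule on the toy backbone", {
  bb <- toy_backbone(w = c(1.5, -0.8))
  x <- array(matrix(c(0.2, -0.1, 0.5, 0.3,
                      0.0, 0.7, -0.4, 0.1,
                      0.6, -0.2, 0.3, 0.9,
                      0.1, 0.4, -0.6, 0.2), 4, 4), c(4, 4, 1))
  Wh <- cbind(male = c(2, 0.5), female = c(-1, 1))  # pooled(2) -> logits(2)
  cls <- manual_classifier(bb, W = Wh, b = c(0, 0))
  m <- grad_cam(cls, x, target_class = "male")

  # by hand: A1 = relu(1.5 x), A2 = relu(-0.8 x); y_male = 2 GAP(A1) + 0.5 GAP(A2)
  # alpha_k = w_k / 16; map = relu(alpha1 A1 + alpha2 A2), then min-max
  A1 <- pmax(1.5 * x[, , 1], 0); A2 <- pmax(-0.8 * x[, , 1], 0)
  raw <- pmax((2 * A1 + 0.5 * A2) / 16, 0)
  expect_equal(m$values, (raw - min(raw)) / (max(raw) - min(raw)),
               tolerance = 1e-12)
  expect_equal(m$logit, 2 * mean(A1) + 0.5 * mean(A2), tolerance = 1e-12)
})

test_that("a single-cell activation puts the Grad-CAM maximum on that cell", {
  bb <- toy_backbone(w = c(1, 1))
  x <- array(0, c(4, 4, 1)); x[2, 3, 1] <- 1
  cls <- manual_classifier(bb, W = matrix(c(1, 0, 0, 0), 2, 2))
  m <- grad_cam(cls, x, target_class = "male")
  expect_equal(which.max(m$values), which(matrix(seq_len(16), 4, 4) == (2 + (3 - 1) * 4)))
  expect_equal(m$values[2, 3], 1)
})

test_that("negating the head zeroes the rectified map where it was positive", {
  bb <- toy_backbone()
  set.seed(3)
  x <- array(rnorm(16), c(4, 4, 1))
  Wh <- matrix(c(1.2, 0.4, -0.3, 0.2), 2, 2)
  m_pos <- grad_cam(manual_classifier(bb, W = Wh), x, "male")
  m_neg <- suppressWarnings(grad_cam(manual_classifier(bb, W = -Wh), x, "male"))
  expect_true(all(m_neg$values[m_pos$values > 0] == 0))
})

test_that("integrated gradients is exact for a linear model at any step count", {
  lb <- linear_backbone(size = 8, weights = c(1, -0.5, 0.25))
  Wh <- cbind(male = c(2, 1, -1), female = c(0, 0, 0))
  cls <- manual_classifier(lb, W = Wh)
  set.seed(4)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  b0 <- array(0.2, c(8, 8, 3))
  for (steps in c(2, 7)) {
    attr <- integrated_gradients(cls, x, b0, steps = steps, target_class = "male")
    # y_male = sum_ch conv_w[ch] * head_w[ch] * mean(x_ch): gradient constant
    wpix <- c(1 * 2, -0.5 * 1, 0.25 * -1) / 64
    want <- x - b0
    for (ch in 1:3) want[, , ch] <- want[, , ch] * wpix[ch]
    expect_equal(attr, want, tolerance = 1e-12)
  }
  # zero image, zero baseline
  z <- array(0, c(8, 8, 3))
  expect_equal(integrated_gradients(cls, z, z, steps = 3, target_class = "male"),
               z, tolerance = 1e-15)
  expect_error(integrated_gradients(cls, x, b0, steps = 1), "steps")
})

test_that("integrated gradients satisfies completeness on a nonlinear backbone", {
  bb <- bb16()
  set.seed(8)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  b0 <- array(0, c(16, 16, 3))
  W <- matrix(rnorm(bb$pooled_dim * 2, sd = 0.5), ncol = 2)
  cls <- manual_classifier(bb, W = W, b = c(0.1, -0.1))
  attr <- integrated_gradients(cls, x, b0, steps = 256, target_class = "female")
  y_x <- gemmaclass:::classifier_logits(cls, matrix(backbone_forward(bb, x)$pooled, 1))[2]
  y_b <- gemmaclass:::classifier_logits(cls, matrix(backbone_forward(bb, b0)$pooled, 1))[2]
  expect_lt(abs(sum(attr) - (y_x - y_b)) / abs(y_x - y_b), 0.05)
})

test_that("attribution maps are deterministic and sized like the input", {
  fx <- area_fixture()
  fit <- run_trials(fx$cache, n_trials = 2, base_seed = 2,
                    hyperparams = train_hyperparams(epochs = 30),
                    backbone = fx$bb)$fits[[1]]
  rec <- fx$ds$records[[1]]
  img <- preprocess_image(rec$image, "eval",
                          preprocess_options(target_size = 64,
                                             scale_bar_box = scale_bar_box(64)))
  m1 <- grad_cam(fit$classifier, img)
  m2 <- grad_cam(fit$classifier, img)
  expect_identical(m1$values, m2$values)
  expect_equal(dim(m1$values), c(64, 64))
  expect_true(all(m1$values >= 0 & m1$values <= 1))
  expect_equal(max(m1$values), 1)
})

test_that("XRAI ranks a concentrated high-attribution region first", {
  lb <- linear_backbone(size = 16, weights = c(1, 1, 1))
  cls <- manual_classifier(lb, W = matrix(c(1, 1, 1, 0, 0, 0), 3, 2))
  # bright square on dark background: all attribution mass inside it
  x <- array(0, c(16, 16, 3)); x[5:9, 6:10, ] <- 1
  m <- xrai(cls, x, target_class = "male", segment_scales = c(8, 20), seed = 2)
  expect_s3_class(m, "attribution_map")
  inside <- m$values[5:9, 6:10]
  outside <- m$values[-(5:9), -(6:10)]
  expect_gt(min(inside), max(outside))
  expect_equal(max(m$values), 1)
})

test_that("degenerate segmentation and uniform attribution are handled", {
  lb <- linear_backbone(size = 8)
  cls <- manual_classifier(lb, W = matrix(0, 3, 2))
  x <- array(0.5, c(8, 8, 3))
  expect_error(xrai(cls, x, target_class = "male", segment_scales = 1),
               "degenerate segmentation")
  # zero head -> zero attribution everywhere -> constant (all-zero) map
  m <- xrai(cls, x + array(runif(192, 0, 0.01), c(8, 8, 3)),
            target_class = "male", segment_scales = c(4, 9))
  expect_true(all(m$values == 0))
})

test_that("attribution maps round-trip to disk with a sidecar", {
  dir <- withr::local_tempdir()
  m <- new_map <- structure(
    list(values = matrix(runif(64), 8, 8), method = "gradcam",
         target_class = "male", logit = 1.25, id = "img1"),
    class = "attribution_map"
  )
  write_attribution_map(m, file.path(dir, "map"))
  expect_true(file.exists(file.path(dir, "map.png")))
  side <- jsonlite::read_json(file.path(dir, "map.json"))
  expect_equal(side$logit, 1.25)
})
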