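# Shared fixtures, memoised across test files to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small backbone for gradient/attribution tests
bb16 <- function() fixture("bb16", function() {
  tiny_backbone(input_size = 16, channels = c(4, 6, 8), seed = 3)
})

# a single-conv linear backbone: pooled features are channel means of a
# 1x1 convolution, so head logits are exactly linear in the input
linear_backbone <- function(size = 8, weights = c(1, -0.5, 0.25)) {
  W <- array(0, c(1, 1, 3, 3))
  for (ch in 1:3) W[1, 1, ch, ch] <- weights[ch]
  cnn_backbone(list(list(type = "conv", W = W, b = rep(0, 3))),
               input_size = size, in_channels = 3)
}

# hand-built classifier around a backbone (no training)
manual_classifier <- function(backbone, W, b = c(0, 0),
                              classes = c("male", "female")) {
  structure(
    list(W = W, b = b, classes = classes, backbone = backbone,
         selected_epoch = 1L,
         log = tibble::tibble(epoch = 1L, train_acc = NA_real_, val_acc = NA_real_),
         hyperparams = train_hyperparams(epochs = 1), seed = 1L),
    class = "trained_classifier"
  )
}

# small rendered plant for segmentation tests
disk_scene <- function(radius = 40, size = 128, seed = 7) {
  render_plant(
    shape = list(r0 = radius, harmonics = data.frame(k = 2, a = 0, phi = 0)),
    appearance = list(color = c(0.2, 0.6, 0.25), texture_amp = 0),
    background = list(base = c(0.1, 0.11, 0.09), tint = 0, noise_sd = 0.005,
                      n_scratches = 0, scratch_contrast = 0),
    image_size = size, seed = seed
  )
}

# small labeled dataset + feature cache, shared by classifier/xai tests
area_fixture <- function() fixture("area_fixture", function() {
  ds <- generate_dataset(synthetic_config(
    40, image_size = 64, effects = channel_effects(area_effect = 3), seed = 21
  ))
  bb <- tiny_backbone(channels = c(6, 12, 24))
  list(ds = ds, bb = bb, cache = prepare_features(ds, bb))
})
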