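# Synthetic gemmaling generator: determinism, geometry, channel separation.

test_that("rendering is deterministic and a zero-harmonic contour is a disk", {
  s1 <- disk_scene(radius = 40, size = 128, seed = 9)
  s2 <- disk_scene(radius = 40, size = 128, seed = 9)
  expect_identical(s1$image, s2$image)
  expect_identical(unclass(s1$mask), unclass(s2$mask))

  area <- measure_area(s1$mask)
  expect_lt(abs(area - pi * 40^2), 2 * pi * 40)  # perimeter-sized error
  # centered
  idx <- which(unclass(s1$mask), arr.ind = TRUE)
  expect_equal(mean(idx[, 1]), 64.5, tolerance = 0.02)
  expect_equal(mean(idx[, 2]), 64.5, tolerance = 0.02)
})

test_that("background parameters never touch foreground pixels", {
  shape <- list(r0 = 30, harmonics = data.frame(k = 2, a = 0.2, phi = 1))
  app <- list(color = c(0.2, 0.6, 0.25), texture_amp = 0.05)
  bg1 <- list(base = c(0.1, 0.11, 0.09), tint = 0, noise_sd = 0.008,
              n_scratches = 2, scratch_contrast = 0.05)
  bg2 <- modifyList(bg1, list(tint = 0.03, n_scratches = 5))
  s1 <- render_plant(shape, app, bg1, 96, seed = 4)
  s2 <- render_plant(shape, app, bg2, 96, seed = 4)
  m <- unclass(s1$mask)
  expect_identical(unclass(s2$mask), m)
  for (ch in 1:3) {
    p1 <- s1$image[, , ch]; p2 <- s2$image[, , ch]
    expect_identical(p1[m], p2[m])          # foreground identical
  }
  expect_gt(sum(s1$image != s2$image), 0)   # some background differs
})

test_that("invalid contours and frame overflows are rejected", {
  shape_bad <- list(r0 = 20, harmonics = data.frame(k = 2, a = 1.2, phi = 0))
  app <- list(color = c(0.2, 0.6, 0.25), texture_amp = 0)
  bg <- list(base = c(0.1, 0.11, 0.09), tint = 0, noise_sd = 0, n_scratches = 0,
             scratch_contrast = 0)
  expect_error(render_plant(shape_bad, app, bg, 96, seed = 1),
               "self-intersection")
  shape_big <- list(r0 = 60, harmonics = data.frame(k = 2, a = 0, phi = 0))
  expect_error(render_plant(shape_big, app, bg, 96, seed = 1),
               "fit inside the frame")
})

test_that("identical configs give bit-identical datasets and balanced labels", {
  cfg <- synthetic_config(6, image_size = 64, seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(dataset_hash(d1), dataset_hash(d2))
  expect_equal(unname(table(d1$manifest$label)), c(6L, 6L), ignore_attr = TRUE)
  # mask fidelity: foreground pixels carry the foreground color model, which
  # differs from any background pixel in the green channel for these settings
  rec <- d1$records[[1]]
  expect_equal(dim(rec$image)[1:2], dim(rec$mask))
})

test_that("config validation and effect reachability errors name the channel", {
  expect_error(synthetic_config(3), "n_per_class")
  expect_error(synthetic_config(8, image_size = 32), "image_size")
  expect_error(synthetic_config(8, days = 5), "days")
  expect_error(
    generate_dataset(synthetic_config(4, effects = channel_effects(color_effect = 30))),
    "channel 'color'"
  )
})

test_that("the scale bar occupies its fixed box", {
  ds <- generate_dataset(synthetic_config(4, image_size = 64, seed = 2,
                                          scale_bar = TRUE))
  bar <- scale_bar_box(64)
  img <- ds$records[[1]]$image
  patch <- img[bar[1]:bar[2], bar[3]:bar[4], 1]
  expect_true(mean(patch >= 0.89) > 0.95)
  ds0 <- generate_dataset(synthetic_config(4, image_size = 64, seed = 2,
                                           scale_bar = FALSE))
  patch0 <- ds0$records[[1]]$image[bar[1]:bar[2], bar[3]:bar[4], 1]
  expect_lt(mean(patch0), 0.5)
})

test_that("growth model radius increases with day and rejects off-schedule days", {
  gm <- growth_model()
  r <- gm$base_radius_frac(c(0, 1, 2, 3, 4, 7))
  expect_true(all(diff(r) > 0))
  expect_error(gm$base_radius_frac(5), "day")
  expect_equal(gm$lobe_count(c(0, 7)), c(2L, 4L))
})

test_that("toggling one channel leaves the other channels' draws untouched", {
  base <- generate_dataset(synthetic_config(8, image_size = 64, seed = 31))
  col <- generate_dataset(synthetic_config(
    8, image_size = 64, seed = 31, effects = channel_effects(color_effect = 2)))
  bgd <- generate_dataset(synthetic_config(
    8, image_size = 64, seed = 31, effects = channel_effects(background_effect = 2)))

  for (i in seq_along(base$records)) {
    m0 <- unclass(base$records[[i]]$mask)
    # color effect: identical silhouettes (area/contour untouched)
    expect_identical(unclass(col$records[[i]]$mask), m0)
    # background effect: identical silhouettes and identical foreground pixels
    expect_identical(unclass(bgd$records[[i]]$mask), m0)
    for (ch in 1:3) {
      expect_identical(bgd$records[[i]]$image[, , ch][m0],
                       base$records[[i]]$image[, , ch][m0])
    }
  }
  # and the color effect does shift foreground green between classes
  green_mean <- function(ds, lab) {
    mean(vapply(ds$records[ds$manifest$label == lab],
                function(r) mean(r$image[, , 2][unclass(r$mask)]), 0))
  }
  gap_base <- green_mean(base, "female") - green_mean(base, "male")
  gap_col <- green_mean(col, "female") - green_mean(col, "male")
  expect_gt(gap_col - gap_base, 0.05)
})

test_that("all-zero effects make classes indistinguishable in area", {
  pvals <- vapply(1:40, function(s) {
    ds <- generate_dataset(synthetic_config(12, image_size = 64, seed = 100 + s),
                           render = "mask")
    a <- dataset_areas(ds)
    stats::t.test(log(area_px) ~ label, data = a)$p.value
  }, 0)
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("a planted area effect is recovered as Hedges' g of log area", {
  ds <- generate_dataset(synthetic_config(
    100, image_size = 64, seed = 77, effects = channel_effects(area_effect = 2)),
    render = "mask")
  a <- dataset_areas(ds)
  g <- hedges_g(log(a$area_px[a$label == "female"]),
                log(a$area_px[a$label == "male"]))$g
  expect_lt(abs(g - 2), 0.5)
})

test_that("datasets round-trip to disk with manifest and config", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(synthetic_config(4, image_size = 64, seed = 12))
  man <- write_dataset(ds, dir)
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(man$mask_path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$seed, 12)
  img <- png::readPNG(man$path[1])
  expect_equal(dim(img), c(64, 64, 3))
  m <- png::readPNG(man$mask_path[1]) > 0.5
  expect_equal(sum(m), measure_area(ds$records[[1]]$mask))
})
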