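# Synthetic gemmaling-like image generator.
#
# Emulates dark-background agar plates bearing one bilobed green plantlet per
# image. Class differences ("male" vs "female") can be injected independently
# into four channels: projected area, foreground color, contour fine
# structure, and background nuisance (tint + scratches). Ground-truth
# silhouette masks are returned with every image, so segmentation, ablation
# and attribution can all be validated against exact foreground knowledge.

# Fixed within-class variation model. These constants define the study
# conditions emulated by the generator; standardized effects are expressed
# relative to them.
.gen <- list(
  sigma_log_radius = 0.10,   # SD of log plant radius (log-area SD = 0.20)
  fg_base_rgb      = c(0.20, 0.55, 0.25),
  sigma_green      = 0.05,   # SD of mean foreground green intensity
  texture_amp      = 0.06,   # multiplicative smooth texture on foreground
  a2_mean          = 0.22,   # bilobed harmonic
  a2_sd            = 0.03,
  a4_mean          = 0.12,   # extra lobes after day 2
  a4_sd            = 0.02,
  a_fine_k         = 40L,    # fine-contour harmonic carrying contour effects
  a_fine_mean      = 0.02,   # high-frequency, low-amplitude serration: sharp
  a_fine_sd        = 0.008,  # edges see k*a, the severe blur leaves ~(a*r)^2
  hue_red_slope    = -0.6,   # foreground red moves against green (hue axis)
  a_noise_sd       = 0.008,  # k = 7, 8 nuisance harmonics
  bg_base_rgb      = c(0.10, 0.11, 0.09),
  sigma_tint       = 0.012,  # SD of global background tint
  bg_noise_sd      = 0.008,  # per-pixel background noise
  scratch_rate     = 3,      # Poisson mean number of scratches
  scratch_contrast = 0.10,
  scratch_log_sd   = 0.35,   # log-rate response to the background latent
  radius_frac_day0 = 0.09,   # base radius as fraction of image size at day 0
  radius_day_slope = 0.10,   # relative radius growth per day
  center_jitter    = 0.02
)

#' Channel-separable class effects
#'
#' Standardized mean differences (female minus male, in within-class SD
#' units) injected into each of the generator's four channels. All-zero
#' effects make the two classes draws from one distribution.
#'
#' @param area_effect standardized difference of log foreground area.
#' @param color_effect standardized shift of mean foreground green intensity.
#' @param contour_effect standardized difference of the fine contour-harmonic
#'   amplitude.
#' @param background_effect standardized difference of the background
#'   latent, expressed as scratch density on the culture medium (a
#'   deliberate, strictly off-plant confound).
#' @return a `channel_effects` list.
#' @export
channel_effects <- function(area_effect = 0, color_effect = 0,
                            contour_effect = 0, background_effect = 0) {
  out <- list(
    area_effect = area_effect, color_effect = color_effect,
    contour_effect = contour_effect, background_effect = background_effect
  )
  stopifnot(all(vapply(out, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)))
  structure(out, class = "channel_effects")
}

#' Day-indexed growth model
#'
#' Days follow the imaging schedule 0, 1, 2, 3, 4 and 7 after planting.
#' Expected plant radius increases strictly with day; plants gain extra
#' contour lobes after day 2 as the thallus starts to bifurcate.
#'
#' @return a list with `base_radius_frac(day)` (fraction of image size) and
#'   `lobe_count(day)`.
#' @export
growth_model <- function() {
  check_day <- function(day) {
    if (!all(day %in% c(0, 1, 2, 3, 4, 7))) {
      stop("day must be one of 0, 1, 2, 3, 4, 7", call. = FALSE)
    }
    day
  }
  list(
    days = c(0, 1, 2, 3, 4, 7),
    base_radius_frac = function(day) {
      day <- check_day(day)
      .gen$radius_frac_day0 * (1 + .gen$radius_day_slope * day)
    },
    lobe_count = function(day) {
      day <- check_day(day)
      ifelse(day >= 3, 4L, 2L)
    }
  )
}

#' Synthetic dataset configuration
#'
#' @param n_per_class images per class (>= 4).
#' @param image_size square image side in pixels (>= 64).
#' @param effects a [channel_effects()] object.
#' @param days developmental days to cycle through (subset of 0,1,2,3,4,7).
#' @param scale_bar draw a fixed-position scale bar in every image.
#' @param seed integer seed; identical config implies a bit-identical dataset.
#' @param line line/accession name recorded in the manifest.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class, image_size = 256,
                             effects = channel_effects(), days = 7,
                             scale_bar = TRUE, seed = 1, line = "synA") {
  if (n_per_class < 4) stop("n_per_class must be >= 4", call. = FALSE)
  if (image_size < 64) stop("image_size must be >= 64", call. = FALSE)
  gm <- growth_model()
  if (!all(days %in% gm$days)) stop("days must be a subset of 0,1,2,3,4,7", call. = FALSE)
  if (!inherits(effects, "channel_effects")) effects <- do.call(channel_effects, as.list(effects))
  structure(
    list(
      n_per_class = as.integer(n_per_class), image_size = as.integer(image_size),
      effects = effects, days = as.numeric(days), scale_bar = isTRUE(scale_bar),
      seed = as.integer(seed), line = as.character(line)
    ),
    class = "synthetic_config"
  )
}

#' Fixed scale-bar bounding box
#'
#' @param image_size square image side in pixels.
#' @return integer vector `(row1, row2, col1, col2)`, 1-based inclusive.
#' @export
scale_bar_box <- function(image_size) {
  c(
    row1 = round(0.92 * image_size), row2 = round(0.945 * image_size),
    col1 = round(0.70 * image_size), col2 = round(0.92 * image_size)
  )
}

# Smooth multiplicative noise field: coarse Gaussian grid upsampled bilinearly.
smooth_field <- function(size, coarse = 8L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  resize_array(g, size, bilinear = TRUE)
}

draw_scratches <- function(bg, n, contrast, size, angles = NULL) {
  if (n <= 0) return(bg)
  for (i in seq_len(n)) {
    p0 <- stats::runif(2, 1, size)
    ang <- if (is.null(angles)) stats::runif(1, 0, pi) else angles[i]
    len <- stats::runif(1, 0.6, 0.9) * size
    amp <- contrast * stats::runif(1, 0.9, 1.1)
    t <- seq(0, 1, length.out = ceiling(len * 2))
    r <- pmin(pmax(round(p0[1] + t * len * sin(ang)), 1), size)
    c <- pmin(pmax(round(p0[2] + t * len * cos(ang)), 1), size)
    idx <- rbind(cbind(r, c), cbind(pmin(r + 1L, size), c),
                 cbind(pmax(r - 1L, 1L), c), cbind(r, pmin(c + 1L, size)))  # ~3-4 px wide
    for (k in 1:3) {
      ch <- bg[, , k]
      ch[idx] <- ch[idx] + amp
      bg[, , k] <- ch
    }
  }
  bg
}

#' Render one synthetic plantlet
#'
#' Paints a star-convex plant defined by a contour-harmonic expansion
#' r(theta) = r0 (1 + sum_k a_k cos(k theta + phi_k)) onto a dark noisy
#' background, and returns both the RGB image and the exact binary mask used
#' to paint it (mask fidelity is 1 by construction).
#'
#' @param shape list with `r0` (radius, px), `harmonics` (data frame or list
#'   with `k`, `a`, `phi`), and optional `center` `(row, col)`.
#' @param appearance list with `color` (foreground RGB means) and
#'   `texture_amp`.
#' @param background list with `base` (RGB), `tint`, `noise_sd`,
#'   `n_scratches`, `scratch_contrast`.
#' @param image_size square side in pixels (>= 64).
#' @param seed integer seed for the image's private noise streams
#'   (foreground texture, background noise and scratches use independent
#'   substreams, so changing background parameters never touches foreground
#'   pixels).
#' @return list with `image` (H x W x 3 array in \[0, 1\]) and `mask`
#'   (ground-truth [silhouette_mask()]).
#' @export
render_plant <- function(shape, appearance, background, image_size, seed = 1) {
  if (image_size < 64) stop("image_size must be >= 64", call. = FALSE)
  S <- as.integer(image_size)
  ctr <- shape$center %||% c((S + 1) / 2, (S + 1) / 2)
  h <- shape$harmonics
  ks <- as.numeric(h$k); as_ <- as.numeric(h$a); phis <- as.numeric(h$phi)

  # contour validity: the radius profile must stay positive (star-convex,
  # single component) and fit inside the frame
  th_grid <- seq(0, 2 * pi, length.out = 720)
  prof <- 1 + colSums(as_ * cos(outer(ks, th_grid) + phis))
  if (min(prof) <= 0.02) {
    stop("contour self-intersection: harmonic profile reaches zero radius",
         call. = FALSE)
  }
  r_max <- shape$r0 * max(prof)
  margin <- min(ctr[1] - 1, ctr[2] - 1, S - ctr[1], S - ctr[2])
  if (r_max >= margin - 1) {
    stop(sprintf("plant radius %.1f px does not fit inside the frame", r_max),
         call. = FALSE)
  }

  rows <- matrix(seq_len(S), S, S)
  cols <- matrix(seq_len(S), S, S, byrow = TRUE)
  dy <- rows - ctr[1]; dx <- cols - ctr[2]
  theta <- atan2(dy, dx)
  rad <- shape$r0 * (1 + Reduce(`+`, Map(function(k, a, p) a * cos(k * theta + p),
                                         ks, as_, phis)))
  mask <- sqrt(dx^2 + dy^2) <= rad

  # background (substream 2) and scratches (substream 3)
  bg <- with_private_rng(derive_seed(seed, 2), {
    b <- array(0, dim = c(S, S, 3))
    for (ch in 1:3) {
      b[, , ch] <- background$base[ch] + background$tint +
        stats::rnorm(S * S, sd = background$noise_sd)
    }
    b
  })
  bg <- with_private_rng(
    derive_seed(seed, 3),
    draw_scratches(bg, background$n_scratches, background$scratch_contrast, S,
                   background$scratch_angles)
  )

  # foreground (substream 1): base color modulated by a smooth texture field
  fg <- with_private_rng(derive_seed(seed, 1), {
    field <- smooth_field(S)
    f <- array(0, dim = c(S, S, 3))
    for (ch in 1:3) {
      f[, , ch] <- appearance$color[ch] * (1 + appearance$texture_amp * field)
    }
    f
  })

  img <- bg
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- fg[, , ch][mask]
    img[, , ch] <- plane
  }
  list(
    image = clamp01(img),
    mask = silhouette_mask(mask, "ground_truth")
  )
}

# Per-class parameter shifts realizing the standardized effects. "male" is
# shifted by -delta/2 and "female" by +delta/2 on each channel's scale.
class_shift <- function(label, delta) ifelse(label == "female", delta / 2, -delta / 2)

#' Generate a labeled synthetic dataset
#'
#' Draws `2 * n_per_class` plantlet images with balanced `male`/`female`
#' labels. Each image gets its own counter-derived RNG stream, so the
#' dataset is bit-identical for identical configurations and parallel-safe.
#'
#' @param config a [synthetic_config()].
#' @param render `"full"` paints RGB images; `"mask"` skips painting and
#'   returns masks only (fast path for morphometric simulations).
#' @return a `gemma_dataset`: list of records (id, label, line, day, image,
#'   mask) plus a manifest tibble and the config.
#' @export
generate_dataset <- function(config, render = c("full", "mask")) {
  render <- match.arg(render)
  stopifnot(inherits(config, "synthetic_config"))
  eff <- config$effects
  gm <- growth_model()
  S <- config$image_size

  # reachability checks, per channel
  g_hi <- .gen$fg_base_rgb[2] + abs(eff$color_effect) * .gen$sigma_green / 2 +
    4 * .gen$sigma_green
  if (g_hi > 1) stop("unreachable effect size for channel 'color'", call. = FALSE)
  if (.gen$scratch_rate * exp(.gen$scratch_log_sd *
                              (abs(eff$background_effect) / 2 + 4)) > 300) {
    stop("unreachable effect size for channel 'background'", call. = FALSE)
  }

  labels <- rep(c("male", "female"), each = config$n_per_class)
  days <- rep(config$days, length.out = config$n_per_class)
  n <- length(labels)
  records <- vector("list", n)
  bar <- scale_bar_box(S)

  for (i in seq_len(n)) {
    lab <- labels[i]
    day <- days[((i - 1) %% config$n_per_class) + 1]
    sd_i <- derive_seed(config$seed, i)

    par <- with_private_rng(derive_seed(sd_i, 101), {
      r0_frac <- gm$base_radius_frac(day)
      log_r0 <- log(r0_frac * S) +
        stats::rnorm(1, sd = .gen$sigma_log_radius) +
        class_shift(lab, eff$area_effect * .gen$sigma_log_radius)
      lobes <- gm$lobe_count(day)
      ks <- c(lobes, .gen$a_fine_k, 7L, 8L)
      a_lobe <- stats::rnorm(1, .gen$a2_mean, .gen$a2_sd)
      a_fine <- stats::rnorm(1, .gen$a_fine_mean, .gen$a_fine_sd) +
        class_shift(lab, eff$contour_effect * .gen$a_fine_sd)
      a_hi <- stats::rnorm(2, 0, .gen$a_noise_sd)
      harmonics <- data.frame(
        k = ks, a = c(a_lobe, a_fine, a_hi),
        phi = stats::runif(4, 0, 2 * pi)
      )
      if (lobes == 4L) {
        harmonics <- rbind(
          data.frame(k = 2L, a = stats::rnorm(1, .gen$a4_mean, .gen$a4_sd),
                     phi = stats::runif(1, 0, 2 * pi)),
          harmonics
        )
      }
      # color latent moves foreground along a hue axis: green up, red down
      hue <- stats::rnorm(1, sd = .gen$sigma_green) +
        class_shift(lab, eff$color_effect * .gen$sigma_green)
      green <- .gen$fg_base_rgb[2] + hue
      red <- .gen$fg_base_rgb[1] + .gen$hue_red_slope * hue
      # the background latent drives scratch density; tint varies as
      # class-neutral nuisance. Scratches are strictly off-plant (the plant
      # is painted over them), so a planted background difference has a
      # localized, background-only signature
      z_bg <- stats::rnorm(1) + class_shift(lab, eff$background_effect)
      tint <- stats::rnorm(1, sd = .gen$sigma_tint)
      ctr <- (S + 1) / 2 + stats::runif(2, -1, 1) * .gen$center_jitter * S
      n_scr <- stats::rpois(1, .gen$scratch_rate * exp(.gen$scratch_log_sd * z_bg))
      list(
        r0 = exp(log_r0), harmonics = harmonics, center = ctr,
        green = green, red = red, tint = tint, n_scratches = n_scr
      )
    })

    max_r <- par$r0 * (1 + sum(abs(par$harmonics$a)))
    if (max_r >= 0.46 * S) {
      stop("unreachable effect size for channel 'area': plant exceeds frame",
           call. = FALSE)
    }

    id <- sprintf("%s_%s_%05d", config$line, substr(lab, 1, 1), i)
    if (render == "full") {
      out <- render_plant(
        shape = list(r0 = par$r0, harmonics = par$harmonics, center = par$center),
        appearance = list(
          color = c(par$red, par$green, .gen$fg_base_rgb[3]),
          texture_amp = .gen$texture_amp
        ),
        background = list(
          base = .gen$bg_base_rgb, tint = par$tint, noise_sd = .gen$bg_noise_sd,
          n_scratches = par$n_scratches, scratch_contrast = .gen$scratch_contrast
        ),
        image_size = S, seed = derive_seed(sd_i, 202)
      )
      img <- out$image
      if (config$scale_bar) {
        keep <- out$mask[bar[1]:bar[2], bar[3]:bar[4]]
        for (ch in 1:3) {
          patch <- img[bar[1]:bar[2], bar[3]:bar[4], ch]
          patch[!keep] <- 0.9
          img[bar[1]:bar[2], bar[3]:bar[4], ch] <- patch
        }
      }
      records[[i]] <- list(id = id, label = lab, line = config$line, day = day,
                           image = img, mask = out$mask)
    } else {
      rows <- matrix(seq_len(S), S, S)
      cols <- matrix(seq_len(S), S, S, byrow = TRUE)
      dy <- rows - par$center[1]; dx <- cols - par$center[2]
      theta <- atan2(dy, dx)
      h <- par$harmonics
      rad <- par$r0 * (1 + Reduce(`+`, Map(function(k, a, p) a * cos(k * theta + p),
                                           h$k, h$a, h$phi)))
      records[[i]] <- list(
        id = id, label = lab, line = config$line, day = day, image = NULL,
        mask = silhouette_mask(sqrt(dx^2 + dy^2) <= rad, "ground_truth")
      )
    }
  }

  manifest <- tibble::tibble(
    id = vapply(records, `[[`, "", "id"),
    label = vapply(records, `[[`, "", "label"),
    line = config$line,
    day = vapply(records, `[[`, 0, "day")
  )
  structure(list(records = records, manifest = manifest, config = config),
            class = "gemma_dataset")
}

#' @export
print.gemma_dataset <- function(x, ...) {
  cat(sprintf(
    "<gemma_dataset> %d images (%s), %d px, days %s, line %s\n",
    length(x$records), paste(table(x$manifest$label), collapse = "/"),
    x$config$image_size, paste(unique(x$manifest$day), collapse = ","),
    x$config$line
  ))
  invisible(x)
}

#' Write a dataset to disk
#'
#' Images as 8-bit RGB PNG, masks as single-channel PNG (0/255), manifest as
#' CSV (id, label, line, day, path, mask_path), config as YAML.
#'
#' @param dataset a `gemma_dataset`.
#' @param dir output directory (created if missing).
#' @return the manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0); mpaths <- character(0)
  for (rec in dataset$records) {
    p <- file.path(dir, paste0(rec$id, ".png"))
    mp <- file.path(dir, paste0(rec$id, "_mask.png"))
    png::writePNG(rec$image, p)
    png::writePNG(matrix(as.numeric(rec$mask), nrow(rec$mask)), mp)
    paths <- c(paths, p); mpaths <- c(mpaths, mp)
  }
  manifest <- dplyr::mutate(dataset$manifest, path = paths, mask_path = mpaths)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  cfg <- dataset$config
  yaml::write_yaml(
    list(n_per_class = cfg$n_per_class, image_size = cfg$image_size,
         effects = unclass(cfg$effects), days = cfg$days,
         scale_bar = cfg$scale_bar, seed = cfg$seed, line = cfg$line),
    file.path(dir, "config.yaml")
  )
  invisible(manifest)
}

#' Hash a dataset's pixel content
#'
#' SHA-256 over all image and mask pixels in record order; identical
#' configurations yield identical hashes.
#'
#' @param dataset a `gemma_dataset`.
#' @return character scalar.
#' @export
dataset_hash <- function(dataset) {
  if (!requireNamespace("digest", quietly = TRUE)) {
    stop("dataset_hash requires the 'digest' package", call. = FALSE)
  }
  payload <- lapply(dataset$records, function(r) list(r$image, as_mask_matrix(r$mask)))
  digest::digest(payload, algo = "sha256")
}
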