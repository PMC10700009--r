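# gemmaclass

Classifier-based detection and validation of cryptic morphological
differences in plant images.

Some phenotypes are visible to a trained eye but resist conventional
morphometrics. The motivating case is sexual dimorphism in young
*Marchantia polymorpha* gemmalings: male and female plants of some
accessions look subtly different during the first week of growth, yet the
thallus offers no obvious landmark to measure. `gemmaclass` implements a
complete protocol for such problems:

1. **Morphometrics** — Otsu-threshold silhouette segmentation (Gaussian
   blur → grayscale → Otsu → dilation → hole filling), projected area, and
   the unbiased standardized mean difference between classes
   (Hedges' *g* = *J*·(x̄₁−x̄₂)/*s*ₚ, *J* = 1 − 3/(4*n* − 9)).
2. **Classification** — last-layer transfer learning: a frozen
   convolutional backbone provides pooled features; only an affine head is
   trained (Adam, lr 0.001, batch 32, 500 epochs, checkpoint at maximum
   validation accuracy) on a stratified 64:16:20 split with 8-fold dihedral
   augmentation, five independent trials, and a permuted-label negative
   control. Reported metrics: confusion matrix, accuracy, and MCC.
3. **Feature ablation** — re-training on images with the background
   blacked out, binarized to a silhouette, or binarized and severely
   blurred, to attribute classification information to background, plant
   color/texture, or fine contour.
4. **Explainable-AI validation** — Grad-CAM (from its definition:
   rectified, gradient-weighted last-conv activations) and an XRAI-style
   region-ranked attribution built on integrated gradients; heatmaps are
   binarized at 0.5 and scored by IoU against the plant silhouette,
   alongside the heatmap-area fraction and logit-based representative
   selection.
5. **Transfer prediction** — applying a classifier trained on one
   population pair to another, exposing asymmetries that reveal which
   features were learned.
6. **RIL genotyping windows** — per-window polymorphism counts against a
   reference, a strict >100-per-100-kb significance rule, and derivation
   calls (TAK1 / TAK2 / SHARED) from the flag intersection pattern, with
   length-weighted genome fractions.

A synthetic gemmaling generator with **channel-separable class effects**
(area, color, contour, background — each an independent standardized
effect, with ground-truth masks) makes the entire pipeline testable at desk
scale; the vignette (`vignettes/methods.Rmd`) documents the model and every
tunable default.

## Worked example

```r
library(gemmaclass)

# a population whose sexes differ in projected area (d = 3 on log area)
ds <- generate_dataset(synthetic_config(
  100, image_size = 96,
  effects = channel_effects(area_effect = 3), seed = 101
))

# morphometrics: recover the planted effect from segmented areas
a <- dataset_areas(ds)
hedges_g(log(a$area_px[a$label == "female"]),
         log(a$area_px[a$label == "male"]))
#> Hedges' g = 2.8254 (d = 2.8362, J = 0.9962; n = 100/100)

# classification: five trials of the frozen-backbone protocol
bb <- tiny_backbone()
fc <- prepare_features(ds, bb)
tr <- run_trials(fc, n_trials = 5, base_seed = 7, backbone = bb)
tr
#> <trial_report> 5 trials: test accuracy 0.840 +/- 0.038

# ablation: the area signal survives binarization + severe blurring
fc_blur <- prepare_features(ablate_dataset(ds, "binarize_blur"), bb)
run_trials(fc_blur, n_trials = 5, base_seed = 7)
#> <trial_report> 5 trials: test accuracy 0.920 +/- 0.045

# attribution: where does the classifier look?
v <- validate_xai(tr$fits[[1]], ds, fc, method = "gradcam")
summarize_iou(v[v$correct, ], c("day", "sex", "method"))
```

The Hedges' *g* near 3 confirms the generator realized the planted effect;
accuracy well above the binomial chance band (0.345–0.655 at *n* = 40)
shows the head learned it; the ablation run shows the information survives
silhouette blurring, as an area difference must; and the IoU table
quantifies how much of the heatmap lands on the plant.

For the genomic module:

```r
lens <- c(chr1 = 2e6)
plan <- tibble::tibble(chrom = "chr1", window = 1:20,
                       call = rep(c("SHARED", "TAK2", "SHARED", "TAK1"), 5))
v <- simulate_ril_variants(plan, 1e5, lens, seed = 8)
calls <- classify_derivation(flag_significant(
  count_window_polymorphisms(v, 1e5, lens)))
summarize_derivation(calls, lens)
#> # A tibble: 3 x 3: SHARED 0.50, TAK2 0.25, TAK1 0.25
```

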