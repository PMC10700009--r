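---
title: "Detecting cryptic morphological differences with validated image classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic morphological differences with validated image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemmaclass)
```

## The problem

Young *Marchantia polymorpha* plants (gemmalings) of different sexes can look
different to a trained eye, but the differences resist conventional
morphometrics: the thallus is a continuous, variable sheet without obvious
landmarks. `gemmaclass` implements a classifier-based protocol for such
*cryptic* phenotypes: train a binary image classifier, and then — because a
high test accuracy alone proves nothing about *what* was learned — validate
the classifier with (i) human-interpretable feature ablations and (ii)
attribution maps scored against the plant silhouette. A final module applies
the same density-threshold logic used to genotype recombinant inbred lines
(RILs) from per-window polymorphism counts.

The package is organized so that every stage runs at desk scale on synthetic
images with known ground truth. Nothing requires a pretrained network or an
image download; the full pipeline, including its negative controls, is
exercised by the test suite.

## The synthetic generator and what it emulates

`generate_dataset()` draws dark-background agar plates bearing one bilobed
green plantlet each, with a ground-truth silhouette for every image. The
plant is a star-convex contour
$r(\theta) = r_0\,(1 + \sum_k a_k \cos(k\theta + \phi_k))$, $k \le 40$, with
a dominant $k = 2$ (bilobed) term; day-indexed growth (days 0, 1, 2, 3, 4, 7)
increases $r_0$ monotonically and adds lobes from day 3.

Class differences ("male" vs "female") are injected independently into four
channels, each expressed as a standardized mean difference $d$ against a
fixed within-class variation model:

| channel | carrier | within-class SD |
|---|---|---|
| area | $\log r_0$ (hence log area) | 0.10 on $\log r$ (0.20 on log area) |
| color | foreground hue latent (green up, red down) | 0.05 intensity |
| contour | amplitude of the $k=40$ boundary ripple | 0.008 |
| background | scratch density on the medium (log-rate response 0.35 per unit latent) | 1 (unit latent) |

Design notes, decided once:

* **Area on the log scale** keeps $d$ coherent across days of multiplicative
  growth.
* **Color as a hue axis** (green and red move together against each other)
  rather than a single channel offset, so one latent carries the difference.
* **Contour as a fine, high-frequency ripple** (about one pixel at classifier
  resolution). This is deliberate: a coarse shape difference would survive
  severe blurring and could not serve as the "fine contour" channel that the
  third ablation is supposed to destroy. The ripple is visible to sharp-edge
  statistics, survives binarization, and is erased by a Gaussian blur whose
  support exceeds its wavelength.
* **Background as a planted confound with a strictly off-plant
  signature**: the background latent drives the density of scratch-like
  line segments on the culture medium (the plant is painted over them),
  while a global tint varies as class-neutral nuisance. A tint-borne
  class difference turns out to be the wrong emulation twice over: it is
  spatially diffuse, and "brighter background" evidence excites the same
  brightness-tuned channels that fire most strongly on the bright plant
  body, so its heatmaps land on the plant. Scratch density reproduces the
  real failure mode attribution validation should expose — confident
  classification with heatmaps concentrated on background furniture.
* **Channel independence is exact by construction**: each image derives all
  its parameter draws from counter-split RNG streams, so toggling one
  channel's effect changes only that channel's draws. The tests verify this
  bit-for-bit.
* Scale bars are drawn at a fixed box and erased during preprocessing, as a
  stand-in for acquisition furniture.

What the generator does **not** emulate: photorealistic thallus texture,
gemma-cup/rhizoid anatomy, optics changes across days, multi-plant plates.
Passing tests on synthetic data therefore demonstrate that the *pipeline
logic* is sound — that ablations destroy exactly their channel, that
attribution finds planted confounds — not that any particular accuracy will
be attained on real micrographs.

## Segmentation and morphometrics

`segment_plant()` follows the standard recipe: Gaussian blur (bandwidth
$\sigma$ = 10 px quoted at a 1,200-px reference width and scaled
proportionally), grayscale, global Otsu threshold, binary dilation, hole
filling, and a largest-component filter. Foreground polarity is auto-detected
as the Otsu side that touches the image border least, which handles both
pale-agar and dark-background images. The dilation element is a 1-px disc at
256-px scale — a safety margin that makes the mask cover the whole plant
while keeping the disk-recovery IoU above 0.95; larger margins inflate the
silhouette measurably.

Between-class differences are summarized with `hedges_g()`, the unbiased
standardized mean difference: $g = J\,(\bar a - \bar b)/s_p$ with the pooled
two-sample SD and $J = 1 - 3/(4(n_1+n_2) - 9)$.

## Preprocessing and augmentation

`preprocess_image()` center-crops to 0.75 of the long side (the geometry of
a 1,200-px crop of a 1,200×1,600 frame), erases the scale-bar box with the
median color of a 10-px surrounding ring, resizes, scales to [0, 1] and
standardizes channels with the fixed constants (0.485, 0.456, 0.406) /
(0.229, 0.224, 0.225). Training mode additionally expands each image into
its 8-element dihedral orbit (right-angle rotations × horizontal flip);
evaluation mode applies no flip or rotation and is bit-deterministic.
Arbitrary-angle rotations are excluded: they would alter frame corners and
break mask correspondence. Masks follow the identical geometry with
nearest-neighbor resampling.

## Backbone, head, and the training protocol

No pretrained convolutional network is bundled. The backbone contract
(`cnn_backbone()`) requires only last-conv activations with gradients, a
pooled feature vector, and input gradients; the reference implementation,
`tiny_backbone()`, is a frozen, fixed-seed, He-initialized 3-block CNN whose
convolutions run through a small compiled kernel; the acceptance
experiments run it at 72-px input (the 0.75 crop of their 96-px images,
no resize) with a widened first block (24 channels), which keeps the
contour serration above the resampling limit and gives the head enough
full-resolution filters to separate boundary serration from scratch-edge
nuisance. Its pooled features
concatenate global average pooling after *each* block (multi-scale taps):
pooling only the deepest block, after two 2×2 down-samplings, erases
pixel-scale boundary statistics and makes the contour channel invisible to
any linear head.

`train_head()` trains only the affine classification head by minibatch
cross-entropy with Adam (learning rate 0.001, batch size 32, 500 epochs),
checkpointing at the maximum validation accuracy (earliest epoch on ties).
Before the head, pooled features are standardized and PCA-whitened with
statistics of the training split, with mild eigenvalue shrinkage
(`shrink = 0.01` toward the mean eigenvalue). The whitening matrix composed
with the head is still a single affine map of the pooled features — the
"train only the last layer" semantics and all attribution algebra are
unchanged — but gradient descent then converges to the well-conditioned
solution in the epoch budget; without it, discriminative directions that are
small relative to nuisance variance (the contour ripple) are unreachable,
and with *hard* whitening the near-noise directions overfit. The shrinkage
value is the package default, set with the rest of the head recipe.
Whitening is the default for the ablation-recovery protocol, where weak
channels must be reachable. The plant-channel attribution experiment
trains its head with `whiten = FALSE` — the classical recipe, which its
strong two-channel model does not need — because the whitened head's
pulled-back gradients spread over near-noise feature directions and turn
Grad-CAM maps into speckle, while the plain head's maps localize cleanly
on the plant. The background-confound attribution model keeps the
whitened head: its scratch-count evidence is unreachable for the plain
head, and its maps are validated for where they do *not* land (the
plant), which speckle and scratch-field maps agree on.

`split_dataset()` stratifies 64:16:20 by class. Augmented variants inherit
their source image's partition, so no orbit straddles the train/test
boundary. `run_trials()` re-randomizes split and head initialization per
trial and reports mean ± SD of test accuracy; `permutation_control()`
permutes labels before splitting as the negative control.

## Ablations

`apply_ablation()` implements the three ablations on raw images, before
preprocessing: background masking (background to black), binarization
(white silhouette on black), and binarization followed by severe Gaussian
blur (bandwidth 60 px at the 1,200-px reference, scaled; output left
gray-valued — re-thresholding would recreate the sharp contour the ablation
is meant to remove). The same kind is applied to training, validation and
test images, and masks come from the generator's ground truth for synthetic
data (segmentation output otherwise, recorded in provenance).

The scientific logic: information can only decrease under ablation, and each
ablation targets one interpretable channel. The acceptance tests plant a
difference in exactly one channel and verify the full collapse pattern —
background masking collapses only the background dataset to the binomial
chance band, binarization additionally collapses color, severe blur
additionally collapses contour, and an area difference survives everything.

## Attribution and its validation

`grad_cam()` is computed from the definition: channel weights are spatial
means of the target-logit gradients at the last convolutional layer
(analytic for a linear head over global average pooling), the weighted
activation sum is rectified *after* summation, bilinearly upsampled, and
min-max normalized (all-zero maps stay zero). `integrated_gradients()`
samples the straight path at step midpoints; completeness is verified to 5%
at 256 steps. `xrai()` averages integrated gradients over black and white
baselines, oversegments the image at three k-means (SLIC-style) scales, and
greedily ranks regions by mean attribution gain over uncovered pixels.

`validate_xai()` binarizes normalized maps at 0.5 and scores IoU against the
geometry-matched ground-truth silhouette on test images, alongside the
heatmap-area fraction, which distinguishes "looked elsewhere" (background
confound: IoU near 0, fraction well above 0) from "looked nowhere".
Representative images per group are chosen by the highest predicted-class
logit among correct predictions, ties to the smallest id.

## Transfer prediction

`transfer_predict()` applies a trained classifier to another population with
an explicit label map and reports the confusion matrix, accuracy and MCC
(zero-denominator MCC defined as 0). By default all target images are
evaluated, since no target training occurs; `target_split = "test"` is
available for strict comparability. The acceptance check plants a shared
color channel (full strength in pair A alongside a strong area difference;
half strength and nothing else in pair B): the B-trained classifier, forced
to use color, transfers to A above chance, while the A-trained classifier
rides the easy area difference and transfers to B at chance.

## RIL window derivation

`count_window_polymorphisms()` tallies per-line variant counts in fixed
windows that tile each chromosome: half-open `[(k-1)w, kw)` in position
coordinates, last window truncated at the chromosome end so widths sum to
the chromosome length; a variant exactly on an interior boundary belongs to
the upper window. `flag_significant()` applies the strict threshold — more
than 100 polymorphisms per 100 kb, scaled proportionally for other widths
including truncated terminal windows. `classify_derivation()` maps flag
patterns to parental origin: no significant Tak-2 density means the parents
share the region; otherwise a significant count in Rit-1 *or* Rit-2 assigns
the region to the Tak-2 parent, else to Tak-1. Sex chromosomes (U/V) are
excluded. `summarize_derivation()` reports length-weighted fractions and
fails loudly on tiling gaps. Window size is always an explicit argument
(100 kb and 1,000 kb are both in use); there is no default.

## Numerical choices and problem sizes

* Compiled same-padding convolution, exact reverse-mode gradients (verified
  against central finite differences to ~1e-8).
* Default synthetic image size 256 px; classifier experiments generate at
  96 px and feed a 64-px backbone — the geometry (crop 0.75, bandwidths
  scaled by image width) matches any resolution. Acceptance experiments use
  100 images per class and five trials, which keeps a full 4-channel ×
  4-ablation grid within minutes on one core.
* Effect sizes in the validation datasets: the area channel is planted at
  d = 3; color at d = 4; contour at d = 6; background at d = 8 (its
  carrier is a Poisson scratch count, whose sampling noise adds to the
  latent's). The background-confound model used for attribution
  localization plants d = 12 — a visibly scratch-heavy plate — because
  thin scratch furniture must cover enough of the frame for binarized
  heatmaps to have measurable area; its IoU and area-fraction summaries
  pool the test images of both trials, as the violin summaries of the
  full-scale protocol do. The strengths are chosen so the Bayes rate is
  never the binding constraint and an accuracy collapse can only come
  from the ablation.
* Chance bands are central 95% binomial intervals around 0.5 at the
  per-trial test-set size.
* Both-empty IoU is 0, not NaN; zero-denominator MCC is 0; degenerate Otsu
  input raises an error rather than guessing a polarity.

## Known limitations

The tiny backbone's random features are not a claim about what a pretrained
deep network would attend to; the attribution validation tests the *methods*
(do heatmaps land on planted evidence), not real gemmaling biology. The
XRAI implementation uses k-means oversegmentation and two baselines rather
than the full published region hierarchy. Real-image accuracies from the
original study (which depend on deposited image/sequence archives) are out
of scope and are not asserted anywhere in the suite.
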