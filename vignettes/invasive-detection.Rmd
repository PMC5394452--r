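---
title: "Detecting invasive carcinoma in whole-slide images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting invasive carcinoma in whole-slide images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wsidetect)
```

## The problem and the model

Manual delineation of invasive breast-cancer extent on a stained slide is
slow and shows substantial inter-reader variability, yet it is the input
to staging, grading and margin assessment. wsidetect implements the
standard patch-based answer: decompose the gigapixel problem into a grid
of fixed-physical-size tiles, learn a tile classifier, and reassemble the
tile scores into a slide-level probability map that can be thresholded
and scored pixel by pixel against a reference annotation.

The classifier is deliberately small. Working at a 4 µm/pixel analysis
resolution, a 200 × 200 µm tile is a 50 × 50 px patch — at that scale the
discriminative signal is texture and stain statistics (nuclear density,
hematoxylin-to-eosin balance), not subcellular morphology, and a network
of a few conv+pool stages suffices. All three candidate architectures end
in a 2-unit softmax (invasive vs non-invasive), trained with negative
log-likelihood under plain SGD.

Assumptions worth stating explicitly:

* **Physical units first.** Every stage reasons in micrometres via the
  slide's microns-per-pixel (mpp) metadata, so the same configuration
  applies to 40x Aperio scans (0.25 µm/px), Ventana scans (0.23 µm/px) or
  anything downsampled from them. Pixel sizes are derived, never assumed.
* **Tiles are homogeneous.** Each tile receives one probability; a tile
  is the atomic unit of prediction. Consequences are discussed under
  *Limitations*.
* **No tumor outside tissue.** Pixels outside any kept tile (glass, or
  tiles below the tissue threshold) get probability 0.
* **Frozen preprocessing.** YUV channel statistics are fitted once on the
  training pool and frozen; inference tiles are standardized with those
  statistics and never refit them. The statistics object carries a
  `frozen` flag and application refuses non-frozen objects, which is the
  package's train/test leakage guard.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `tile_side_um` | 200 | µm | physical tile size shared by training and prediction |
| analysis mpp | 4 | µm/px | 16:1 downsampling of a 40x scan; 200 µm ⇒ 50 px input |
| `sat_min`, `val_max` | 0.05, 0.85 | HSV | glass is near-white: low saturation and high value |
| `min_tissue_frac` | 0.5 | fraction | a tile mostly off-tissue carries little signal |
| `overlap_threshold` | 0.8 | fraction | a training tile is positive iff ≥ 80 % of it is annotated invasive; inclusive at the boundary |
| `negative_overlap_max` | 0 | fraction | training negatives come from non-invasive regions only; mixed boundary tiles are excluded from the pool |
| `epochs`, `batch_size` | 25, 32 | — | the fixed training schedule |
| `learning_rate`, decay | 1e−3, 1e−7 | — | per-update decay `lr/(1 + decay·t)` |
| `augmentation_factor` | 8 | — | the dihedral group of the square: 4 rotations × mirror |
| `max_patches_per_class` | 256 | patches | desk-scale cap on the training pool (below) |
| `threshold` | 0.5 | probability | operating point for the binary map; inclusive |

The operating threshold deserves a note: it is configurable precisely
because no single threshold is canonical, and every report this package
writes records the threshold used.

## The synthetic slide generator

`generate_slide()` emulates the two texture classes the tile classifier
must separate on an H&E slide. A smooth random field, thresholded at the
quantile matching `tissue_fraction`, carves a tissue region out of the
white background; a second, longer-range field thresholded *within
tissue* marks the invasive subregion, so the realized invasive/tissue
area ratio equals `invasive_fraction` almost exactly and the ground truth
is a subset of tissue by construction. Stroma is rendered as pink base
color with sparse light-purple elliptical nuclei; invasive regions get a
darker base tint and ≥ 3× denser, darker nuclei (hematoxylin-rich), plus
per-pixel Gaussian noise and a light separable blur. Two batch-effect
artifacts mirror common real-world failure modes: `eosin_shift` applies a
channel gain (R up, B down) on tissue, and `dark_bubble` multiplies a
soft-edged random disc down to 35 % brightness.

Default geometry is 1000 × 800 px at 4 µm/px (a 4 × 3.2 mm region, 320
candidate tiles), with `tissue_fraction = 0.55` and
`invasive_fraction = 0.3` — a mid-sized invasive component chosen once as
representative of a tumor-bearing section; the defaults are not tuned per
experiment.

What the generator does *not* emulate: glandular and ductal architecture,
in-situ lesions (DCIS/LCIS), mucinous patterns, nuclear pleomorphism,
scanner optics, or realistic stain variation beyond the two artifact
knobs. Passing tests on synthetic cohorts therefore demonstrates that the
pipeline's machinery — tiling, normalization, optimization, stitching,
scoring — is correct and reproducible, not that the classifier would
reach any particular accuracy on clinical material.

## Numerical choices

* **YUV matrix.** BT.601 luma with chroma in the exact difference form
  `U = 0.492(B−Y)`, `V = 0.877(R−Y)`; the rows sum to zero exactly, so
  achromatic pixels have zero chroma to machine precision, and the
  inverse is computed from the matrix, keeping the round trip below 1e−6.
* **Population standard deviation** (1/n) for channel fitting — pixel
  counts are in the millions — clamped below at 1e−8 so constant channels
  cannot divide by zero.
* **Conv geometry.** 5 × 5 kernels with zero padding 2 ("same") in every
  stage. With valid convolutions the six-layer variant cannot fit on a
  50 × 50 input (the fourth stage would need a 5 × 5 window on a 2 × 2
  map); same-padding keeps all three architectures valid with one rule.
  Pooling is 2 × 2, stride 2, trailing row/column dropped on odd sizes.
* **L2-norm pooling** computes `sqrt(sum of squares)` over the window; its
  gradient `y/‖y‖` is guarded at 1e−8. ReLU precedes pooling.
* **Rate decay** is per update, `lr_t = lr / (1 + decay·t)`, with `t`
  counting mini-batch updates from 0.
* **Initialization** is uniform fan-in scaled, `U(±√(6/fan_in))`, from one
  seeded generator that also drives epoch shuffling, making loss
  trajectories bit-reproducible for a given seed on one machine.
* **Single precision with flushed denormals.** The network runs in
  float32; denormalized intermediates are flushed to zero in the compiled
  code because they are numerically irrelevant at this scale and
  pathologically slow on x86.
* **Half-up rounding** for the tile side (`round(200/mpp)`), avoiding
  banker's-rounding surprises at exact halves.
* **Inclusive thresholds** everywhere a fraction meets a cutoff: overlap
  exactly 0.8 is positive, probability exactly 0.5 is positive, so
  thresholding at 0.5 coincides with the per-tile argmax.
* **Ties in AUC** are handled by midranks (ties count ½), the Mann–Whitney
  convention; a single-class slide has no defined AUC and is excluded
  from validation averages.
* **Undefined metrics stay `NA`.** A zero denominator (e.g. no positive
  ground truth) yields `NA`, excluded from cohort means and reported as
  such, never silently zeroed.

## Design choices that were genuinely open

* **Evaluation domain.** Pixel metrics are computed over *all* slide
  pixels by default, background glass counting as negative; a
  `tissue_only` flag restricts the domain to tissue. Both are reported
  honestly — the default favors comparability across slides with
  different tissue coverage, at the cost of inflating TNR/NPV on sparse
  slides.
* **Validation AUC aggregation.** AUC is computed within each validation
  slide and averaged (slides with a single tile class are skipped);
  pooling all tiles first is available behind `pooled_val_auc`. Per-slide
  averaging weights slides equally regardless of size.
* **Grid stride equals tile side.** Non-overlapping tiles make the
  stitched map well defined without an averaging rule and keep the
  evaluation unambiguous; overlapping/sliding-window prediction is a
  non-goal.
* **Training-pool cap.** After 8-fold positive augmentation the pool is
  subsampled to a balanced 256 patches per class (sources are subsampled
  before augmentation so the cap is met after it). The cap is the
  package's desk-scale operating point, chosen from the compute envelope
  of a single-CPU run before any accuracy was measured; on the synthetic
  textures the classes are separable enough that a few hundred balanced
  patches saturate tile AUC. `max_patches_per_class = Inf` removes the
  cap for larger studies.
* **Model-selection tie-break** prefers the architecture with fewest
  layers — when two networks validate equally, take the simpler one.
* **Sample (n−1) standard deviation** in cohort summaries.
* **Heatmaps at 16-bit depth**, so persisted maps re-threshold identically
  to in-memory ones at any plausible operating point.

## Problem sizes used by the test suite

The shipped experiments run at the package's desk scale: cohorts of
30 training / 10 validation / 10 test slides (plus a 5-slide
normal-control cohort) at the default 1000 × 800 px geometry, the 3-layer
network trained for the full 25 epochs on the capped 512-patch pool, and
a 20-slide shared test set for the two-model agreement analysis (trained
with the 4-layer network). These sizes are the package's chosen
demonstration scale; every piece accepts larger cohorts unchanged.

## Limitations

* Tile-level prediction quantizes region boundaries: a 50 px tile
  straddling a boundary is wholly right or wholly wrong, which bounds the
  attainable Dice on slides with high boundary-to-area ratio. Overlap-
  averaged stitching would soften this but is out of scope.
* Training examples are class-pure by design: positives are tiles with
  ≥ 80 % annotated overlap, negatives are tiles from non-invasive regions
  (zero overlap by default), and mixed boundary tiles are excluded from
  the pool. The classifier's behavior on those boundary tiles at
  prediction time is therefore an emergent property of generalization,
  not something the pipeline controls directly; labeling mixed tiles as
  negatives instead (set `negative_overlap_max = NULL` semantics via
  `label_tiles`) pushes the effective decision boundary toward the 80 %
  rule and measurably lowers pixel Dice at region borders.
* No stain normalization or stain-transfer preprocessing is included; the
  YUV standardization compensates global shifts only, which is exactly
  why the eosin-shift artifact degrades cross-cohort agreement.
* The ConvNet is a from-scratch implementation sized for 50 × 50 inputs
  on one CPU; it is not a general deep-learning framework (no GPU, no
  momentum/weight decay, fixed layer vocabulary).
* Vendor pyramid formats and annotation XML are not parsed; slides enter
  as plain rasters with a JSON mpp sidecar.
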