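---
title: "Weakly supervised grading of intestinal inflammation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised grading of intestinal inflammation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histomil)
```

## The problem

Histological activity in inflammatory bowel disease is scored on the
Nancy Histological Index (NHI, 0–4). A slide-level grade summarizes a
gigapixel image whose diagnostic evidence — cryptitis, crypt abscesses,
neutrophil infiltrates, epithelial erosion — may occupy a tiny fraction of
the tissue. Annotating those regions is expensive; slide-level labels are
routine. `histomil` therefore treats grading as multiple instance
learning (MIL): a slide is a *bag* of patch embeddings carrying one label,
and the model learns which instances matter.

The package implements the full surrounding pipeline as well, because the
classifier's behaviour depends on it: what reaches the bag (tiling, QC,
region filtering) shapes what attention can find.

## Pipeline stages and their parameters

### Tiling and quality control

Slides are handled as RGB rasters at the caller's working magnification
(the reference protocol digitizes at 40x and works at 20x; the package
does not resample — hand it the resolution you mean). Foreground is
detected on a block-averaged downscale (default factor 8) by thresholding
mean brightness (default 0.85; stained tissue is darker than scanner
background). Tiles default to 1520 px — large enough to give a tissue
segmenter context — and a tile is removed when it has less than 5% tissue
(a published rule; the boundary value 5% is kept because the rule is
"less than") or fails a QC bound. The QC metric definitions are:
brightness = mean grayscale, saturation and hue = HSV channel means,
sharpness = variance of the 4-neighbour Laplacian. The cut-off *values*
are not published; the defaults in `default_qc_thresholds()` (brightness
in [0.10, 0.97], saturation ≥ 0.02, hue unconstrained, Laplacian variance
≥ 1e-5) are package choices, exposed in config and logged in the tile
manifest, and the rejection reason is always the first failed check in
the fixed order tissue → brightness → saturation → hue → sharpness, so a
rejected tile has exactly one primary reason. Partial edge tiles are
dropped, not padded.

### Segmentation bundles

An external multitask segmenter provides per-tile label maps: nucleus
instance/type/boundary, gland instance/type (the type map separates
glandular from surface epithelium), lumen instance, tissue type. The
package defines the container (one HDF5 file per tile, fixed dataset
names, bit-exact round trip) and the adapter contract, not the network.
Maps may be individually absent — a lumen level has only an instance map,
the tissue level only a type map — and absence is explicit metadata rather
than zero-filled fabrication. The default label vocabulary covers the
classes the downstream rules name (background, normal/abnormal
epithelium, inflammatory, debris, stroma, muscle, mucous, adipose;
epithelial/lymphocyte/neutrophil/plasma/eosinophil/connective nuclei) and
is config-overridable because published segmenters do not share one class
inventory. A seeded mock segmenter keeps the pipeline runnable offline;
it derives plausible maps from pixel brightness and a spatial hash and
claims no histological validity.

### Quantitative tissue statistics

Per tile: nuclear counts per type (a nucleus is one instance id, typed by
the majority code over its pixels), the cross-tabulation of nuclei over
tissue classes (a nucleus belongs to the tissue class at its centroid
pixel; background-centroid nuclei are excluded), gland count, per-gland
circularity, surface-epithelium area, tissue areas. Per slide, sums are
normalized by total non-background tissue area. Two choices were open and
are fixed as follows:

* **Circularity** is 4πA/P², clamped to (0, 1]. The formula needs a
  perimeter for a rasterized region, and naive pixel-edge counting is
  ~27% biased for discs (taxicab geometry), which would make a perfect
  gland score 0.62. The package traces the boundary (Moore neighbourhood)
  and uses the Vossepoel–Smeulders corrected chain length (0.980/axial
  step, 1.406/diagonal, −0.091/corner) plus a π/2 half-pixel-offset term.
  Rasterized discs of radius ≥ 10 px then land within ~1% of the
  continuous value 1; axis-aligned polygons keep a few percent of corner
  bias (a 40-px square scores ≈ 0.85 against the continuous π/4 ≈ 0.785),
  which is why the square-gland test uses a 10% tolerance while disc
  tests use 5%.
* **Gland averaging** is an unweighted mean over glands (area weighting
  was equally defensible; unweighted is what "average gland circularity"
  most plainly reads as).
* **Epithelial-to-stromal nuclear ratio** = nuclei with centroid on any
  epithelium class / nuclei on stroma; a zero denominator flags the
  feature as undefined instead of propagating NaN into the feature table
  (the gradient-boost stage then imputes 0).

The gradient-boosted baseline on these features uses stratified 5-fold CV
at the patient level with a small grid (trees × depth × learning rate).
No boosting package is available in the target environment, so the
booster is implemented in-package: multinomial gradient boosting with
exhaustive-split regression trees and Friedman leaf updates. It is a
baseline harness, not the contribution; its tests assert planted-signal
recovery and chance behaviour under label shuffling, not any particular
cohort number.

### Region filtering

A tile enters the MIL stage only if it contains at least 10% reference
tissue — stroma plus normal epithelium, summed, over *all* tile pixels
including background — and at least one pixel of abnormal epithelium,
inflammatory tissue, or debris. Two readings of the 10% rule were
possible ("each class ≥ 10%" vs "the sum ≥ 10%"); the sum was chosen as
the plainer reading, and the threshold and denominator are config. The
boundary semantics follow the source wording exactly: exactly 10%
reference tissue keeps ("at least 10%"), exactly 60% background excludes
("≥ 60%"). Filtering happens at tile level *before* subdivision into
25 non-overlapping 250-px patches; the preprocessing tile size (1520) and
the subdivision size (1250) are reconciled by a deterministic center
crop, keeping the 25-patch arithmetic exact. Patch ids are pure functions
of slide id, tile origin and grid position — the key contract the
embedding store depends on.

### Embeddings and the MIL classifier

Frozen encoders are adapters: any function patch → fixed-length vector.
The mock encoder (seeded random linear map of an 8×8×3 block-mean
summary) is deterministic and pixel-sensitive, which is all the plumbing
tests need. Embeddings are stored one HDF5 container per slide, indexed
by patient id and patch base name, so a patient-level split provably
induces disjoint embedding sets (tested as the leakage guard).

The classifier is:

* encoder MLP: linear → ReLU → dropout → linear → ReLU → dropout → layer
  normalization, to 256 dimensions. The interleaving order is not
  published; this order is fixed here and covered by shape and
  determinism tests.
* gated attention: `s_k = w^T (tanh(V h_k) ⊙ σ(U h_k))`, masked softmax
  over real patches (pads get weight exactly 0), weighted sum to one bag
  vector. The functional form is the standard tanh/sigmoid gate; the
  hidden width (default 128) is a package choice.
* linear head to K ∈ {2, 3, 5} classes per the grouping scheme.

Training: Adam (published learning rate 1e-5 as the default), focal loss
with γ = 2 (γ unpublished), epoch-wise dynamic class weights
(formula unpublished; fixed as inverse frequency normalized to mean 1,
with smoothing ε = 1 so empty classes stay finite, recomputed from each
epoch's training label counts), zero-padded mini-batches with masks,
per-epoch validation, early stopping on validation macro F1 with
patience 10, best-checkpoint restoration. Backpropagation is implemented
explicitly (no deep-learning framework exists in the target R
environment) and is verified against numerical differentiation to 1e-4
relative error in the test suite; training is deterministic given the
seed under single-threaded BLAS.

Desk-scale note: the published 1e-5 learning rate is calibrated to a
cohort of ~1700 slides with thousands of patches per bag. The synthetic
recovery experiments (~200 bags of 30–60 instances) train with 3e-3,
chosen up front for that scale and used consistently across all
conditions; nothing else is tuned per test.

### Evaluation and attention maps

Accuracy, per-class F1 (0/0 ≡ 0), macro and support-weighted F1,
per-class one-vs-rest AUC with midrank tie handling (the estimator is not
stated in the source; one-vs-rest with midranks is assumed), confusion
matrices with truth on rows. A 5-class evaluation can be collapsed to any
grouping after the fact; the tests assert this equals grouping first.
Attention maps paint each kept patch's footprint with its weight on a
downscaled raster, `NA` outside kept patches; the raw raster is the
tested artifact, colormaps are presentation.

## The synthetic world

The study cohort is private, so every input kind has a deterministic
generator whose ground truth is recorded at construction:

* `gen_bundle` rasterizes tissue-class pixel runs with exact areas,
  non-overlapping disc/square/ellipse glands with central lumina and an
  optional surface-epithelium band, and non-overlapping nuclei of
  prescribed types placed with centers in prescribed tissue classes. The
  ledger (counts, areas, per-gland continuous circularities) is exact for
  counts and areas, which is what the oracle-equivalence tests assert.
* `gen_slide_image` draws eosin-tinted discs on white with controllable
  brightness, blur and noise, returning the exact foreground mask.
* `gen_bags` emulates the statistical structure weak supervision faces:
  background instances from a common Gaussian, plus a sparse minority
  (default 10%, always ≥ 1 in labelled bags) of class-specific
  mean-shifted signal instances — the Gaussian-mixture reading of the
  standard MIL assumption and of the clinical observation that sparse
  lesions drive slide grades. Class 0 is a null class with no signal.
  Separation is the mean shift in noise-sd units; 3 is the default
  "clearly separated" world. Optional *confuser* instances (fresh random
  direction per instance, magnitude 6 sd) model non-informative patches
  that region filtering would remove: they carry no class information by
  construction but dilute attention, which is exactly the mechanism the
  filtering ablation probes. The returned keep-masks play the region
  filter's role at bag level.

What a green test does and does not establish: the generators share none
of the texture, stain variation, scanner artifacts or label noise of real
slides. Passing tests establish that the algorithms are implemented as
specified (exact bookkeeping, correct gradients, mask semantics, rule
boundaries) and that the training loop can recover planted structure; they
do not establish clinical performance. Cohort-scale accuracy figures are
therefore never asserted.

## Numerical choices and degenerate inputs

* Masked softmax subtracts the per-bag max before exponentiating;
  all-masked bags are an error, not a silent NaN.
* Focal-loss probabilities are clamped to [1e-12, 1 − 1e-12]; at γ = 0
  the loss and its gradient reduce exactly to weighted cross-entropy
  (asserted to 1e-9).
* Layer normalization uses ε = 1e-5 inside the square root.
* Non-finite training loss aborts with diagnostics rather than continuing.
* Nucleus-type ties within an instance resolve to the lowest code;
  nucleus centroids are rounded to the nearest pixel and clamped to the
  tile.
* Shapes of one or two pixels get circularity 1 by convention (a disc at
  raster resolution).
* An empty class in the dynamic weights stays finite through ε; a
  stratum with fewer than 3 patients in the splitter warns and assigns in
  train/val/test priority order.

## Known limitations

* The mock segmenter and encoder are plumbing stand-ins; plugging in real
  models is the adapter contract's job.
* Pyramidal scanner formats are not read; callers supply rasters at their
  working magnification.
* The chain-length perimeter keeps a small systematic bias for
  axis-aligned polygonal regions (not for smooth blobs, the realistic
  case).
* The gradient-boost grid search selects on the same cross-validation it
  reports, which is mildly optimistic; it is a baseline, and the final
  refit is on all data.
* Bags are batched by shuffle order without length bucketing; results are
  seed-deterministic regardless, bucketing would only affect padding
  waste.
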