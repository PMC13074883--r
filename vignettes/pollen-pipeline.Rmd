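---
title: "Methods: the detection-to-classification interface for pollen recognition"
author: "melissoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the detection-to-classification interface for pollen recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melissoscan)
```

## The problem and the pipeline

Automated melissopalynology pipelines decompose pollen recognition on
light-microscopy slides into three stages: a detector proposes bounding
boxes for individual grains, a frozen feature extractor embeds each
cropped region of interest (ROI) into a fixed-length vector, and a
linear classifier assigns the taxon. The decomposition matters because
the stages fail differently: detectors miss grains or fire on debris,
while classification errors reflect the geometry of the embedding
space. This package implements everything *between and after* the
neural components — the interface that makes the stages comparable and
auditable — together with synthetic fixtures that let every stage be
tested with known ground truth and no GPU.

Two modelling assumptions run through the design:

* **Single-taxon slides.** Each training slide holds one taxon, so
  image-level dataset splitting is sufficient to prevent leakage, split
  stratification can use the slide's taxon, and class-aware NMS
  coincides with class-agnostic NMS on realistic data.
* **A largely linear embedding space.** The probe is deliberately a
  multinomial logistic regression: its accuracy is a *measurement* of
  the embeddings' linear separability, not an attempt to maximize
  classification performance. No recalibration or nonlinear head is
  applied; calibration is measured (ECE), never altered.

## Stage interface: boxes, NMS, context expansion

Boxes are continuous pixel rectangles, origin top-left. Rasterization
uses half-open integer windows `[floor(xmin), ceil(xmax)) ×
[floor(ymin), ceil(ymax))`, which makes YOLO round-trips lossless
(within `1e-6 · max(W, H)`) and crops unambiguous, with every valid box
yielding at least a 1 × 1 ROI.

Overlap is Intersection over Union, `IoU = |A∩B| / |A∪B|`, with the
union computed as `area(A) + area(B) − intersection`. Greedy NMS visits
detections by descending confidence (ties broken by input order, so the
procedure is deterministic) and discards any detection reaching the IoU
threshold against an already-kept one. The default threshold 0.65 is
the operating point for dense microscopy: low enough to remove
near-coincident duplicates, high enough not to merge genuinely adjacent
grains.

Context-aware expansion grows each detected box by `pad_ratio` of its
width and height **in total** (half per side) before cropping; the
default 0.12 keeps peripheral morphology — notably the exine
ornamentation at the grain boundary — inside the crop handed to the
feature extractor. We read "expanded by 12% of its width" as a total
growth factor of 1.12 rather than 12% per side; the `pad_ratio`
argument accepts any value, so the per-side reading (0.24 total) is one
call away. Clamping to the image happens *after* expansion, never
before, so context is maximal at image borders. The ablation harness
sweeps `{0, 0.08, 0.12, 0.16}`; we treat the published grid's "0.8"
entry as a typographical slip for 0.08, since a padding ratio of 0.8
would be far outside the regime every other entry probes.

## Embedding algebra

The extractor's raw embeddings `f_i` are processed in a fixed order,
each step exactly once, tracked by a state flag on the
`PollenEmbeddings` container:

1. **L2 normalization**: `f̂_i = f_i / ||f_i||₂`, putting every sample
   on the unit hypersphere so dot products equal cosine similarities.
2. **z-score standardization**: `x_ij = (f̂_ij − μ_j) / σ_j`, with
   `μ_j`, `σ_j` estimated on *training rows only* (no leakage into
   held-out data). The standard deviation uses the population (1/N)
   formula by default — the definition names the standard deviation
   across the training set, with no bias correction — and the sample
   variant is a flag. Zero-variance components are kept in place with
   an `ε = 1e-12` guard rather than dropped, preserving the embedding
   layout so serialized models stay aligned with any extractor.

Standardization removes the unit norm but preserves angular structure;
the enforced ordering (an error if you standardize twice or normalize
after standardizing) exists because silently reordering these steps
changes the classifier's geometry.

Cluster separability is measured by the silhouette under cosine
distance `d(i,j) = 1 − f̂_i'f̂_j`: `s(i) = (b−a)/max(a,b)` with `a` the
mean intra-class and `b` the smallest mean inter-class distance.
Singleton classes get `s = 0` (the common convention; it never arises
in the study's two-class setting but must be defined).

## The linear probe

The probe is multinomial logistic regression with softmax over class
scores `w_j'x + b_j`. Fitting minimizes the penalized cross-entropy
`Σ_i −log P(y_i|x_i) + (λ/2)||W||²` in the reference-class
parameterization (last class pinned to zero, penalty on weights only),
which makes the optimum unique and the fit convex. The solver is
L-BFGS-B with analytic gradients from zero initialization — fully
deterministic, so "same seed, same data → identical parameters" holds
trivially — polished until the gradient norm is below `1e-6`. The
default `λ = 1` (in the sum-loss convention above) is a stand-in: the
study specifies regularization only for its detector, not the probe, so
the strength is surfaced in the serialized model file rather than
hidden. Argmax ties break to the lowest class index.

## Evaluation

Matching is greedy in score order: each detection claims the unmatched
same-class ground truth in its image with the highest IoU at or above
the threshold (lowest index on ties). The F1–confidence curve rematches
from scratch at every cutoff; its grid defaults to all distinct
detection scores plus the endpoints, so any reported optimum is exactly
representable. Two operating-point selectors are provided: maximum F1,
and minimum Euclidean distance to the ideal point (1, 1) — on
well-behaved curves they practically coincide.

Average precision integrates the precision envelope of the ranked
detection list; the primary variant is COCO-style 101-point
interpolation, with the exact all-points area behind a flag (the source
framework's choice is not documented, and on instances with a few dozen
ground truths the two differ by well under 0.01). mAP averages
per-class APs unweighted; classes without ground truth are excluded
with a warning rather than contributing zeros.

The detector confusion matrix adds an explicit background category:
missed ground truths land in (true class, background), unmatched
detections in (background, predicted class), and the
(background, background) cell is undefined and left zero. Orientation
is fixed — rows true, columns predicted — and stated in the report,
since figure orientations are a recurring source of silent transposes.
Duplicates-per-ground-truth counts post-NMS detections at the operating
confidence overlapping each ground truth at the match IoU; a pre-NMS
variant is a flag, as the published metric's operational definition is
ambiguous (its printed value is constant across NMS thresholds
0.30–0.65, which a post-NMS count reproduces only qualitatively).

Calibration uses 10 equal-width bins on [0, 1] by default (the source
omits its binning); `ECE = Σ_b (n_b/N)|acc_b − conf_b|`, empty bins
contributing nothing. The probe's confidence histogram bins the maximum
softmax probability on `[1/K, 1]`, the attainable range for K classes.

One arithmetic note: the published classifier confusion matrix
(318/17/2/480) yields accuracy `798/817 = 97.7%`, consistent with the
accompanying "19 errors out of 817" but not with the 98.1% printed
beside it. The package reports the matrix arithmetic; the per-class
recalls and precisions (94.9/99.4/99.6/96.6%) all verify exactly.

## What the synthetic generators emulate — and what they do not

`generateSlide()` renders textured ellipses (radial shading plus
speckle) on a bright noisy background at the study's acquisition
geometry: 2576 × 1932 canvas, Poisson grain counts with means 49
(dandelion) and 39 (hazel) per image. Ellipse axis distributions —
Normal(130, 15) and Normal(105, 12) pixels — are loosely shaped after
the observed bounding-box size histograms, which are published only as
figures; these are configuration values, not claims. Placement uses
rejection sampling against a pairwise box-IoU cap (200 attempts, then
acceptance with a warning, mirroring real grain overlap). Annotation
boxes are tight around each grain's rendered pixels by construction.

`detectorNoiseSpec()` injects the error modes that dominate real
detectors on this task — misses, localization jitter, duplicates and
background false positives, with Beta-distributed confidences
(defaults Beta(8, 2) for true and Beta(2, 6) for false detections) —
so that evaluation code can be checked against *known* rates.
`embeddingClusterSpec()` draws `normalize(direction + N(0, σ²I))`
samples around per-class unit directions at a chosen angular
separation; `generateCalibratedPredictions()` produces confidences
Uniform(0.5, 1) with Bernoulli correctness shifted by a chosen
miscalibration.

What passing tests on these fixtures *show* is that the interface and
evaluation machinery are correct: rates in, rates out. What they do
*not* show is performance on real microscopy — no debris, wax
artifacts, damaged or overlapping grains, no correlated embedding
structure, and grain texture far simpler than real exine patterns. The
published headline numbers that depend on trained backbones (mAP 0.936,
silhouette mean 0.407, ECE 0.075, F1 0.88 at confidence 0.234) are
therefore out of reach at desk scale by design; the test battery
replaces them with oracle-equivalence and parameter-recovery checks.

## Numerical and design choices

* Seeds: every generator is a pure function of (spec, seed); nested
  streams are keyed by `(seed, image id, variant index)` through a
  polynomial string hash kept below 2³¹, so parallel and repeated runs
  are reproducible and two pipeline runs with one seed are
  byte-identical.
* Augmentation implements the subset of the published recipe that the
  pipeline's computations actually exercise — brightness/contrast ±20%,
  gamma [0.8, 1.2], multiplicative noise [0.9, 1.1] (per-pixel by
  default, per-image by flag, as the source does not say which),
  Gaussian blur/sharpen, mild downscale, flips and 90° rotations
  (counterclockwise convention; rot270 = rot90³). CLAHE, ISO noise,
  motion/defocus blur and JPEG degradation are out of scope: they shape
  training-data variety for detector training, which this package does
  not perform.
* The split supports explicit counts summing to fewer images than
  available, returning the remainder in an `unused` component — the
  published subset counts (54 + 16 + 12) cover 82 of the 101 acquired
  images, so a faithful reproduction needs exactly this.
* Degenerate inputs fail loudly: zero-area boxes in IoU, zero-norm rows
  in normalization, single-class silhouette or probe fits, empty
  calibration input, boxes wholly outside an image.

## Problem sizes

The test suite and the acceptance script run the generators at reduced
canvases (typically 640 × 480 to 1288 × 966 with proportionally scaled
grains) and compact embedding dimensions (32–64) for the end-to-end
pipeline, keeping the training-ROI count per feature dimension in the
regime the full-scale pipeline operates in; the probe separability
checks use the full D = 1024 at 500 samples per class. Oracle
comparisons use 200 random instances of up to 50 boxes; recovery checks
use 2,000 objects and 10,000 predictions. These sizes are the package's
choice of desk-scale study conditions and are stated here so they can
be scaled up verbatim.

## Limitations

The fixture embedder is class-keyed — it looks up the matched ground
truth's class and draws from that cluster — so pipeline-level
classification accuracy measures the wiring and the probe, not any
visual feature extraction. Real backends plug in through the
`DetectionSet` and embedding-matrix contracts. The package does not
train detectors or backbones, render photorealistic pollen, handle
segmentation polygons or oriented boxes, or perform soft-NMS/box
fusion.
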