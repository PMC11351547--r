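---
title: "Methods: automatic aortic valve calcification screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic aortic valve calcification screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

```{r setup}
library(echocalc)
```

## The screening problem

Aortic stenosis is preceded, often by years, by aortic valve calcification
(AVC): calcium deposits that appear in echocardiography as small, strongly
hyperechoic (near-white) structures on the valve leaflets. In the
parasternal short-axis view the valve is seen in cross-section, roughly as a
bright ring. A screening pipeline for this view has two stages:

1. **Localization** — find the valve in the frame and produce a bounding
   box.
2. **Classification** — decide from the valve region whether calcium is
   present.

echocalc implements both stages plus everything a small clinical imaging
dataset needs around them: sector extraction, annotation persistence,
augmentation, class balancing, and evaluation. Because clinical
echocardiograms cannot ship with a package, it also provides a fully seeded
synthetic scene generator, and every claim the test suite makes is measured
on those synthetic scenes.

## The synthetic scene model

`generateScene()` renders the minimal structure the pipeline actually
exploits:

* a dark background with a wedge-shaped ultrasound sector (the "cone")
  opening downward from an apex near the top edge, filled with Gaussian
  speckle (default mean 70, SD 25, clamped to 0-255);
* a bright ring (default gray level 160) standing in for the valve in
  cross-section, with an exactly known tight bounding box;
* for calcified scenes, 1-3 Gaussian-profiled blobs with peak intensity
  exactly 255 placed on the ring — the blob center snaps to a pixel center
  so the stated peak is attained, which makes threshold behavior exactly
  controllable.

What the generator emulates is the *geometry and contrast ordering* of the
real problem: background < speckle < valve < calcium, a sector-shaped field
of view, and variation in valve position and size (`generateDataset()`
jitters the center by ±10 % of the image size and the ring radius by
±20 %). What it deliberately does **not** emulate: real speckle statistics
(Rayleigh-like, correlated), anatomy (leaflets, neighboring structures),
shadowing, probe-dependent post-processing, or ambiguous intermediate
echogenicity. Consequences are discussed under *Limitations*.

```{r scene}
p <- SceneParams(imageSize = 256, seed = 4)
sc <- generateScene(p)
sc$truth$valveBox
```

All randomness is seeded: the same `SceneParams` produce a bit-identical
image, which is what makes the acceptance suite reproducible.

## Preprocessing

`detectCone()` recovers the sector with a parametric fit: the left and right
foreground boundaries are fitted as straight lines over the upper straight
part of the sector, their intersection gives the apex, and the far-arc
radius comes from the 99.9 % quantile of foreground distances. The fitted
sector is rasterized; if it disagrees with the observed foreground
(IoU < 0.8) the convex hull of the foreground is used instead and flagged as
a fallback. On noiseless synthetic scenes the fitted mask agrees with the
analytic sector to IoU > 0.95 (this is an acceptance criterion).

`standardizeCrop()` produces the fixed 640 × 640 analysis frame by
windowing, *not* resampling: pixels are kept 1:1 and the window is padded
with zeros, so no aspect-ratio deformation is introduced and box coordinates
map by a pure offset. `reduceNoise()` subtracts the global scalar minimum of
the image, which sends the darkest zones to exactly 0 and is idempotent.

## Annotations and augmentation

Valve annotations are axis-aligned boxes in 0-based, half-open pixel
coordinates, persisted as plain CSV (`image_id, x_min, y_min, x_max, y_max`)
with exact round-trip. Four box-aware augmentation operators expand a
dataset, each applied with a fixed parameter pair so each selected technique
contributes exactly two variants per record:

| technique   | parameters      | box rule                                   |
|-------------|-----------------|--------------------------------------------|
| translation | +0.2 / −0.2     | integer shift `round(f·W)`, `round(f·H)`, clipped |
| zoom        | 0.5 / 2         | corners scaled about the image center, AABB, clipped |
| rotation    | +10° / −10°     | axis-aligned box of the four rotated corners, clipped |
| gamma       | 0.5 / 1.2       | unchanged (`round(255·(v/255)^γ)` pointwise) |

so `n` records become `n · (1 + 2·k)` with `k` techniques — 61 images give
183 with one technique, 305 with two, 549 with all four. Class balancing
duplicates minority records cyclically (61 images with a 22/39 split become
78; balancing then rotation-augmenting gives 234). Variants and duplicates
carry their original's `group`, and `splitManifest()` is group-aware by
default, so no augmented copy of a test image can leak into training.

A subtlety worth stating: for rotation, the *annotation rectangle's* own
axis-aligned bounding box after rotation is what the operators produce (the
AABB of the four rotated corners). This necessarily grows the box relative
to the tight box of the rotated *content* — the cost of staying in an
axis-aligned annotation format. The test suite verifies the implemented rule
against an independent brute-force rectangle-mask oracle to within ±2 px
over 100 random cases.

## Models

The deployment-scale system this package mirrors uses large pretrained
convolutional networks (a one-stage object detector, and ImageNet-pretrained
classification backbones). This package has a hard constraint of zero
trained-weight dependencies: everything must train from scratch, seeded, on
one CPU in seconds. The models are therefore small and classical, but they
keep the *interfaces and the experimental protocol* of their large
counterparts (configuration objects record input size 640/224, batch size
32/1, epochs 75/50 and the 80-10-10 / 80-20 splits; the classifier head is a
120-unit dense layer).

**Detector.** A multi-scale sliding-window scorer. The frame is downscaled
so its longest side is 160 px; square windows at three scales (0.8×, 1×,
1.25× the median annotated box side) slide with stride `s/6`; each window is
summarized as a 12 × 12 bilinearly sampled, per-window z-normalized patch
and scored by a 16-unit ReLU network with a sigmoid output, trained by
seeded full-batch gradient descent. Training labels windows with IoU ≥ 0.65
against the annotation as positive and windows with IoU ≤ 0.25 as negative
(half of them "hard": windows brushing the valve); the band in between is
ignored, so the score peaks on well-centered windows instead of plateauing
over marginal ones. At inference, candidates above the confidence threshold
go through greedy NMS (overlap 0.45) and the survivors through a local
position/scale refinement. All ranking uses the pre-sigmoid logit: the
sigmoid saturates at 1.0 in double precision for every strong candidate and
would make ranking, and thus refinement, meaningless.

**Classifier.** A descriptor-bank model: the valve region is cropped at its
box, noise-reduced, resized to 224 × 224, and summarized on a G × G grid
(G = 4, 8 or 16) with five channels per cell — mean, max and SD of
intensity, and the fraction of pixels above 0.75 and above 0.9 of full
scale; the `grad-*` backbone family adds mean absolute horizontal and
vertical gradients. The `pooling` option controls what the 120-unit dense
head sees: `"none"` flattens the full G × G × C map, `"max"`/`"avg"` pool
each channel over the grid. The two bright-fraction channels are the
physically meaningful ones: calcium is, by construction of the problem,
the only near-white structure in the region.

The pooling choice matters more than the grid size. With `pooling = "none"`
the head's weights are tied to grid positions, and with only a few hundred
training regions a calcium blob at a grid position never seen in training is
missed; max/avg pooling are translation-invariant by construction and
generalize reliably at this data scale. The package default keeps the
flattened map (the configuration with the most capacity), but the
acceptance-scale runs use the smallest backbone (`pool-4`) with average
pooling, and we recommend pooled configurations whenever training data is
scarce.

**Heuristic.** Independent of all training, `heuristicClassify()` binarizes
the region at a strict threshold (white iff *all* channels exceed it; the
screening range of interest is 190-220) and declares calcium iff any white
pixel remains. On scenes where calcium peaks at 255 and everything else
stays at or below 200, threshold 220 separates the classes exactly; this
end-to-end path has no trained-weight dependency at all.

## Evaluation

Detection metrics use greedy one-to-one matching per image: predictions are
visited in decreasing confidence (stable on ties) and claim the unmatched
truth box of highest IoU; a claim counts as a true positive iff IoU ≥ 0.5.
True negatives are undefined for detection, and any metric with a zero
denominator is reported as `NA` and flagged, never silently as 0. F1 is
computed from unrounded precision and recall. `splitManifest()` gives all
non-first splits `floor(f·n)` units with the remainder to training (61
images at 80-10-10 give 49/6/6), and `kfold()` balances folds to within one
unit.

## Numerical and design choices

* **Coordinates.** 0-based, half-open boxes; pixel `(x, y)` is matrix entry
  `[y+1, x+1]`; pixel centers at half-integers; zoom and rotation use image
  center `(W/2, H/2)`. Half-open semantics make width exactly
  `xmax − xmin` and keep IoU free of ±1 ambiguities.
* **Determinism.** Both trainable models fit by full-batch gradient descent
  with momentum 0.9 and L2 10⁻⁴, seeded initialization, and feature
  standardization stored in the model — identical data, configuration and
  seed give bit-identical weights on one machine.
* **Problem sizes.** Training-scale experiments in the tests and the
  acceptance script run on 320 px scenes with 61-image datasets and reduced
  epochs. These sizes are this package's own choice: large enough that the
  dataset-assembly arithmetic (61 → 183 → 234 …) is exercised at its real
  shape, small enough that the whole suite trains from scratch on one CPU
  in minutes.
* **Balance, then augment.** Balancing first and augmenting afterwards
  (61 → 78 → 234) multiplies minority duplicates by the same augmentation
  factor as everything else, preserving exact class balance in the final
  set.

## Limitations

* Synthetic scenes are far easier than clinical frames: contrast ordering
  is exact, speckle is Gaussian and uncorrelated, and no confounding bright
  anatomy exists. Metrics obtained here bound nothing about clinical
  performance; they verify the pipeline's mechanics, not its medicine.
* The sliding-window detector scores windows independently and does not
  regress box coordinates, so localization is quantized by the stride and
  refinement grid; it assumes exactly one valve per frame.
* The descriptor-bank classifier stands in for a pretrained deep feature
  extractor; on real images its hand-chosen statistics would be far weaker
  than learned features.
* The heuristic depends on absolute gray levels and would require
  calibration on any data whose white point differs.
* The DICOM reader covers only explicit-VR little-endian files with
  uncompressed 8-bit pixel data — the common export format for cine loops —
  and drops the entire patient group rather than anonymizing selectively.
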