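---
title: "VesselVote: methods and design choices"
author: "VesselVote authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VesselVote: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

VesselVote implements a patch-wise detection pipeline for two common
cerebrovascular pathologies on time-of-flight MR angiography (TOF-MRA)-like
volumes: intracranial atherosclerotic stenosis (ICAS; a focal narrowing of
the arterial flow diameter of at least 50%) and saccular aneurysms
(outpouchings of at least 2 mm). The pipeline combines classical computer
vision — fuzzy c-means vessel segmentation — with a 3-D residual patch
classifier and a spatial voting rule, and evaluates itself at the
participant level with prevalence-aware diagnostic metrics. Because
population TOF-MRA cohorts are application-only data, the package ships a
synthetic vascular phantom generator so that every stage is testable
end to end without clinical images.

This vignette records the model, its assumptions, the tunable parameters,
and the design decisions taken where the method description left choices
open.

## The region of interest and coordinate conventions

All volumes live on a fixed cropped region of interest (ROI): a
102 × 73 × 78 mm box centred at (0, 3, −33) mm in an MNI-like space —
large enough to cover the circle of Willis, the internal carotid, basilar
and vertebral arteries, and the proximal anterior/middle/posterior cerebral
arteries — sampled at 0.5 mm isotropic resolution as a 204 × 146 × 156
voxel grid (`roiBox()`, `roiDim()`). Skull-stripping and affine
registration to this space are upstream of the package: inputs are assumed
already aligned. Voxel `i` along an axis has its centre at
`origin + (i − 1) · 0.5` mm, with the origin at the ROI corner voxel.

## Synthetic phantoms

`generateVesselTree()` builds an idealised circle of Willis: a closed
elliptical ring (semi-axes ~12–15 × 9–11 mm, mild out-of-plane modulation)
split into arcs at `2 × complexity` attachment points, from each of which a
curved branch radiates outward. Attachment points are therefore shared by
exactly three segment endpoints (two arcs and one branch) and are recorded
as bifurcations. Ring radii are 1.8–2.5 mm and branch radii 1.4–2.2 mm,
all within the 1–3 mm range of the arteries the ROI covers. Geometry is
fully determined by the seed.

`rasterizePhantom()` draws the tree onto the ROI grid with a two-level
intensity model: tissue at 0.25 and flowing blood at 1.0 (a 4:1 flow/tissue
contrast; the method's source reports no intensity statistics for its
scanner data, so the contrast is a package choice, not a calibration).
Lesions modify the tube model in the way each pathology manifests on
TOF-MRA:

* a **stenosis** of severity *s* scales the local radius by (1 − *s*) over
  its `extent_mm`, narrowing both the bright lumen and the ground-truth
  mask;
* an **occlusion** (severity 1) leaves the geometry untouched but resets
  the signal to tissue level over its extent — TOF contrast comes from
  flow, so a blocked artery appears as a signal void, not a thin vessel;
* an **aneurysm** adds a bright sphere of diameter `size_mm` tangent to
  the vessel wall.

Additive Gaussian noise (default sd 0.1, i.e. a tenth of the vessel
signal) completes the volume. Rician noise, partial-volume effects, skull
or tissue texture, and flow artefacts are deliberately out of scope — so a
passing phantom suite demonstrates that the pipeline's machinery is
correct and self-consistent, not that it meets any particular accuracy on
clinical TOF-MRA.

`makeCohort()` simulates participants: `round(n × prevalence)` of them
(round-half-up) carry at least one lesion — one or, with probability
0.405, two on different segments, matching the ~1.4 lesions per affected
participant of the population cohorts this pipeline emulates. Default
stenosis severities are drawn from U[0.5, 0.7) — the moderate range that
dominates the population data the method targets
(moderate : severe ≈ 5 : 1) — and are
placed on segments of at least 1.6 mm radius, because at 0.5 mm voxels a
more severe narrowing of a thin branch rasterises into a disconnected
mask, which is the occlusion-like appearance the patch-wise approach is
documented not to handle. Alongside each cohort the generator writes the
lesion truth table and a per-participant table of *hard-negative sites*:
bifurcations, one interior centreline point per segment, and every branch
tip. These are the lesion-free locations that most resemble lesions;
oversampling them during training follows the method's own false-positive
mining strategy.

## Vessel segmentation

`ffcmSegment()` minimises the standard fuzzy c-means objective over the
intensity histogram rather than over voxels, weighting each bin by its
count. When a volume has no more distinct intensities than histogram bins,
the distinct values themselves serve as bins, making the histogram result
*exactly* equal to voxel-wise FCM (the test suite exploits this for its
oracle equivalence checks); otherwise 256 equal-width bins are used, and
memberships are broadcast back to voxels through the bin index.

Defaults: 3 clusters (background / tissue / vessel appearance of
skull-stripped angiography), fuzziness 2, tolerance 1e-5 on the largest
centroid change, 100 iterations maximum. The vessel class is the
highest-centroid cluster. Centroids are initialised at evenly spaced
positions across the intensity *range*: quantile-based initialisation
collapses onto the tissue mode when vessels occupy ~1% of the volume,
which prevents the vessel cluster from forming, whereas the range-based
rule is deterministic and robust. Constant-intensity volumes and runs in
which centroids collide raise errors rather than returning a degenerate
clustering; a noise-free two-valued phantom is exactly such a degenerate
input for three clusters, so binary phantoms are segmented with
`n_clusters = 2`.

`removeSmallClusters()` deletes connected components of 3500 voxels or
fewer (inclusive threshold) under 26-connectivity. The volume-based
figure sometimes quoted for this step is inconsistent with 0.5 mm voxels;
the voxel count is the internally consistent reading and is authoritative
here. Segmentation is applied in the stenosis pipeline and skipped in the
aneurysm pipeline, where fuzzy clustering delineates saccular dilations
poorly; `use_segmentation` exposes the toggle.

## Patch sampling and augmentation

Patches are 32 × 32 × 32 voxels (16 mm cubes). The patch centre voxel is
the voxel containing the requested world coordinate; out-of-volume regions
are zero-filled (zero being the background of skull-stripped TOF).
Augmentation enumerates the eight axis-flip orientations of `1 +
n_offsets` re-centred copies, with integer-voxel offsets drawn uniformly
up to 4 mm per axis, applied before flipping so no interpolation occurs.

`buildTrainingSet()` assembles, per participant-level split:

* positives — lesion-centred patches, augmented in the training split;
* negatives — drawn only from lesion-free participants, at (i) every
  lesion coordinate observed in the cohort (matched negatives) and
  (ii) the participant's own hard-negative sites.

The training split holds `ratio` negatives per (augmented) positive — 5:1
for stenosis, 4:1 for aneurysms — and validation/test are exactly 1:1.
Phantom cohorts are far smaller than the hundreds of healthy participants
available to the original study, so when the finite pool of
(participant × site) pairs cannot reach the ratio, sites are recycled
through flip/offset augmentation before a genuine shortfall raises an
error. Splits are 80/5/15 by participant with largest-remainder rounding;
the pipeline applies the split separately to lesioned and healthy
participants so that every bucket contains both classes even in small
cohorts. No participant contributes to more than one split, which the
test suite checks as a leakage invariant.

Patch intensities are standardised per volume (zero mean, unit variance)
after optional vessel masking, identically at training and inference time.

## The 3-D residual classifier

`buildModel()` assembles a bottleneck residual network with 3-D kernels.
Two presets exist:

* `resnet50-3d` — the canonical 50-layer topology (7³ stride-2 stem,
  3×3 max pooling, stages of 3/4/6/3 bottleneck blocks on 64 base
  channels, expansion 4). It is provided for completeness and for GPU-scale
  users; it is not exercised by the phantom experiments beyond
  construction.
* `small-3d` — the same bottleneck grammar at desk scale: an unpadded 3³
  stride-2 stem, 2³ max pooling, one stride-2 bottleneck stage on 12 base
  channels and one stride-1 stage on 24, global average pooling and a
  single-logit head (~30k parameters). The unpadded stem is a deliberate
  choice: valid convolutions commute with cropping, which lets
  sliding-window inference share the stem across overlapping windows (see
  below) and keeps full 0.5 mm detail in the first layer, where the
  caliber difference between a stenosed lumen and a thin but normal branch
  lives.

Training (`trainClassifier()`) minimises binary cross-entropy on a sigmoid
output with Adam at an initial learning rate of 5e-4 for up to 50 epochs,
with early stopping on validation loss (patience 10) and best-snapshot
restoration — the reference recipe. Batch size 32 and He initialisation
are package choices. A `pos_weight` option multiplies positive-class loss
terms; the phantom pipeline sets it to the class ratio so that the 5:1
negative-heavy sampling does not bias the probability scale downward. All
randomness (initialisation, shuffling) derives from explicit seeds, and
gradient correctness of every layer is verified against finite differences
in the test suite.

The phantom-scale pipeline trains for 10 epochs at learning rate 3e-3 with
three offset draws per lesion — sizes chosen so a full experiment
(simulate, segment, sample, train, detect, evaluate) completes in minutes
on one CPU core. The learning rate and capacity sit deliberately above
the reference recipe's: with the epoch budget an order of magnitude
smaller than the original 50, the probability scale has to saturate
quickly for the extreme voting threshold to be reachable.

## Sliding-window voting

`slideInfer()` scores a 32³ window at every stride-4 position of the ROI
(origin-anchored, no padding: `floor((D − 32)/stride) + 1` positions per
axis, 44 × 29 × 32 = 40 832 for the full ROI). When a vessel mask is
supplied, windows containing no vessel voxel are skipped and scored 0.
For networks with an unpadded stem the implementation evaluates
stem + pooling once over the whole ROI and runs the residual stages on
feature-map crops; this is bitwise-identical to scoring windows
independently (valid convolution and aligned pooling commute with
cropping) and is roughly an order of magnitude faster than naive
per-window evaluation.

`thresholdLattice()` binarises at τ = 0.99954 (threshold inclusive), and
`extractFindings()` keeps connected components of at least 25 adjacent
positive positions — 26-adjacency by default, since the rule's source
describes only "adjacent" in a 2-D illustration. Component labelling is
cross-checked against an independent flood-fill implementation on random
lattices. A participant is positive iff at least one finding survives
(`participantDecision()`). Probabilities are counted on the stride-4
lattice; they are not upsampled to voxel space.

## Evaluation

`confusionCounts()` and `diagnosticMetrics()` produce the standard 2×2
fractions; any metric with a zero denominator is reported as `NA` and
flagged in `undefined`, never silently 0, so degenerate phantom cohorts
cannot pass unnoticed. `stratifiedSensitivity()` works per lesion (not per
participant), e.g. by artery or severity grade. `prevalenceAdjusted()`
rescales predictive values to a population prevalence by Bayes' rule:

$$\mathrm{PPV}_p = \frac{s\,p}{s\,p + (1-c)(1-p)}, \qquad
  \mathrm{NPV}_p = \frac{c\,(1-p)}{(1-s)\,p + c\,(1-p)}$$

for sensitivity $s$, specificity $c$ and prevalence $p$. For phantom runs,
findings are matched to true lesions greedily (nearest first, one-to-one)
within 8 mm — half a patch edge — a tolerance the package needs because it
scores lesions spatially, whereas the original evaluation was purely
participant-level.

## Numerical and degenerate-input conventions

* FCM convergence is on the maximum centroid change; memberships sum to 1
  per voxel to 1e-9; zero distances are clamped at 1e-300 before the
  inverse-distance update.
* Cluster-size pruning is inclusive (`size ≤ min_voxels` removed) and
  idempotent.
* Thresholding uses ≥ τ; raising τ or the support can only shrink the
  finding set (tested monotonicity invariants).
* Augmentation uses integer-voxel offsets only; no interpolation anywhere.
* Ties in membership argmax resolve to the lower class index;
  `max.col(ties.method = "first")`.
* Constant volumes, single-class training sets, empty splits, mismatched
  participant sets and off-tree lesion centres all raise informative
  errors.

## Problem sizes

The phantom experiment runs 60 training participants (prevalence 0.5,
noise 0.1) and a held-out balanced cohort of 20; training uses ~4600
patches for 10 epochs; detection scores ~10 000 vessel-touching windows
per volume at stride 4. These sizes make the full pipeline reproducible
in minutes on a single CPU core while leaving every stage's behaviour
observable. Unit tests run on much smaller crops (8³–48³).

## Known limitations

* The phantom's two-level intensity model and tube geometry are far
  simpler than clinical TOF-MRA; pipeline performance on phantoms does
  not transfer to clinical accuracy claims.
* Occlusions are represented as signal voids; the patch-wise classifier
  has no mechanism for such long-range evidence, mirroring the method's
  documented weakness, and the default phantom mix therefore emphasises
  moderate stenosis.
* The small-3d preset trades capacity for CPU practicality; the
  resnet50-3d preset is constructed and tested for shape/determinism but
  not trained in the standard experiments.
* Lesion-to-finding matching (8 mm, greedy one-to-one) is a package
  convention; other radii change lesion-level sensitivity but not
  participant-level metrics.
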