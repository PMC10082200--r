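---
title: "Organ localization by projection classification: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ localization by projection classification: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Contouring a kidney or spleen in an abdominal CT study means finding, in a
stack of 40–100 axial slices of 512×512 pixels, first the small axis-aligned
cube (region of interest, ROI) that contains the organ, and then the organ
boundary inside that cube. `ctroi` implements a localization strategy that
avoids semantic segmentation networks entirely:

1. **Per-axis slice classification.** A 3D point belongs to the organ's ROI
   exactly when the three orthogonal projection images through it — the
   sagittal plane at its *x*, the coronal plane at its *y*, the axial slice
   at its *z* — all look like "organ present" to three small CNN binary
   classifiers (one per axis). Because each projection depends on a single
   coordinate, classifying one line classifies a whole plane of points at
   once; a negative decision excludes all of them. Scanning each axis
   independently and intersecting the three flag vectors is therefore an
   exact refactoring of the naive per-point scan with exclusion — the
   package tests this equivalence against brute force.
2. **In-plane consolidation.** Positive scan points (pitch 10 px) are
   merged by drawing axis-aligned segments between grid neighbors, only the
   largest 8-connected component is kept (stray false positives vanish
   here), and the mask is dilated by a centered 30×30 square so the cube
   safely covers the organ boundary between scan lines. The z extent is
   the longest contiguous run of positive axial slices after bridging
   interior gaps of up to 3 slices (the z analog of the point merging:
   one mid-volume miss must not split the organ in two), padded by one
   slice per side.
3. **Intensity clustering inside the ROI.** Each ROI slice is clustered
   into (up to) 7 intensity groups by adaptive K-means on pixel intensity:
   assign to the nearest center by 1D Euclidean distance, recompute each
   center as the mean intensity of its members, repeat until centers move
   less than `tol`; after convergence, adjacent centers closer than 1.5×
   the sum of their within-cluster spreads are fused (the "adaptive"
   ingredient — see the clustering notes below). The cluster lying at the
   window center is selected, interior holes are filled, everything
   outside the ROI is discarded and the largest connected component
   remains. Stacking the per-slice masks gives the 3D contour.

Accuracy is reported with the standard volumetric suite: F1/Dice,
sensitivity (TPR), precision (PPV), volumetric overlap error (VOE = 1 −
Jaccard), relative volume difference (RVD) and the symmetric surface
distances ASSD and MSSD (Hausdorff).

## The classifiers

All three networks share one architecture: input, two 3×3 convolution
layers with 32 filters, three batch normalizations, three ReLUs, two 2×2
max-pooling layers (stride 2), a 2-unit fully connected layer, softmax.
They differ only in input size — sagittal 43×512, coronal 43×256 (the
coronal plane is cropped to the organ's image half, since only one kidney
is analyzed at a time), axial 512×512. Projections are linearly resampled
along z to 43 rows, the canonical organ z extent. Training uses SGD with
momentum (learning rate 0.01, minibatch 64, shuffling every epoch); 40
epochs is the final-system setting and 4 epochs the fast preset used by the
demo pipeline and test suite.

Choices the reference configuration leaves open, and what this package
does:

* **Momentum** is unstated; we use the conventional 0.9.
* **Third BN/ReLU placement.** The layer census lists three batch-norm and
  three ReLU layers but only two convolutions; the third pair is placed
  after the second pooling stage, immediately before the fully connected
  layer.
* **Class imbalance.** Background points outnumber organ points; the loss
  uses inverse-frequency class weights (toggleable).
* **Validation.** A seeded 15% stratified held-out split is evaluated after
  the final epoch; the reference setup reports a validation frequency but
  not a split.
* **Update budget on reduced data.** The reference minibatch (64) against a
  desk-scale training set of a few dozen images yields a handful of SGDM
  updates per training and the optimization visibly oscillates; the
  effective batch is capped at `ceil(N/8)` so every epoch makes at least
  ~8 updates. A no-op at the reference data scale. Independently, a
  training run that still collapses onto one class (detected on its own
  training set) is restarted deterministically from a derived seed, at
  most three times.
* **Ghost batch norm.** At 512×512 the activations of a 64-image minibatch
  do not fit in 8 GiB, so batch-norm statistics are computed over
  memory-bounded sub-batches (size chosen automatically, e.g. 8 for the
  axial network) while the SGD minibatch keeps its configured size. This
  is the standard "ghost batch norm" construction; gradients still
  accumulate over the full minibatch before each weight update. After
  training, the batch-norm population statistics are re-estimated with
  frozen weights (three passes, one per normalization layer): with few,
  rapidly saturating iterations the conventional running averages lag the
  weights so far that inference-mode normalization misclassifies
  everything.
* **Numerics.** The core runs in single precision (im2col + GEMM
  convolutions via BLAS); training is bit-reproducible for a fixed seed on
  a given platform because all randomness (He-normal init, shuffling,
  splits) is drawn from R's seeded RNG.

## Sampling the training set

Organ-class (OC) points are generated per annotated slice under *both*
readings of "equidistant every 50 px": a 50 px 2D grid anchored at the
top-left of the expert-mask bounding box, intersected with the mask
(`organ_points`), united with along-axis point sequences — one point per
50 px of mask height at each row's center column, and one per 50 px of
mask width at each column's center row, including the terminal edge rows
and columns (`organ_line_points`). The union matters: the pure grid
reading concentrates its surviving in-mask points at the organ's widest
rows (the pitch is comparable to the organ size), which leaves the organ's
edge bands without a single positive example and makes the classifiers'
edge-line recall arbitrary — and edge-line recall is precisely what the
ROI's complete-containment property rests on.

Background-class (BC) points lie on a 50 px grid anchored at the image
origin, restricted to the image minus (a) the mask dilated by a Euclidean
disk of radius 60 px, (b) the horizontal strip of the mask's row range and
(c) the vertical strip of its column range, both strips widened by 20 px
per direction. The strip construction guarantees that no BC point's
sagittal or coronal ray touches the organ, so BC projection images are
clean negatives. Because scanning is restricted to the organ's image half
(only one kidney is analyzed at a time), training points are restricted to
that half as well — a sagittal plane through the *mirrored* organ is
visually identical to a positive, and labeling it background poisons the
sagittal classifier. Grid anchors are not stated by the reference
description; fixing them (bbox for OC, origin for BC) makes point counts
reproducible. The axial (Z) training set is built per slice — slices
intersecting the 3D mask are organ, others background, with every slice
within 3 of the mask's z extremes always included (the boundary slices
carry the axial decision) — a construction the reference leaves
unspecified.

## The synthetic phantom world

The clinical dataset behind the method is not public, so the package ships
a phantom generator that reproduces the *structure* the method depends on:
a 43×512×512 grid; a kidney-like ellipsoid (semi-axes ≈ 18×55×35 voxels, so its z extent
fills most of the 43-slice organ region, as the per-organ volumes the
method trains on do) in one image half and a spleen analogue in the other,
each wrapped in a dark fat capsule; a bright spine-like cylinder at the
midline and a large liver-like soft-tissue ellipsoid next to the kidney; a
smooth low-frequency background texture; additive Gaussian noise σ = 0.03
on the normalized soft-tissue-window scale (≈10 HU, the realistic
contrast-CT level — clinical separation-to-noise ratios are 5–10×, and the
intensity-clustering stage only functions in that regime) with
organ/background contrast ≥ 3σ so the two classes are learnable. Cohorts
jitter organ position (±3 slices, ±15 px), size (±15%) and intensity
(±0.04) under a single seed.

The multi-tissue neighborhood is not decoration — the clustering stage is
only well-posed against it. Seven intensity clusters are the right budget
when the window holds several background populations (fat, parenchyma,
muscle) and one compact organ mode, as clinical CT windows do; over a
*single*-tissue background, 1D K-means instead spends several centers
inside the organ's intensity mode, the selected cluster becomes a sparse
stipple below the percolation threshold, and the contour fragments. Early
versions of this phantom violated the regime twice — homogeneous
surroundings (single background cluster, end-to-end F1 near 30% despite
perfect ROI containment), then noise wide enough that K-means split the
organ's own intensity mode into sub-percolation stipples — and the
end-to-end accuracy collapsed both times while every individual stage
behaved exactly as specified. The fat capsule, liver analogue and the
~10 HU noise level restore the intensity structure the method assumes.
Phantom accuracies are analogues of, not substitutes for, clinical results
either way.

What the phantoms deliberately do **not** model: reconstruction artifacts,
beam hardening, organ-shape irregularity, touching organs, pathology. A
green phantom test therefore establishes that the pipeline's logic and
numerics are correct and that its stages interact as designed — not that
the method reaches any particular accuracy on clinical CT.

## Numerical and design decisions

* **Coordinates.** Everything public is 0-based with half-open ranges;
  the scan "starting at (1,1)" in 1-based figure language is index (0,0)
  here. Uniform half-open boxes avoid off-by-one in cube arithmetic.
* **Depth resampling** is linear interpolation along z with endpoint
  preservation; resampling to the source depth is the identity.
* **HU windowing.** The reference pipeline only mentions automatic
  brightness adjustment; the window is a free parameter defaulting to a
  soft-tissue window (−135, 215) HU. Phantoms are generated in [0, 1].
* **Z scan stride.** The 10 px scan step is an in-plane economy (512×512
  points per slice); slices themselves number only ~43–100, so axial
  classification runs at stride 1 by default. With a coarse z stride the
  cube could clip the organ's z tails, contradicting the containment
  property the ROI stage must deliver.
* **Even structuring element.** The 30×30 square dilation uses centered
  offsets [−15, +14] per axis.
* **z padding.** The z run is padded by one slice per side; boundary
  cross-sections are small and their slices may classify as background.
* **K-means details.** Centers initialize at evenly spaced intensity
  quantiles (deterministic; seeded random init available). Assignment ties
  go to the lower-index center. Clusters that end empty are dropped. With
  fewer distinct intensities than clusters the effective count shrinks
  with a warning.
* **Adaptivity.** The reference method names an *adaptive* fuzzy K-means
  but prints only the crisp center-update rule. The adaptive part is not
  optional here: with 7 centers, plain crisp K-means provably splits any
  narrow intensity mode holding 30–50% of the window mass (the organ in
  its tight ROI) across two or three near-identical centers — under
  quantile or range-uniform initialization, at any realistic noise level —
  and the selected cluster degenerates into a sparse organ stipple that
  hole filling cannot repair (both sub-bands percolate to the window
  border, so nothing is an enclosed hole). The package therefore applies
  an ISODATA-style merge after convergence: adjacent centers are fused
  while their separation is below `merge_alpha` (default 1.5) times the
  sum of their within-cluster standard deviations. Distinct tissues stay
  separate (separations are several band widths); sub-bands of one tissue
  fuse. `merge_alpha = 0` restores the literal crisp reading, and the
  Lloyd-iteration oracle tests run in that mode.
* **Cluster selection.** "The cluster closest to the ROI center" is
  scored by the *mean distance of member pixels* to the window center,
  not by the cluster centroid. The centroid rule is unstable in exactly
  the intended case: for an organ slightly off the window center by δ,
  the background complement's centroid sits only δ·n/(N−n) from the
  center — closer than the organ's δ — so the background would win. Mean
  member distance instead favors a compact central blob (the organ, since
  the ROI was built around it) over any border-hugging background
  cluster, which is the selection the published example shows.
* **Hole filling** treats 8-connected background regions not touching the
  window border as interior holes. This matters: when image noise splits
  the organ's intensity range over two clusters, the selected cluster is a
  dense stipple over the organ; above the percolation threshold it forms
  one giant component whose holes (the other cluster's pixels) are filled
  back, recovering the full cross-section.
* **Surface distances** use face-connectivity surfaces (6-neighborhood in
  3D, 4 in 2D, grid edges count as outside) and exact Euclidean distance
  transforms with anisotropic spacing; ASSD averages both directed
  distance sets jointly, MSSD is their maximum.
* **TPR/PPV formulas.** The printed equations (TP/(TP+FP) labelled
  sensitivity, TN/(TN+FP) labelled specificity) conflict with their names
  and with the reported value ranges; the defaults are the standard
  sensitivity TP/(TP+FN) and precision TP/(TP+FP), with the literal
  printed formulas available behind `paper_formulas = TRUE`.
* **Epochs 4 vs 40.** Two stated values exist; 40 (the final-system
  table) is the default, 4 is kept as the fast preset and used by the
  demo and the acceptance runs.

## Runtime scaling of the demo preset

The demo pipeline (`run_config()` defaults) must train three networks and
evaluate ten full-size phantoms on one CPU inside a test-suite budget, so
the *amount* of data is reduced without touching the stated world: 6
training phantoms, X/Y sampling on every 3rd annotated slice, at most 8
background points per slice (seeded subsample), the axial set from 4 cases
at z stride 4 plus the ±3 boundary windows, 4-epoch preset. Grid size,
network shapes, sampling geometry (50/60/20 px), scan parameters
(10/10/30 px) and phantom statistics are exactly the stated values. On a
single throttled CPU one full pipeline run takes ~10 minutes; measured
there, the seeded demo reaches complete ROI containment in 10/10
evaluation phantoms and a mean voxel F1 of 88.2%.

## Known limitations

* Multi-instance detection is out of scope: one cube per organ per volume,
  by largest-component selection.
* Clustering is strictly per-2D-slice and intensity-only; no spatial
  features, no 3D clustering, no fuzzy memberships.
* The NIfTI reader handles single-file NIfTI-1 scalar images (the formats
  this pipeline produces and consumes), not DICOM series or orientation
  matrices beyond axis reordering.
* Phantom realism is structural, not radiometric; accuracy numbers from
  phantom cohorts are analogues, not reproductions, of clinical results.
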