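# ctroi

Localization and contouring of abdominal organs (kidneys, spleen) in CT
volumes by **orthogonal projection classification**: three small CNNs decide,
per axis, whether the sagittal / coronal / axial projection through a point
shows the organ; the intersection of the three per-axis decisions yields a 3D
region-of-interest cube; intensity K-means clustering inside the cube, with
morphological post-processing, recovers the organ contour. No semantic
segmentation network, no GPU.

The package is a complete, self-contained laboratory for the method:

* `volume_io` — NIfTI-1 reading/writing, `(z, y, x)` convention, HU
  windowing, depth resampling, half-cropping;
* `phantom` — seeded synthetic CT phantoms (ellipsoid organs, spine-like
  distractor, texture, noise) standing in for restricted clinical data;
* `sampling` — organ-class/background-class point generation from expert
  masks and projection-triplet extraction;
* `models` — the three per-axis classifiers (2×conv 3×3×32, 3×BN, 3×ReLU,
  2×maxpool, FC+softmax; SGDM, lr 0.01, minibatch 64), implemented in
  RcppArmadillo;
* `roi_search` — step-10 scan with per-line exclusion, point merging,
  largest-component + 30×30 dilation, z-run bounding → ROI cube;
* `clustering` — per-slice 7-cluster intensity K-means, central-cluster
  selection, hole filling → 3D organ mask;
* `metrics` — F1/Dice, TPR, PPV, VOE, RVD, ASSD, MSSD (exact EDT), cohort
  tables;
* `cli` / `pipeline` — end-to-end orchestration with one master seed.

## The statistic at the core

A point `P(x, y, z)` belongs to the ROI iff all three of its projections
classify as organ:

    ROI = { (x,y,z) : N_X(I_x) = N_Y(I_y) = N_Z(I_z) = organ }

Each projection depends on one coordinate only, so scanning each axis once
and intersecting flag vectors is *exactly* the per-point scan with the
paper-style exclusion optimization (tested against brute force). Clustering
then minimizes within-cluster intensity variance per ROI slice,

    c_j = (1 / n_cj) * sum_{p in cluster j} p(x, y),

iterated with nearest-center assignment until convergence; the cluster whose
pixels lie closest to the cube center is the organ.

Evaluation: `F1 = 2TP/(2TP+FP+FN)·100`, `TPR = TP/(TP+FN)·100`,
`PPV = TP/(TP+FP)·100`, `VOE = (1−J)·100`, `RVD = (|P|−|R|)/|R|·100`, plus
average and maximum symmetric surface distance in mm.

## Worked example

```r
library(ctroi)

# train the three per-axis classifiers on six synthetic abdomens
# (fast 4-epoch preset; ~5 min on one CPU)
cfg  <- run_config(organ = "kidney_right", seed = 7)
nets <- train_axis_classifiers(make_cohort(cfg$n_train, phantom_spec(),
                                           seed = 7),
                               "kidney_right", cfg)

# locate and segment one unseen case
cohort <- make_cohort(10, phantom_spec(), seed = 8)
vol <- cohort[[1]]$volume
roi <- find_roi(vol, nets, cfg$search, organ = "kidney_right")
roi
#> <roi_box z[2,37) y[195,335) x[125,225)>
roi_coverage(roi, cohort[[1]]$masks$kidney_right)
#> [1] 1
seg <- segment_organ(vol, roi, cluster_config(), label = "kidney_right")
overlap_metrics(seg, cohort[[1]]$masks$kidney_right)
#> F1 97.69  TPR 100.00  PPV 95.48  VOE 4.52  RVD +4.73  (TP 159227 FP 7540 FN 4)
```

The cube completely contains the ground-truth kidney (coverage 1) and the
clustered contour matches the expert mask to F1 97.7 on this case.  The
numbers above are the printed output of this exact script; the same seeds
reproduce them bit for bit on the same platform.

The full demo pipeline — cohorts, training, localization, clustering,
metrics report — is one call (or `inst/cli/ctroi run --demo --seed 7`):

```r
res <- run_pipeline(run_config(seed = 7))
tail(res$report[, c("Group", "F1", "VOE", "ASSD", "coverage")], 1)
#>    Group       F1      VOE     ASSD coverage
#> 11  mean 94.59288 10.12815 2.690079        1
```

On the seeded 10-phantom evaluation cohort the ROI cube completely
contains the organ in 10/10 cases and the mean voxel F1 is 94.6%
(VOE 10.1%) — the same scale as the 88–89% F1 / 9.4% VOE reported on
clinical kidneys by the method this package implements.

## Command line

```
ctroi phantom  --n 10 --seed 7 --out phantoms/
ctroi train    --n 4 --organ kidney_right --seed 7 --preset fast --out models/
ctroi locate   --in vol.nii.gz --models models/ --organ kidney_right --out roi.json
ctroi segment  --in vol.nii.gz --roi roi.json --out mask.nii.gz
ctroi evaluate --pred mask.nii.gz --ref ref.nii.gz --out report.csv
ctroi run      --demo --seed 7 --out out/
```

See `vignettes/methods.Rmd` for the model, its assumptions, parameter
meanings and the design decisions behind ambiguous corners.
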