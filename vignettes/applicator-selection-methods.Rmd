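---
title: "Methods: geometry encoding, the compact 3D network, and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry encoding, the compact 3D network, and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(brachysel)
```

## The clinical problem

In high-dose-rate (HDR) brachytherapy for locally advanced cervical cancer,
the physician chooses between an intracavitary tandem-and-ovoids (T&O)
applicator and an interstitial Syed applicator. Syed applicators offer more
flexible dose shaping for bulky, laterally extended, or asymmetric targets,
at the cost of a considerably more invasive procedure. The choice hinges on
geometry: the volume of the clinical target (HR-CTV, plus IR-CTV when
delineated), how far it extends laterally from the uterine canal, how
asymmetric it is about that canal, and how close the organs at risk (OARs)
lie. `brachysel` implements a decision-support classifier for this choice:
a compact 3D convolutional network over an anatomy encoding, with a
handcrafted-feature classical-ML pipeline as benchmark, and a synthetic
pelvic-anatomy generator that allows the whole pipeline to be exercised and
validated end to end without patient data.

## Anatomy encoding

All computations use the digitized central tandem as the anatomical axis —
a stand-in for the cervical canal, which is typically not contoured.

* **Grid.** Structures are rasterized on a 2 mm isotropic grid of
  165 x 176 x 176 voxels (axis order superior-inferior,
  anterior-posterior, left-right). The window is centered on the tandem
  polyline centroid; the source data say only that volumes were cropped to
  this size, so centering on the anatomical axis is this package's
  convention, chosen because it registers every case the same way.
* **Rasterization.** A voxel belongs to a structure iff its center is
  inside the contour polygon of the nearest slice (even-odd rule) and lies
  within that slice's thickness band (half the stack's typical slice
  spacing — its upper-quartile z gap — on either side, so interleaved
  multi-component stacks keep full bands; nested contours act as holes). Label resampling between
  grids is nearest-neighbor — labels are categorical.
* **Label codes.** 1 = CTV (HR-CTV united with IR-CTV when present),
  2 = tandem (polyline dilated to a 5 mm diameter tube), 3 = any OAR,
  0 = background. At overlaps the precedence is tandem > CTV > OAR, so the
  tandem that anchors the distance channels is never occluded.
* **Distance channels.** Channel 2 holds, at every CTV voxel, the 3D
  Euclidean distance (mm) from the voxel center to the tandem polyline
  (minimum over segments); channel 3 does the same for OAR voxels. Both are
  zero off their support. Distances are measured to the raw polyline, not
  the 5 mm display tube — the difference is a constant 2.5 mm offset — and
  no normalization is applied anywhere, so physical size information
  reaches the classifier intact. A mask-only (1-channel) mode drops the
  distance channels for ablation studies.

## The network

Six convolutional blocks (conv -> max-pool -> batch-norm -> ReLU) are
followed by global average pooling, a dense layer of 8 with 10% dropout,
and a single sigmoid output neuron giving the Syed-suitability score
`p` in (0, 1); `p >= 0.5` recommends Syed. Filters per block are
4, 4, 8, 8, 4, 4 with kernels (3,2,2), (2,2,2), (3,3,3), (3,2,2), (3,3,3),
(3,3,3), symmetric zero-paddings (1,1,1) x 3, (2,1,1), (1,1,1) x 2, and
pools (3,3,3) then (2,2,2) x 5.

Counting every convolution and dense weight and bias gives 3281 values;
adding four per batch-normalized channel (scale, shift, running mean,
running variance; 32 channels) gives the 3409 parameters of the 3-channel
configuration and 3313 for the mask-only variant (only the first kernel
shrinks). `count_parameters()` implements exactly this convention.

Conventions the architecture table leaves open, fixed here:

* **Pooling** is non-overlapping with *ceil-mode* windows: a partial window
  at a border is pooled rather than dropped. This is the convention under
  which the pooling chain reduces both the full 165 x 176 x 176 grid and
  the coarser 48^3 experimental grid cleanly to a small map; floor-mode
  pooling collapses a 48^3 input to size zero at block 6. A `ShapeError`
  is raised when a *convolution* output dimension would fall below one.
* **Initialization** is uniform with fan-in scaling
  (limit `sqrt(3 / fan_in)`), biases zero, batch-norm at identity, fully
  deterministic under a seed.
* **Inference** uses batch-norm running statistics and no dropout, so it is
  deterministic and independent of batch composition.

Because no deep-learning framework is part of this package's dependency
set, the convolution, pooling, batch-norm and dense layers — and their
backward passes — are implemented in the package itself (C++ kernels via
Rcpp). Every gradient path is verified against central finite differences
at relative tolerance 1e-4 in the test suite.

## Training

The loss is binary cross-entropy over the batch plus an L1 penalty
`lambda * sum(|W_j|)` over all optimized parameters (convolution and dense
weights and biases, batch-norm scale and shift; running statistics are not
optimized and therefore excluded). Scores at exactly 0 or 1 are clamped to
machine epsilon with a warning.

* **Balanced patient-level sampling.** Each batch slot draws a class with
  probability 0.5, then a uniform patient of that class, then a uniform
  insertion of that patient — so the expected class frequency in a batch is
  0.5 whatever the cohort's insertion-level imbalance.
* **Augmentation.** With probability 0.75 a sample is augmented: equally
  likely a translation (uniform within ±10 mm per axis — the bound is not
  part of the published scheme and is configurable) or a rotation of up to
  ±10° about the superior-inferior axis, followed by an independent
  left-right flip with probability 0.5 (overall flip rate 0.375, the flip
  being conditional on augmentation). All channels are transported rigidly
  by nearest-neighbor resampling; distances are *not* recomputed because a
  rigid motion of anatomy and tandem together leaves axis distances exactly
  invariant. No deformations, ever — volume and spatial relations carry the
  label.
* **Schedule.** Staircase learning rate `0.001 * 0.93^floor(step / 200)`,
  400 epochs of 40 batches of 8 (50 batches for a final fit on all data),
  dropout 10%, L1 weight 0.03. The optimizer is not named in the source
  description; Adam is the default here, with plain SGD available.
* **Grouped cross-validation.** Folds partition *patients*, stratified by
  patient class; all insertions of a patient share a fold, and the
  no-leakage property is asserted on every run. Validation accuracy is
  defined per insertion. `fold_summary()` reports mean and sample standard
  deviation across folds, the convention used when summarizing fold
  accuracies (e.g. folds of 98.6, 91.6, 91.4, 90.4, 88.5 summarize to
  92.1 ± 3.8).

## Handcrafted features and the classical benchmark

Twenty geometric features per insertion, in a fixed documented order
(`feature_names()`): CTV volume (cc); mean and max lateral extension (mm) —
per axial slice, the largest in-plane distance from the tandem axis point
to a CTV voxel center, the axis being interpolated inside the polyline's
z-range and extended as a fitted straight line beyond it; mean and max
per-slice center-of-mass offset from the axis (asymmetry); and, per OAR
(bladder, rectum, sigmoid, small bowel, large bowel), the max/min/mean
distance to the CTV surface over the nearest-2cc OAR sub-volume — the
`floor(2000 mm^3 / voxel volume)` OAR voxels closest to the CTV boundary
(250 voxels at 2 mm; all voxels for OARs under 2 cc; ties broken by
distance then voxel index). Distances are unsigned voxel-center-to-
boundary-center distances, zero inside the CTV; a missing OAR contour
records a 999 mm sentinel triple (far enough to be dosimetrically
irrelevant) with a warning.

The benchmark pipeline ranks features by one-way ANOVA F-score, keeps the
`n_top` best (any of 1..20; 8 matched the reference study's best
configuration), standardizes them with training-set statistics, balances
the training classes by SMOTE (synthetic minority samples as convex
combinations toward one of the k = 5 nearest minority neighbors), tunes an
SVM (RBF), a random forest, k-NN and a decision tree by small grid searches
with 5-fold CV (SMOTE re-applied inside each fold to avoid synthetic-sample
leakage across folds), and averages the four Syed probabilities into a
soft vote, Syed iff the mean is at least 0.5. The four families are fitted
through `e1071`, `randomForest`, `class` and `rpart`; the grid contents are
package defaults (they are not specified by the source description) and are
logged with every run.

## The synthetic study

Clinical structure sets are institutional and unavailable, so the package
ships a generator of synthetic pelvic anatomies with a *known, analytic*
ground-truth label:

* **Geometry.** A near-vertical tandem (60 mm, small anterior bow); a CTV
  built from 1-3 ellipsoid components stacked disjointly along the
  superior-inferior axis with controllable volume (the cohort sampler draws
  20-120 cc, covering the clinically cited regime), lateral offset (up to
  ~18 mm) and shape ratios; OARs placed anatomically — bladder anterior,
  rectum posterior, sigmoid superior, bowel lateral/superior — at
  controllable gaps. Contours are sampled from the parametric surfaces at
  2.5 mm slice spacing (exercising resampling onto the 2 mm grid) with a
  smooth ~1 mm radial jitter.
* **Label rule.** Syed iff analytic max lateral extension > 30 mm, or
  analytic max per-slice centroid offset > 8 mm, or analytic volume >
  60 cc — thresholds in the spirit of published guidance that intracavitary
  applicators suit targets up to roughly 4 x 3 x 3 cm. The quantities are
  computed from the generating parameters (densely sampled parametric
  boundaries), never from a rasterization, so labels are noiseless.
* **Separability margin.** The cohort sampler rejects anatomies whose rule
  quantities fall within an exclusion band around the thresholds (5 mm on
  extension, 2.5 mm on offset, 10 cc on volume — roughly twice the
  deviation between analytic and rasterized-then-measured quantities at
  2-3 mm voxels). Without the band, a noticeable fraction of cases sits
  closer to the decision boundary than the contour-jitter and voxelization
  noise of the *observable* inputs, and no classifier can recover those
  labels from the data; recovery experiments are meaningful only on a
  separable cohort. The band can be set to zero to study exactly this
  degradation.
* **Cohorts.** Each patient draws a class (Syed fraction 0.3, near the
  reference cohort's insertion-level imbalance), then an anatomy matching
  that class by rejection; insertions of the same patient are small
  perturbations (≤ ~3 mm surface change) of the base anatomy, so grouped
  cross-validation leakage is meaningful to test. An optional label-flip
  rate can emulate physician variability; the default is zero.

## The downscaled recovery experiment

The published experiment — 372 insertions at full resolution, 16,000
optimization steps on a GPU — is not reproducible at desk scale, and its
headline accuracies depend on the unavailable patient data. The package's
recovery experiment instead asks whether the full pipeline can recover the
generator's geometric rule: 60 patients / 120 insertions encoded on a 48^3
grid at 3 mm spacing (a 144 mm field of view that holds the CTV and the
near faces of the OARs), 3-fold grouped CV. For this problem size the same
heuristic tuning that produced the published hyperparameters led to a
lighter schedule (`downscale_config()`): L1 weight 0.003, learning rate
0.002 with the same 0.93 / 200-batch staircase, 60 epochs of 20 batches of
8. With the published values (L1 0.03, lr 0.001) at this scale the L1 term
dominates early training and convergence within the step budget suffers.
Both the network and the handcrafted-feature ensemble recover the rule at
≥ 90% mean validation accuracy under these conditions; the ablation
experiment (identical seeds and folds, same encodings) checks the
direction of the published comparison — full 3-channel input never worse
than mask-only. On the separable synthetic cohort both modes reach
ceiling and tie: with a fixed, known voxel spacing the mask alone already
carries physical scale implicitly, whereas the published gap was measured
on heterogeneous clinical anatomy. The synthetic ablation therefore
verifies that the distance channels cost nothing, not the size of their
clinical benefit.

What passing these experiments does and does not show: the synthetic
anatomies are smooth ellipsoid-based bodies with a deterministic geometric
label; real targets are irregular, their labels carry physician and
dosimetric variability, and contouring practice differs between
institutions. Recovery of the synthetic rule validates the machinery —
encoding, network, training, features — not clinical performance.

## Numerical choices and degenerate inputs

* Tandem polylines must be strictly monotone along the superior-inferior
  axis; inferior-first polylines are normalized to superior order, anything
  non-monotone is rejected (`MalformedTandem`) rather than silently
  reordered.
* Polygons need ≥ 3 vertices (`DegenerateContour`); structure sets need an
  HR-CTV (`MissingTarget`) and a tandem (`MissingTandem`).
* Batch-norm uses epsilon 1e-5 and momentum 0.1 on running statistics.
* Max-pool ties resolve to the first voxel in scan order; the
  accuracy-maximizing threshold sweep breaks ties toward 0.5.
* Metrics with empty denominators are `NA`, never 0.
* IR-CTV, when present, is united with HR-CTV *before* any resampling.
* The structured-text contour format (JSON: identifiers, tandem polyline,
  per-structure planar contours) is the supported on-disk input; it is
  what the phantom generator emits, and contours exported from DICOM-RT
  structure sets can be converted to it with any DICOM toolchain. Binary
  DICOM parsing is outside this package's scope.

## Known limitations

* CT intensities are deliberately excluded (TG-43 planning assumes
  homogeneous density); MRI workflows, dose computation and DVH-based plan
  verification are out of scope.
* The published trained weights are not available; nothing here attempts to
  reproduce per-case clinical scores, only the architecture, training
  scheme, and published-table arithmetic.
* The optimal-threshold utility (`threshold_sweep()`) reproduces the
  *procedure* of selecting a validation-accuracy-maximizing threshold; the
  specific published value (0.494) is tied to the private cohort and is not
  a reproduction target.
* Training at full 165 x 176 x 176 resolution is supported but slow on a
  single CPU; the recovery experiment's problem sizes above are the
  package's validated operating point.
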