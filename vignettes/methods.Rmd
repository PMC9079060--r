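---
title: "Coarse-to-fine 3D U-Net segmentation of the maxillary sinus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine 3D U-Net segmentation of the maxillary sinus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The maxillary sinus is an air-filled cavity in the maxilla whose 3D
segmentation from cone-beam CT (CBCT) underpins volumetric assessment,
surgical planning and virtual model generation. Manual and semi-automatic
segmentation are slow and observer-dependent; the pipeline implemented here
automates it: two 3D U-Nets arranged coarse-to-fine produce a binary sinus
mask and a smoothed surface model from a raw CBCT volume, and a metric suite
quantifies agreement between segmentations.

Because clinical CBCT data cannot be redistributed, the package ships a
synthetic phantom generator that emulates the geometry and intensity
structure the method relies on. Everything — training, inference,
evaluation — runs end to end on phantoms on a single CPU.

## The segmentation model

Both stages use the same 3D U-Net family (`network_spec()`): 4 encoder and 3
decoder blocks; each block applies two 3×3×3 convolutions, each followed by
group normalization (8 groups) and a ReLU; 2×2×2 max pooling with stride 2
after each of the first three encoders, so the resolution drops by a factor
8 along the encoder path and input extents must be divisible by 8. Decoders
upsample trilinearly, concatenate the skip connection from the matching
encoder level and convolve again; a 1×1×1 convolution with a logistic
squashing produces a per-voxel probability. Channel widths are
`base_channels * (1, 2, 4, 8)`.

Design points that the architecture description leaves open, and how they
are resolved here:

* **Block ordering.** "Two convolutions followed by ReLU and group
  normalization" is ambiguous about order; we use the standard
  conv → GN → ReLU ordering.
* **Group count vs. group width.** "Group normalization with 8 feature maps"
  is read as 8 *groups* (the common convention). When a reduced-width
  network has fewer channels than groups, the group count drops to the
  largest divisor of the channel count.
* **Upsampling.** Trilinear interpolation followed by convolution rather
  than transposed convolution: unspecified upstream, and it avoids
  checkerboard artifacts.
* **Input normalization.** Intensities are mapped linearly from the fixed
  window [−1000, 400] HU to [0, 1] and clamped. A fixed window (rather than
  per-scan statistics) keeps inference a pure function of the weights and
  the voxel data, which is what makes the test–retest property exact.
* **Head initialization.** The final bias starts at −2, a background prior
  that reflects the strong class imbalance (the sinus occupies a few percent
  of a scan); conv weights are He-normal, seeded and reproducible.

The network, its backpropagation and the ADAM optimizer are implemented in
the package itself (R + RcppArmadillo): the 3×3×3 convolution runs as 27
shift-and-GEMM passes over a zero-padded feature map, in single precision on
the GEMM path with double precision everywhere else. A package option
(`sinusseg.conv_double = TRUE`) switches the convolutions to full double
precision; the test suite uses it to validate the analytic gradients against
finite differences at ~1e-3 relative accuracy.

## Training

Both networks are trained as per-voxel binary classifiers with a weighted
binary cross-entropy,

$$L = -\frac{1}{N}\sum_n \big[\, w\, y_n \log p_n + (1-y_n)\log(1-p_n) \,\big],$$

with probabilities clamped to $[10^{-7}, 1-10^{-7}]$ before the logs. The
positive-class weight $w$ defaults to the inverse class frequency of each
batch, capped at 100 to keep nearly-empty patches from blowing up the
gradient. Optimization uses ADAM with learning rate 1.25e−4. Random spatial
augmentations — rotation (±10°), isotropic scaling (±10%) and an elastic
deformation sampled on a 4³ control grid (sd 1 voxel) — are applied to half
the training samples, with the image interpolated trilinearly and the mask
by nearest neighbour so it stays binary. The validation set drives early
stopping: training stops once the validation loss has failed to improve for
more than `patience` consecutive epochs (default 5; `patience = 0` stops at
the first non-improving epoch) and the weights of the best validation epoch
are returned. Every run is reproducible from a single integer seed, which
fans out to phantom generation, weight initialization, patch sampling,
shuffling and augmentation through a fixed derivation.

Batch size, epoch budget and augmentation magnitudes are configuration
values (`train_config()`), not claims about any reference system.

## The two-stage pipeline

`run_pipeline()` chains, deterministically:

1. **Isotropic resampling** to the working resolution (default 0.4 mm).
2. **Coarse stage**: the scan is downsampled to a fixed 32³ grid, segmented
   by the first network, and the probability map is upsampled back.
3. **Patch proposal**: the coarse map is thresholded at 0.5; the bounding
   box of the foreground, inflated by a 4-voxel margin, is tiled with 32³
   patches at 16³ stride. Patches that stick out of the grid are shifted
   inside (origins move, sizes never shrink); only patches intersecting the
   thresholded foreground are kept, in lexicographic origin order.
4. **Fine stage**: each patch is segmented at full resolution by the second
   network; overlapping voxels receive the arithmetic mean of contributing
   predictions, uncovered voxels probability 0. Averaging before
   thresholding is order-independent, which the stitching tests verify.
5. **Post-processing**: binarization at 0.5 (≥ is foreground) and selection
   of the single largest 26-connected component; ties break to the component
   containing the first voxel in raster order. An all-background result is
   returned as an empty mask with a failure flag (the "could not predict
   anything" outcome, exit code 1 in the CLI).
6. **Mesh extraction**: an isosurface at level 0.5 via marching tetrahedra —
   each lattice cell is split into 6 tetrahedra sharing a body diagonal, so
   neighbouring cells triangulate their shared faces identically and the
   mesh is watertight whenever the mask avoids the grid boundary. Vertices
   are welded on lattice edges and mapped to mm world coordinates. We chose
   the tetrahedral variant of the marching family because it needs no
   256-case table and is easy to prove watertight; the properties checked
   downstream (Euler characteristic, closedness, volume) do not depend on
   the variant. Smoothing uses 10 Taubin λ/µ iterations (λ = 0.5,
   µ = −0.53), which smooths without the volume shrinkage of plain Laplacian
   smoothing; the tests bound the enclosed-volume drift at 2% on a 10³ cube.

Patch size, stride, the coarse grid and the margin are `pipeline_config()`
values sized for CPU execution; none of the evaluated properties depend on
matching any particular original values.

## The phantom generator

`generate_phantom()` rasterizes a parametric scene chosen to exercise
exactly the structures the method must handle:

* an air cavity (−1000 HU) shaped as a rotated superellipsoid — a cheap
  proxy for the sinus' rounded-pyramidal shape that admits a closed-form
  volume check (the voxelized cavity volume matches $\frac{4}{3}\pi abc$
  within 5% at the default resolution);
* a bone shell (+1000 HU) of 1.2 mm around it, inside uniform soft tissue
  (+40 HU);
* an optional mucosal lining (+30 HU) of configurable thickness on the
  cavity wall. The lining belongs to the *wall*, not to the air: the ground
  truth excludes it, which reproduces the clinically relevant ambiguity that
  concentrates segmentation errors at thickened walls (shallow > 2 mm,
  moderate > 4 mm in the usual grading);
* an optional ostium-like channel draining into a second, smaller "nasal"
  cavity. The ground truth stops at the channel's mouth on the cavity
  surface, implementing geometrically the convention of cutting the
  segmentation at the early start of the ostium; and
* additive Gaussian noise (default sd 40 HU), applied last, seeded.

The default cohort (`generate_dataset()`) jitters cavity size (±15%),
orientation (±15°) and lining thickness (half the samples carry a 2–4 mm
lining) at 64³ voxels and 0.4 mm spacing. The air window −1024..−200 HU
(`threshold_air_mask()`) isolates air exactly on noiseless phantoms, which
gives the generator its own oracle: restricted to the cavity's connected
component, the thresholded air mask equals the ground truth bit for bit.

What the phantoms deliberately do **not** model: beam-hardening streaks,
metal artifacts, detector noise correlation, HU calibration drift, and
anatomical shape statistics. Passing the phantom benchmark therefore shows
that the pipeline machinery — training, patching, stitching,
post-processing, metrics — works end to end on data with realistic contrast
and class imbalance; it does not certify clinical accuracy on real CBCT.

## Evaluation metrics

`evaluate_pair()` computes, from exact voxel-wise confusion counts:

* **DSC** $= 2|X\cap Y| / (|X|+|Y|) = 2TP/(2TP+FP+FN)$,
* **IoU** $= |X\cap Y|/|X\cup Y| = TP/(TP+FP+FN)$ (the identity
  $DSC = 2\,IoU/(1+IoU)$ is asserted to 1e−12 in the tests),
* **95% Hausdorff distance**: boundary voxels (foreground voxels with a
  background 6-neighbour) of both masks are scaled to mm; the two directed
  closest-point distance sets are pooled and their 95th percentile taken
  with linear interpolation between order statistics. Pooling makes the
  value symmetric; the source formulation of the percentile construction is
  garbled in the literature this follows, and the pooled-percentile reading
  is the one consistent with "robust symmetric Hausdorff". Mask surfaces
  and mesh vertex sets are both accepted; which one was used is up to the
  caller and recorded in the report.
* **RMS surface distance**: $\sqrt{\tfrac1n\sum x_i^2}$ over closest-point
  distances from each vertex of one mesh to the *triangle surface* of the
  other (point-to-triangle, not vertex-to-vertex), averaged over the two
  directions to make it order-independent.

Degenerate input: when both masks are empty, DSC and IoU are defined as 1
with a warning (perfect agreement on absence) — this avoids 0/0 while
keeping the case visible, and batch summaries can exclude it via the
`both_empty` flag.

All four metrics are validated against brute-force oracles (set arithmetic
and all-pairs distances) on small random masks, exactly for the overlap
metrics and to 1e−9 mm for the distances.

## Numerical and reproducibility choices

* Voxel indexing is 0-based with the voxel centre at
  `origin + index * spacing`; this convention is what makes mesh/world
  coordinates exact in the STL round-trip tests.
* Resampling aligns grid centres, preserving the field of view to within
  one voxel; masks always resample nearest-neighbour.
* DICOM input is restricted to uncompressed Explicit-VR little-endian CT
  slices with axis-aligned orientation cosines (permutations and flips are
  normalized at load; oblique series are rejected with a format error).
  The reader is validated against an independent DICOM implementation in
  the test suite.
* The pipeline contains no random number draws at inference time, no
  time-dependent state and no parallel reductions with nondeterministic
  order, so repeated runs are byte-identical — the test–retest property is
  asserted as exact equality, not a tolerance.

## Problem sizes used by the shipped benchmark

`run_headline_experiment()` trains on 50 phantoms (plus 10 validation) and
evaluates on 20 held-out phantoms at 64³, with 4 fine patches per training
scan. The coarse stage gets an 8-epoch cap — it only has to propose a
region of interest, which it learns quickly — while the fine stage, which
sets the final boundary, gets 14 epochs (patience 3 on the validation
loss). These sizes are the package's desk-scale defaults: at the fixed
learning rate the fine network needs a few thousand ADAM steps to saturate
its boundary accuracy, and ~2800 steps (14 epochs of 200) provides that
while keeping the whole benchmark runnable unattended on one CPU. Seeds
differ in convergence speed; across the seeds exercised by the test suite
the held-out mean DSC lands between roughly 0.985 and 0.996 at this
schedule, still rising slowly with further epochs. The mean held-out DSC
is the quantity `scripts/acceptance.R` reports.

## Known limitations

* The phantom family is geometric; none of the confounders that drive
  residual error on clinical CBCT (artifacts, pathology, true anatomical
  variability) are represented, so phantom DSC values sit above what any
  clinical dataset would yield.
* The fine stage sees only patches proposed by the coarse stage; a coarse
  miss cannot be recovered downstream (mitigated, not removed, by the
  bounding-box margin).
* Training is single-threaded CPU code; it is meant for desk-scale
  experiments and testing, not for training clinical-scale models.
* Meshes for masks touching the grid boundary are open at the boundary and
  flagged with a warning rather than capped.
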