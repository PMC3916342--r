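---
title: "Detecting chemical synapses in anisotropic ssTEM volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chemical synapses in anisotropic ssTEM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Serial-section transmission electron microscopy (ssTEM) images brain tissue
at a few nanometers laterally but tens of nanometers axially (the reference
resolution throughout this package is 4.5 x 4.5 x 45 nm). Chemical synapses
appear as dark, slightly curved sheets — the thickened pre- and postsynaptic
membranes around a 10–20 nm cleft — with a cloud of 40–50 nm synaptic
vesicles on the presynaptic side. Finding every synapse by hand in a
connectomics-scale volume is prohibitive; `emsynapse` automates it with a
two-stage learning pipeline that needs only sparse voxel scribbles and a few
hundred object-level yes/no labels, and no prior segmentation of the tissue
into cells.

## The pipeline

1. **Axial upsampling.** The stack is interpolated by a factor of 2 along z
   (edge-aligned linear interpolation, so original slices are preserved
   exactly). This does not create information, but gives the 3D filters a
   grid on which their isotropic neighborhoods are less distorted.
2. **3D pixel features.** A fixed 26-channel bank: Gaussian smoothing at
   sigmas 0.7, 1.0, 1.6, 3.5, 5.0, 10.0; Hessian eigenvalues at 1.6, 3.5,
   5.0, 10.0 (3 channels each); Laplacian of Gaussian at 3.5, 5.0, 10.0;
   difference of Gaussians at 5.0 and 10.0 (inner sigma 0.66 x sigma);
   structure-tensor eigenvalues at 5.0 (gradient scale sigma/2). Sigmas are
   in pixels of the upsampled grid and identical in all three dimensions.
3. **Pixel classification.** A Random Forest (100 trees, grown to purity,
   sqrt(26) features per split) learns three classes — synapse, membrane,
   everything else — from sparse labels, and produces a per-voxel synapse
   probability map.
4. **Detection.** The synapse probability is thresholded at 0.5 (strict),
   connected components are extracted (26-connectivity, the most forgiving
   of z-anisotropy), components outside [100, 1e6] native-grid voxels are
   discarded, and each surviving bounding box is enlarged by 500 nm per side
   — the prior on the full spatial extent of a synapse.
5. **Graph-cut segmentation.** Inside each enlarged box the binary labeling
   minimizing
   `E(L) = sum_p D_p(L_p) + beta * #{6-neighbor pairs with unequal labels}`
   is found exactly by max-flow/min-cut, with
   `D_p(background) = 2 p_syn(p)` and `D_p(synapse) = 2 (1 - p_syn(p))`.
   The pairwise term is a *constant* Ising penalty, not a contrast-modulated
   one: a synapse contains two strong internal edges (the cleft), so the
   model must not encourage the object boundary to snap to image edges.
   The `beta = 0` limit coincides with the 0.5 detection threshold, which
   fixes the sign convention for the unary term.
5b. **Candidate bookkeeping.** An enlarged box may contain more than one
   object, and one object may seed several detected components. Each
   candidate is therefore restricted to the connected components of the
   graph-cut output that touch its seeding component, and candidates whose
   segmented masks share voxels are merged and reported once. Candidates
   whose mask is empty or misses the seeding component are dropped.
6. **Object classification.** For every candidate, 29 object-level features
   are computed: mean/variance/skewness/kurtosis of the raw gray values over
   the object and over its neighborhood (within 30 px in x and y and 1 px in
   z, by anisotropic distance transform, object excluded); 10-bin uniform
   local-binary-pattern histograms (P = 8, R = 1, per-slice 2D, pooled) of
   object and neighborhood; and the ratio of the largest to the smallest
   principal component of the voxel coordinates in nm. A second 100-tree
   Random Forest scores each candidate; `score >= 0.5` accepts it.

Raising the acceptance threshold trades recall for precision monotonically;
the package exposes the sweep directly via `classify_candidates()`.

## Why graph cut rather than hysteresis

Hysteresis thresholding (keep components above a low threshold that contain
a voxel above 0.5) is faster but under-segments: it attaches long
thin probability ridges to correct objects and sometimes merges neighboring
candidates. The min-cut solution pays `beta` per exposed face, so thin
protrusions whose per-voxel unary advantage is small are cut off — the
"shrinking bias" works in our favor. `segment_hysteresis()` is provided as
the comparison baseline and tested against exactly this behavior on a
constructed protrusion fixture.

## Choosing beta

The printed record of the original pairwise constant is not available, so
the package never hard-codes one. `default_beta()` calibrates it the same
way one would against a handful of manually segmented synapses:
`calibrate_beta()` maximizes the mean Jaccard index of graph-cut output
against reference masks over a grid (default 0, 0.05, 0.1, 0.2, 0.4, 0.8,
1.6; ties resolved toward the smaller value). The built-in calibration
fixtures are probability phantoms with realistic two-sided noise (object
voxels dip under 0.5, background speckle rises above it) — on noise-free
maps every beta is equally perfect and calibration would be vacuous. With
the default fixtures the calibrated value is 0.4; `pipeline_config(beta =
NULL)` re-derives it at run time.

## The max-flow solver

The Ising energy with `beta >= 0` is submodular, so the global optimum is a
minimum s-t cut. General-purpose min-cut routines in R handle graphs of this
size (10^6–10^7 nodes per candidate box) orders of magnitude too slowly, so
the package ships a Boykov–Kolmogorov max-flow implementation specialized to
the 6-connected grid (in C++). Its exactness is enforced by tests in two
independent ways: exhaustive enumeration of all labelings on every crop up
to 2 x 2 x 3 (over a thousand random instances), and agreement of the cut
value with `igraph`'s max-flow on medium crops. Ties among multiple optima
are resolved by the solver's deterministic construction order; voxels left
unreachable from either terminal are assigned to background, which makes the
`beta = 0` limit implement the *strict* `p > 0.5` threshold.

## The phantom generator

Real ssTEM ground truth at desk scale does not exist, so the package
generates phantoms that emulate the *appearance statistics the pipeline
actually uses*, not EM physics:

* **Synapses** are dark (gray 0.20 on a 0.62 background) curved sheets,
  major extent 200–800 nm, thickness 50 nm, with vesicle-like dark speckle
  (radius 18–25 nm, offset 50–140 nm) clustered on one side. Orientation:
  80% steep sheets (normal within 30 degrees of the cutting plane) and 20%
  tilted at a low angle to the plane (normal elevation 55–75 degrees) — the
  orientation class that is genuinely hard at 45 nm slice thickness.
* **Distractors** share the darkness but not the sheet+speckle conjunction:
  thin membranes (25 nm, labeled as the membrane class), mitochondrion-like
  textured blobs with darker rims, and — crucially — *membrane appositions*:
  sheets at synapse-like thickness (42–55 nm) with no vesicles, which are
  never offered as training labels. These are the phantom's analogue of the
  dominant false-positive sources in tissue (membrane appositions, myelin,
  organelle boundaries); they make the first stage over-detect, so the
  object stage has genuine negatives to learn from and something real to
  fix. Small dark clutter specks are scattered through the background so
  that per-voxel context alone does not give the answer away.
* Placement keeps a 70 nm minimum clearance between objects (so truth masks
  stay disjoint and components separable); all randomness derives from one
  seed, and the same seed reproduces the volume bit for bit.

The default study volume is 32 x 384 x 384 voxels (1.44 x 1.73 x 1.73 um)
with 20 synapses. What passing phantom tests shows is that the pipeline
mechanics — feature discriminability, detection bookkeeping, exact
segmentation, the precision/recall trade — work as designed; it does not
show robustness to section artifacts (rips, folds, contrast drift, missing
slices), staining variation, or true biological texture, none of which the
phantom attempts to model.

## Training protocol on phantoms

`train_phantom_classifiers()` reproduces the two-stage training workflow on
phantom blocks. The pixel stage is trained on 400 sparse labels per class
from the first block — the point where, on the phantom, further labels keep
lowering the out-of-bag error only slowly while the detection output is
already stable (the analogue of labeling until the OOB error stops
improving). The object stage pools, over three blocks, the segmented
candidates labeled against truth plus each block's annotated synapse masks
(positives) and distractor masks (negatives) — a bit over 200 examples with
balanced classes. Using extra blocks for the object stage matters: the
decisive confusions (a membrane apposition that happens to lie near a
vesicle cloud) are rare per block, and the object forest only learns to
reject them when training has seen a few. This mirrors the original
workflow, where the several hundred object labels came from dedicated
training blocks, at roughly scaled-down counts.

## Blockwise processing

Synapses are small and sparse, so the volume can be processed in lateral
blocks with a halo. The halo (500 nm, like the box enlargement) must cover
both the filter context (the largest kernel reach is about 30 upsampled
pixels, 135 nm) and half the extent of the largest expected object; with
these margins a voxel owned by a block sees exactly the data a whole-volume
run would give it, and per-block probabilities are bitwise identical to
global ones. Detection then runs per block on the block+halo crop, each
component is owned by the block containing its centroid (this deduplicates
objects straddling block boundaries), and segmentation reads from the
stitched probability map. Objects reaching farther than the halo from their
centroid are the documented failure mode of halo'd blockwise processing; at
the phantom's object sizes (<= 800 nm extent, so <= 400 nm reach < 500 nm
halo) output equality with the whole-volume run is exact. Blocks are
lateral only: stacks are shallow relative to their lateral extent, and an
axial halo of 500 nm (11 slices each way) would cost more than it saves.

## Numerical and implementation choices

* **Filter kernels** are sampled Gaussians (radius 3 sigma) calibrated so
  that smoothing preserves constants and linear ramps exactly, first
  derivatives reproduce a unit ramp's slope exactly, and second derivatives
  are exact on quadratics. Boundaries are handled by half-sample
  reflection — the natural choice when blocks must behave like crops of a
  larger volume.
* **Eigenvalues** of the 3 x 3 Hessian/structure tensor use the closed-form
  trigonometric method, sorted descending; structure-tensor eigenvalues are
  clamped nonnegative only by the test tolerance, not by fiat.
* **Prediction at native slices.** Probabilities are conceptually predicted
  on the upsampled grid and subsampled back; because prediction is
  voxelwise, the pipeline evaluates the forest only on the slices that
  survive, which is identical output at half the cost. The full
  predict-then-`downsample_z()` path remains available through the public
  API.
* **Forest evaluation.** Voxelwise prediction uses a flattened export of
  the trained ranger trees evaluated in C++; a test asserts bit-identical
  agreement with `predict.ranger`.
* **Degenerate object statistics** (constant or too-small regions) yield
  zeros with a warning rather than errors, so candidate feature rows stay
  aligned with the candidate list.
* **LBP convention:** neighbor >= center, bilinear interpolation at the
  four diagonal sampling points, rotation-invariant uniform binning
  (bins = number of ones for patterns with <= 2 circular transitions, one
  bin for the rest). On constant regions all mass falls in the all-ones
  bin.
* **Skewness/kurtosis** are central-moment ratios (`m3/m2^1.5`,
  non-excess `m4/m2^2`); variance is the unbiased sample variance. The
  accumulators merge across sub-blocks exactly (pairwise update formulas),
  which is what makes blockwise feature computation equal whole-volume
  computation to 1e-9.
* **Matching for evaluation** is greedy one-to-one by increasing
  anisotropic distance with a 250 nm tolerance — half the 500 nm extent
  prior; the original validation re-examined errors manually, which an
  automated test cannot do.
* **Error-rate normalization:** both the false-negative and false-positive
  fractions are divided by the ground-truth count, matching the convention
  in which 16 false positives against 238 synapses is reported as 7%.

## Problem sizes used by the test suite

Unit tests run on toy grids (tens of voxels per side). The end-to-end
checks use the default 384 x 384 x 32 phantom: classifiers are trained on
an independent phantom (seed 2, 200 labels per class) and evaluated on the
default phantom (seed 1), and the blockwise check uses a 2 x 2 grid of
192 x 192 blocks on the same volume. These sizes keep a full suite run in
the tens of minutes on a single core while leaving every stage's behavior
observable at realistic anisotropy.

## Known limitations

* The phantom's intensity model is piecewise-constant plus Gaussian noise;
  real EM texture is far richer, and per-voxel classification is
  correspondingly harder on tissue.
* Section artifacts (rips, folds, missing slices) are not modeled and not
  handled; on real stacks they must be detected and masked upstream.
* `skeleton_size()` underestimates synapses lying nearly parallel to the
  cutting plane, by construction of the per-slice medial-axis estimate.
* The matching tolerance and the apposition/clutter density in the phantom
  are package choices; they shape the measured recall/precision and should
  be re-examined before quoting numbers for any real dataset.
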