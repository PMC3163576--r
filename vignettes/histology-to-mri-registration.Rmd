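---
title: "Relating 3D tumor histology to in vivo MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating 3D tumor histology to in vivo MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Histology is the reference standard for characterizing tumor tissue, but it
is acquired destructively: the specimen is excised, fixed in formalin,
embedded in paraffin, cut into micrometer-thin sections and stained. Each of
these steps deforms the tissue, and the sections themselves are only sparse
2D samples of a 3D object. To learn what an in vivo MR image actually shows
— which signal intensities correspond to viable, necrotic or hemorrhagic
tissue — every histology section must be placed back, in 3D, at the position
in the living tumor it came from.

`histomri` implements a complete chain for this spatial correspondence
problem, built around three ideas:

1. **An intermediate ex vivo MRI** of the fixed specimen. The gap between a
   stack of stained sections and an in vivo scan is too wide to bridge in
   one step; the ex vivo image shares geometry with the histology (it is the
   same fixed specimen) and modality with the in vivo scan.
2. **A reference cutting plane**, cut through the fixed tumor along its
   longest axis, perpendicular to its subcutaneous face. Sections are cut
   from this plane onwards, the ex vivo image contains it as an exposed flat
   face, and its orientation is known in the in vivo frame. All three 3D
   images are therefore anchored at one physical plane, which removes the
   out-of-plane pose ambiguity before any intensity-driven optimization.
3. **Registrations of gradually increasing freedom** — rigid, then affine
   (with isotropic scaling for the fixation step), then a free-form cubic
   B-spline — so that pose, global volume change and residual elastic
   deformation are each absorbed by the stage equipped to model them.

The pipeline has four named procedures:

* `stack_sections()` ("stacking"): serial sections are rigidly aligned
  slice-to-slice on their red channel and stacked at the physical
  inter-section interval (80 µm by default) into a 3D color volume.
* `stack2ex()`: the histology stack (moving) is registered to the ex vivo
  MRI (fixed) with the three-step strategy, initialized by the shared
  reference plane and in-plane centers of mass.
* `ex2in()`: the ex vivo MRI (moving) is registered to the in vivo MRI
  (fixed), after the in vivo volume has been realigned so the reference
  plane is its first slice. The middle stage is a 7-DOF similarity — rigid
  plus isotropic scale — because the dominant effect of fixation is a
  near-uniform shrinkage.
* `stack2in()`: the two stage transforms are concatenated automatically and
  the color stack is warped onto the in vivo grid.

All transforms use the pull-back convention: a registration result maps
fixed-image world points into the moving image's frame, so warping the
moving image is a direct resampling without hole filling. Under this
convention the pull-back of each stage is also the *physical* map of the
corresponding processing step (in vivo to ex vivo for fixation; ex vivo to
section plane for cutting), which is why `global_volume_change()` reports
`100 * (det - 1)` of the stage's linear pull-back: about −13% for fixation
shrinkage and about +2% for sectioning expansion, with local, per-VOI
changes available through `voi_volume_changes()`.

## The registration engine

Every stage is driven by the same four-component engine: a transform model,
a similarity metric, an interpolator and an optimizer.

**Metric.** Inter-modality stages (histology vs MRI, and the two MRI
contrasts) use mutual information from a joint histogram with 32 fixed and
32 moving bins and linear (partial-volume) binning; the histogram size
adapts downward (to a minimum of 8 bins) when a masked coarse level offers
too few samples for a stable 32x32 histogram. The mono-modal 2D stacking
uses normalized correlation, which is invariant to the staining-intensity
drift between neighboring slides. Out-of-domain samples contribute the
configurable fill value rather than being dropped, so the optimizer cannot
improve the metric by pushing samples out of the overlap region — without
this, a contracting transform can "win" by expelling the ambiguous boundary
zone, which visibly biases the recovered scale.

**Sampling and masks.** The metric is evaluated on the fixed-image voxels
inside a registration mask — the tumor, dilated by three voxels. The
dilation is deliberate: a mask cut exactly at the tumor boundary gives a
contracting transform a free pass around the boundary transition, and the
recovered fixation shrinkage then overshoots by several percentage points.
Pyramid levels whose masked sample count falls below 1000 are skipped; the
reference-plane initialization already supplies the coarse alignment such
levels would provide, and a 32x32 joint histogram estimated from a few
hundred samples is degenerate enough to create false optima.

**Optimizer.** Each level runs adaptive stochastic gradient descent: 2048
random masked samples per iteration, analytic gradients (the exact gradient
of the trilinear interpolant, chained through the transform Jacobian), and
a decaying step `a / (A + k)^0.602` with `A = 50` and the gain auto-scaled
from an initial gradient probe so the first step moves points about one
voxel. 500 iterations per level, 3 levels with downsampling factors
(4, 2, 1) and smoothing widths (2, 1, 0) voxels. At the finest level a
deterministic refinement follows: BFGS for the low-DOF models and L-BFGS-B
for the B-spline coefficients, on the full masked sample set, started from
both the stochastic endpoint and the stage initialization (whichever
full-sample optimum is better wins). The refinement is what pins the
similarity scale to a fraction of a percent and removes the stochastic
noise floor from the deformation coefficients; the dual start recovers the
occasional run in which the stochastic search fails to leave the
initialization's basin, and the pipeline additionally restarts a stage from
a shifted random substream when it fails to improve the full-sample metric.
A stage that still ends worse than its initialization returns the
initialization unchanged. With a fixed seed every run is bit-reproducible.

**Interpolation.** Nearest, trilinear and interpolating cubic B-spline
(with the standard recursive prefilter) schemes are provided. Intensities
are warped with linear interpolation; masks always with nearest-neighbor.
The in vivo realignment onto the reference plane uses the cubic scheme by
default: the realigned volume becomes the fixed image of `ex2in`, and the
resolution loss of linear resampling on an oblique grid — a loss the native
moving image does not share — measurably biases the recovered scale.

**2D stacking.** Adjacent-section alignment is deterministic (Nelder-Mead
plus a BFGS polish on the full-overlap correlation cost; only 3 DOF) and
runs in two passes: a whole-image fit for capture range, then a refinement
restricted to the eroded tissue interior. The split exists because adjacent
sections differ not only by mounting jitter but by the slow evolution of
the specimen outline — cross-sections grow and shrink — and that boundary
flow biases a whole-image rigid fit; the shared interior structure does not
carry it. Alignment to the already-aligned predecessor is realized by
registering raw adjacent pairs and concatenating the rigid transforms
analytically, so no interpolation error accumulates along the chain. A
section whose pairwise correlation stays below magnitude 0.2 is flagged,
logged, and given the identity transform.

## Quantitative evaluation

* `landmark_rms()` — root-mean-squared Euclidean distance between
  corresponding named landmark points, optionally after mapping one set
  through a transform; `interobserver_rms()` is the same quantity between
  two observers' annotations of one image.
* `stagewise_landmark_rms()` — the per-step accuracy table: the initial
  level is the correspondence the reference plane provides by itself
  (`plane_identification()`, no optimization), followed by the rigid,
  affine/similarity and elastic levels of the concatenated chain.
* `angulation_report()` — the out-of-plane angulation of a stage's rigid
  rotation: the angle between the reference-plane normal and its image
  under the rotation. It is exactly zero for a pure in-plane rotation and
  measures the residual reference-plane positioning error. Reported in
  degrees.
* `global_volume_change()` and `volume_change_percent()` — the Jacobian
  (determinant) form and the voxel-counting form
  `100 * (V_R - V_O) / V_O` of the volume change; the two agree on
  affinely warped masks up to voxelization.
* `estimate_pdf()` and `interquartile_segment()` — the MRI
  characterization step: the intensity probability density of a
  histologically confirmed VOI is a normalized 64-bin histogram; its
  quartiles are computed by linear interpolation of the empirical CDF of
  the masked intensities (R's default type-7 quantiles), and the closed
  interval [Q1, Q3] segments the image. With integer-quantized MRI
  intensities heavy ties make the quartiles land on observed values, so
  the closed interval can select more than half of a tightly distributed
  class — which is precisely what makes a well-separated class (necrosis)
  recoverable with a Dice coefficient above the 2/3 ceiling a continuous
  distribution would impose.

## The synthetic phantom

No real specimens ship with the package; a seeded generator
(`generate_phantom()`, or the three steps `generate_invivo()`,
`simulate_exvivo()`, `simulate_sections()`) produces the full study setup
with exact ground truth: an in vivo volume, its fixed-and-shrunk ex vivo
counterpart, a jittered RGB section stack, landmarks in every frame, VOI
masks, and every true transform.

The defaults are the study conditions:

* 64^3 voxels at 0.2 mm; tumor semi-axes (4.8, 3.8, 2.6) mm — roughly
  10 mm across, flatter along the cut normal, as a subcutaneous tumor
  growing parallel to the skin;
* compartment fractions 0.60 / 0.30 / 0.10
  (viable / necrotic / hemorrhagic) of the tumor volume, realized by
  construction to within a few percent (the necrotic radius is calibrated
  by bisection, pockets are added until their budget is met);
* T2*-like integer intensities: necrosis distinctly dark with a tight
  distribution; viable and hemorrhagic bright and strongly overlapping —
  the intensity structure that makes necrosis identifiable from MRI while
  hemorrhage is not;
* fixation: 13.2% programmed volume loss, a rigid misalignment of up to
  2 degrees of tilt, and a smooth random deformation (coefficient sd
  0.9 mm in-plane / 0.35 mm through-plane on a 4 mm control grid, plus a
  0.25 mm short-wavelength detail component that only the elastic stage
  can recover);
* sectioning: 30 sections at 80 µm from the reference plane, +1.9%
  in-plane expansion with a 12% cutting-direction compression
  (area-preserving), a common slide-placement offset of 1.5–3 mm, and
  per-slice rigid jitter up to 5 px / 3 degrees;
* H&E-like colors (viable dark purple, necrotic pale pink, hemorrhagic
  red-dominant, white slide background) with a shared texture field, built
  so that the red channel separates necrotic from viable tissue best — the
  property that motivates driving the stacking with the red channel.

Three generator choices deserve explanation, because they are what makes
the ground truth *recoverable* rather than merely defined:

* **The deformation is volume-neutralized and swirl-free over the tumor.**
  A single draw of a random coefficient field carries a net volume change
  of several percent and a coherent rotation of several degrees across the
  tumor. Real fixation shrinkage carries the volume change (which the
  phantom programs explicitly, enforced exactly by an isotropic
  correction), and strains tissue without coherently rotating it; the
  average rotation and translation of the field over the tumor region are
  therefore projected out exactly (cubic B-splines reproduce linear fields
  when coefficients equal the field at the control points). Without this,
  the linear registration stages legitimately absorb the spurious swirl
  into their pose and every "recovered vs programmed" comparison is
  confounded.
* **Compartment structure is extruded along the cut normal.** Necrotic
  core, hemorrhagic pockets and tissue texture are columnar: their in-plane
  appearance changes only slowly from section to section. Isotropic
  pockets appear and disappear abruptly between adjacent sections, and no
  slice-by-slice alignment can distinguish that through-plane feature
  turnover from mounting jitter — the recorded jitters would be defined
  but unrecoverable by any stacking algorithm. Real lobules, vessels and
  stromal strands do extend through neighboring sections; the phantom
  makes that coherence explicit.
* **The slide-placement offset dominates the initial error.** The tissue
  never sits centered on its slides; the common 1.5–3 mm offset makes the
  plane-only initial landmark RMS a few millimeters, matching the
  initial misalignment scale reported for plane-based alignment of real
  specimens, and gives the center-of-mass initialization and rigid stage
  something real to recover.

What passing tests on this phantom do **not** show: robustness to histology
artifacts (tears, folds, missing sections), to MRI bias fields or Rician
noise, to imperfect reference-plane knowledge beyond a few degrees, or to
tissue whose through-plane structure decorrelates faster than the section
interval. The phantom's noiseless variants (used for the jitter-recovery
and tilt-recovery studies) isolate single effects by switching every other
perturbation off.

## Numerical choices and degenerate inputs

* Joint histograms use linear (partial-volume) binning; MI is reported in
  bits and is exactly 1 for the canonical two-cluster toy case.
* Metric evaluations with fewer than 2 distinct intensities, zero variance,
  or an empty mask raise errors rather than returning silent zeros.
* Samples are taken at voxel nodes by default; `sample_jitter` draws
  them off-grid instead (an option for grid-artifact diagnosis).
* Euler angles use the intrinsic x-y-z convention; at gimbal lock the third
  angle is set to zero. The angle round-trip is exact away from lock.
* B-spline transforms are identity outside their control-grid support —
  safe extrapolation for points beyond the tumor or the sectioned slab.
* Transform files store parameters as hexadecimal floats, so write/read
  round trips are bit-lossless; composite files reference their component
  files in application order.
* Degenerate single-node image axes are handled explicitly in the
  interpolation kernels (zero stride), so single-slice "volumes" used for
  2D fixtures are safe.
* The volume-change sign convention is fixed as the physical change of the
  specimen at each processing step (fixation negative, sectioning
  positive); the determinant and voxel-counting routes agree by
  construction of the convention.

## Problem sizes

The shipped defaults are desk-scale: 64^3 MRI grids, 176^2 sections, 30
sections per stack. The full phantom pipeline (`run_all()`) takes on the
order of 1–2 minutes; single registration stages take seconds. All
geometric parameters scale through voxel spacing rather than grid size, so
the same code runs on acquisition-scale data (512^2 in-plane matrices,
3.64 µm histology pixels) without modification — only slower.

## Known limitations

* The sectioning covers a slab of the tumor; landmarks and VOI
  comparisons are meaningful only inside it, and the elastic stage of
  `stack2ex` is unconstrained (identity) beyond the slab.
* Sequential stacking cannot recover a global twist or bend of the
  specimen; that is exactly the degeneracy the ex vivo MRI resolves, and
  the reason the per-slice jitter test switches the deformation off.
* The B-spline stages carry no explicit regularization; their grid spacing
  (3.2 mm default) is the smoothness control, and a finer grid visibly
  overfits at this image resolution.
* Mutual information is estimated from a finite histogram; with very small
  masked regions the adaptive bin reduction trades sensitivity for
  stability.
* The qualitative visual grading of registrations and multi-stain
  extensions are out of scope; the quantitative evaluation (landmarks,
  angulation, volume change, PDFs) is the package's deliverable.
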