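---
title: "Multi-phased coarse-to-fine regression of craniofacial landmarks"
author: "craniomark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-phased coarse-to-fine regression of craniofacial landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Cephalometric analysis measures distances and angles between anatomical
landmarks of the skull.  Plotting the 16 bony landmarks handled by this
package (nasion, sella, menton, the anterior and posterior nasal spines,
the external occipital protuberance, the crista galli, point A, and the
bilateral gonion / porion / inferior-lateral orbital rim / supraorbital
incisura pairs) on a CT study by hand takes an expert substantial time, so
the package automates it as *coordinate regression*: networks map a voxel
volume directly to the numeric coordinates $(x, y, z)$ of the landmarks,
in pixel units of the axial frame (1 px = 500/512 mm at the standard CT
scale; z shares the pixel unit, so a 5 mm slice interval is a z step of
5.12 px).

A single network at full resolution would be prohibitively expensive: a
512 × 512 × 81 study has 21 million voxels.  The system therefore predicts
in three phases, the way one finds an address on progressively
larger-scale maps:

1. **Phase 1 (coarse).**  Every slice is compressed to 96 × 96 px,
   binarized at the bone threshold, and stacked bottom-up into a zero
   template of depth 81.  One network regresses all 48 coordinates
   (16 landmarks × 3) in the *original* 512-px frame.
2. **Phase 2 (refine).**  For each landmark, a 100 × 100 px full-depth,
   full-resolution binary crop is cut, centred on the phase-1 estimate
   $(x, y)$.  A per-landmark network predicts the local
   $(x_\mathrm{loc}, y_\mathrm{loc})$ inside the crop and the global $z$.
   The recorded crop origin remaps the local prediction to the global
   frame exactly: $x = x_0 + x_\mathrm{loc}$.
3. **Phase 3 (refine again).**  The same construction with a 50 × 50 px
   crop centred on the phase-2 estimate.

The full system is therefore 1 + 16 + 16 = 33 trained networks.
Localization error is reported per axis ($|\Delta x|, |\Delta y|,
|\Delta z|$) and as the 3D distance
$d_3 = \sqrt{\Delta x^2 + \Delta y^2 + \Delta z^2}$, pooled over all
case × landmark observations per phase, and phases are compared with the
Conover–Iman rank test after a Kruskal–Wallis step (Holm-adjusted,
two-sided).

## Training data and augmentation

Refinement networks are trained with *shift-grid augmentation*: around the
true landmark, crops are re-cut at every offset $(d_x, d_y)$ of a lattice
covering $[-s, +s)$ in steps of $\delta$ on both axes, and the regression
target moves opposite to the shift: the unshifted width-$w$ crop has
target $(w/2,\, w/2,\, z)$ and the shifted crop
$(w/2 - d_x,\, w/2 - d_y,\, z)$.  The lattice is half-open; with the
standard phase-2 grid ($s = 30$, $\delta = 10$) or phase-3 grid ($s = 15$,
$\delta = 5$) it has $6^2 = 36$ offsets, so 90 training cases yield
exactly 3240 examples per landmark.  An inclusive-both-ends lattice would
give $7^2 = 49$ offsets and a different dataset size; the half-open
convention is fixed throughout the package.

## Key parameters

| parameter | default (full scale) | meaning |
|---|---|---|
| `frame` | 512 px | in-plane width/height of a slice |
| `depth` | 81 | depth of the zero template (max slices per case) |
| `phase1_size` | 96 px | in-plane size of the compressed phase-1 input |
| `threshold` | 1100 | stored-value bone threshold (raw values, not HU) |
| `cross_value` / `cross_index` | 4000 / 255 | calibration-cross fiducial |
| `in_plane_mm` | 500/512 | pixel size, mm |
| `slice_mm` | 5 | slice interval, mm |
| `crop_width` | 100 / 50 px | phase-2 / phase-3 crop widths |
| `max_shift`, `shift_step` | ±30 step 10; ±15 step 5 | augmentation lattices |
| `batch_size` | 8 / 16 / 16 | per phase |
| `epochs` | 150 / 100 / 150 | per phase |
| `width_scale` | 1.0 | channel-count multiplier of the networks |

CT stored values are used raw, without DICOM rescale slope/intercept,
because the system only thresholds them (bone ≥ 1100) and the threshold is
defined on stored values.  Binarization uses the ≥ convention so the
threshold value itself counts as bone.  Compression is area-style (box)
resampling of raw intensities followed by binarization, in that order.
The calibration cross — every pixel of row 255 and column 255 of the most
caudal slice set to 4000 — is retained in network inputs by default
(`apply_cross`), since it is part of the files the networks see; a config
flag disables it.

## The network

All 33 regressors share one architecture: a 50-layer 3D residual network
(stem 7³ convolution, 3-4-6-3 bottleneck blocks, batch normalization,
ReLU) ending in a *linear* head — coordinate regression, not
classification.  Two head-adjacent choices matter for sample efficiency
and are this package's own design:

* **Flatten head.**  The final feature map is flattened into the linear
  layer rather than globally average-pooled.  Average pooling discards
  spatial layout, which is exactly the signal a coordinate regressor
  needs; flattening preserves it linearly.
* **Adaptive downsampling.**  Stages 2–4 downsample only while the
  feature map is at least 4 voxels on every axis, so small desk-scale
  inputs retain a spatial map at the head instead of collapsing to 1³.
* **Target centring.**  Networks regress residuals around the
  training-set mean target (the centre is stored with the weights and
  added back at inference), so the linear head starts from the cohort
  mean rather than from zero.

Training minimizes mean squared error over the coordinate vector with
mini-batch Adam (step size `lr`, default 10⁻³; β₁ = 0.9, β₂ = 0.999).
The loss is the canonical choice for a linear-head regressor; no
validation split or early stopping is used.  Weight initialization, batch
shuffling and the phantom cohort all derive from explicit seeds, so
training and inference are bit-reproducible.  Convolution is implemented
as `vol2col` + GEMM in C++ (with a reshape fast path for 1³ pointwise
convolutions); gradients of every layer are verified against finite
differences in the test suite.

## The skull phantom

Real head-CT cohorts with expert landmark annotations cannot ship with a
package, so the phantom module generates synthetic cases with *exact*
ground truth.  Each case is an ellipsoidal vault shell (uniform-intensity
bone band), soft-tissue interior, a half-torus mandibular arch whose ends
(the gonia) connect to the shell (at the poria) through two rami, and a
small bone knob at each of the 16 catalog positions, giving every
landmark a distinct local shape cue.  Geometry is drawn per case from a
stream seeded by `(seed, case_index)`:

* head-centre jitter with σ = (1, 3, 1) px at the 96-px reference width —
  the y scatter is three times the x scatter, emulating how heads are
  centred in x but scattered in y on real axial series;
* ellipsoid radii uniform in fixed fractional ranges of the grid;
* independent sub-pixel perturbation (σ = 0.4 px) of each bilateral
  landmark, so left/right pairs mirror only approximately;
* per-voxel uniform stored values: bone in [1500, 2500], soft tissue in
  [100, 800], straddling the 1100 threshold.

All lengths are fractions of the grid, so scaling the grid scales the
ground truth exactly.  Slices are rendered as *slabs*: each slice samples
its geometry over the full z step, emulating the partial-volume averaging
of thick CT slices and keeping thin oblique structures connected across
the coarse z grid.

What the phantom deliberately does not model: real skull anatomy and
shape variation, pathology, CT physics (noise spectra, beam hardening,
metal artifacts), and annotation ambiguity.  Passing the phantom
benchmark therefore demonstrates that the *pipeline machinery* — data
preparation, augmentation, window bookkeeping, training, staged inference
and evaluation — works end to end and that refinement improves on coarse
prediction under controlled conditions; it does not certify clinical
accuracy on patient data.

## Desk scale

The full-scale configuration would need days of GPU time.  The `"desk"`
configuration runs the identical pipeline at sizes a single CPU handles
in minutes, derived from the full-scale geometry by the frame ratio
96/512 = 0.1875: 96 × 96 × 24 volumes (z step 4 px), phase-1 input 18 px,
crop widths 18 and 10 px, shift lattices ±6 step 3 and ±2 step 1 (the
phase-3 lattice stays within the crop half-width minus the marker radius,
as the full-scale shift ranges track the previous phase's error scale),
`width_scale` 0.0625, batch sizes 8/16/16, epochs 15/6/10.  The benchmark
in `run_desk_benchmark()` trains all 33 networks on 20 phantom cases and
evaluates on 10 held-out cases; the acceptance suite asserts that the
pooled mean $d_3$ decreases strictly from phase 1 to phase 3 and that the
phase-1 vs phase-3 Conover comparison is significant.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based, continuous px; a slice is `pixels[x+1, y+1]`
  with x the image column, matching DICOM pixel-stream order.
* Crop origins are `round(center) - width/2` (banker's rounding, R's
  `round`), so window placement and local↔global remapping are exact in
  integer arithmetic.
* Crops falling partly or wholly outside the frame are zero-padded, never
  errors: phase-1 estimates can legitimately push refinement windows past
  the borders.
* Slices are ordered by the physical slice-position tag (most caudal
  first), with instance number as tie-break; file names are ignored.
* `compare_groups()` returns p = 1 with a warning when all observations
  are tied (the test statistic is undefined), and uses Holm adjustment —
  conservative and order-free among the standard choices for this
  post-hoc test.
* Dataset serialization uses R's native format behind
  `write_dataset()`/`read_dataset()`; no HDF5 dependency.

## Known limitations

* 5 mm (desk: scaled) slice intervals only; thin-slice studies would need
  resampling that is out of scope.
* The refinement z prediction is global and never moves the crop window;
  crops always span the full depth.
* Full-scale training (90 cases, `width_scale` 1, 150/100/150 epochs) is
  supported by the same code paths but is not exercised by the tests.
* The Conover implementation assumes pooled independent observations per
  group; repeated-measures structure (landmarks within cases) is ignored,
  as in the summary-table usage it reproduces.
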