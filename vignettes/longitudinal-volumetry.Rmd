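---
title: "Measuring longitudinal structure volume change with meshes and Jacobians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring longitudinal structure volume change with meshes and Jacobians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longivol)
```

## The measurement problem

Neurodegenerative disease, and possibly cranial irradiation, shrink the
hippocampus by a few percent per year, while the volume errors of independent
per-timepoint segmentations are of the same order or larger.  `longivol`
implements the registration-agnostic alternative: segment the structure once
at baseline, and let a non-linear registration's deformation field carry that
single segmentation to the follow-up scan.  The package deliberately consumes
the *outputs* of registration (dense displacement fields in NIfTI) rather
than wrapping any particular registration tool, so Elastix, NiftyReg, ANTs,
MIRTK or anything else that can export a dense field can feed it.

Volume is carried by a triangle mesh.  The baseline binary segmentation is
converted to a closed surface with marching cubes; transforms are applied to
the mesh vertices directly, never by resampling a label image, so no
interpolation error accumulates across time points.  Volumes are the sum of
signed tetrahedra spanned by the origin and each triangle — exact for a
closed, consistently oriented surface and translation-invariant by the
divergence theorem.  The atrophy measure is the percentage volume change

$$\mathrm{PVC} = \frac{V_{FU} - V_{BL}}{V_{BL}} \times 100,$$

negative for shrinkage.

Every mesh measurement has an independent cross-check: the Jacobian
determinant $\det(I + \partial u/\partial x)$ of the field is the local
volume-scaling factor, and summing it over the baseline mask times the voxel
volume gives a second, mesh-free estimate of the follow-up volume.
`measure_volume_change()` always reports both routes and their difference.

## Marching cubes variant

No isosurface extractor was available as a reusable component in this
toolchain, so the package implements one natively (in C++).  Instead of the
classic 256-entry triangle lookup table — whose complementary cases are not
mutually consistent and can crack the surface on binary data — each cell's
patch is assembled from marching-squares segments traced on its six faces.
Ambiguous faces (foreground on one diagonal) are resolved with the
*foreground-connected* rule; since both cells sharing a face see the same
four corner values, both generate the same segments and the mesh is
watertight and consistently oriented by construction.  Patch loops with more
than three vertices (the saddle configurations) are fanned from their
centroid.  Every returned surface satisfies the closed-2-manifold check in
`mesh_is_closed()`, which `mesh_volume()` enforces before integrating.

For binary masks the iso level is 0.5, the unbiased midpoint, and no
smoothing or decimation is applied.  A single foreground voxel yields the
octahedron $|x|+|y|+|z| \le 1/2$ of volume exactly $1/6$ mm³; a digitized
$12 \times 8 \times 6$ mm ellipsoid at 1 mm spacing is within 1% of
$\tfrac{4}{3}\pi \cdot 576 \approx 2412.7$ mm³, converging as spacing
shrinks.  Foreground touching the grid boundary is padded with one
background layer (logged), so surfaces are never clipped open.

## Deformation fields and numerical choices

Fields are dense per-voxel world-mm displacements with a mandatory direction
tag (`baseline_to_followup` warps baseline meshes).  The on-disk dialect is
a 5-D `X×Y×Z×1×3` NIfTI with vector intent, with a fallback reader for plain
4-D `X×Y×Z×3` images.

* **Sampling.**  Mesh vertices sample the field by component-wise trilinear
  interpolation in voxel space; trilinear sampling is exact for constant and
  linear fields, which the tests exploit.  Points outside the field's
  bounding box receive zero displacement with a logged count; more than 1%
  of a mesh outside the domain is an error rather than a silent freeze.
* **Derivatives.**  Jacobians use central differences in world units, with
  second-order one-sided stencils at grid edges, so affine fields are
  reproduced exactly everywhere including the boundary slices.  Rotated
  voxel-to-world affines are supported by mapping index-space gradients
  through the affine's 3×3 block; sheared affines are rejected.
* **Non-positive determinants** (folding) are counted, logged, and carried
  on the result rather than silently clamped.
* **Orientation.**  A world affine with negative determinant flips mesh
  orientation; extraction re-orients so outward-positive volume is
  preserved.  A mesh that still integrates negative raises a warning and
  reports the magnitude, because downstream PVC needs positive volumes.

## What the synthetic generators emulate

The raw data behind the reference numbers are access-controlled MRI scans,
so the package ships generators for every input the pipeline needs.

* **Shapes** (`make_segmentation()`): digitized ellipsoids (default
  semi-axes 12, 8, 6 mm ≈ 2400 mm³, inside the 2000–4000 mm³ range commonly
  reported for a human hippocampus — a literature convention, not a measured
  reference) and smoothly perturbed blobs (low-order angular modulation of
  the radius, ≤ 8% by default).  The shape centre is placed midway between
  voxel centres: centring on a voxel biases the digitized volume low by
  about 2% at 1 mm for these sizes, which would consume the entire analytic
  tolerance before any meshing error is measured.
* **Fields** (`make_field()`): zero, translation and uniform scaling (exact
  ground truth; a uniform factor of 0.983 per axis gives
  $\mathrm{PVC} = (0.983^3-1)\cdot 100 \approx -5.0\%$, a plausible
  two-year hippocampal loss), a radial Gaussian contraction
  $u(x) = -k\,(x-c)\,e^{-r^2/2\sigma^2}$ (smooth, localised, invertible for
  the documented $k$ bounds), and Gaussian-smoothed random fields emulating
  the incidental spatial structure of real registration output.  Where no
  closed form exists, ground truth is Jacobian integration on a grid at a
  quarter of the working spacing.  For the random fields this oracle is
  defined on the trilinear interpolant and carries a small resolution bias
  relative to coarse-grid estimates, so ground-truth recovery is asserted
  only for the deterministic kinds; the random kinds are covered by the
  route-equivalence property instead.
* **Cohorts** (`simulate_cohort()`): subjects in CTRL/MCI/AD groups (default
  20/40/20) with A/B back-to-back replicates and left/right sides.  Group
  PVC distributions are parameterised by the published per-method group
  means and SDs bundled in `method_reference_stats()`.  The variance is
  partitioned as $\sigma^2_{\text{true}} = \sigma^2_g - \sigma^2_\epsilon$
  between subjects and replicates, so the pooled group SD matches the
  published value *and* the A-vs-B reproducibility distance has the closed
  form $\sqrt{2}\,\sigma_\epsilon$ simultaneously — the simplest generative
  model consistent with both published summaries.  Replicate noise defaults
  to $\sigma_\epsilon = 1.5\%$ (mid-range of the published per-method
  reproducibility distances); sides split antithetically
  ($L = v + \delta$, $R = v - \delta$, $\sigma_\delta = 0.5\%$, a free knob)
  so left/right averaging is exercised without distorting subject-level
  statistics.  Optional outlier injection places records beyond ±25% to
  exercise the exclusion rule.

What passing tests on these generators do *not* show: real deformation
fields have anatomy-dependent spatial structure, real segmentations have
correlated boundary errors, and real group distributions are not exactly
Gaussian.  The synthetic results validate the measurement and statistics
machinery, not any specific registration tool.

## The statistics layer

Records are flagged, never deleted: `apply_exclusion()` marks $|PVC| > 25$
(strict inequality) as implausible, and every analysis masks flagged rows,
keeping the table auditable.  Left and right PVCs are averaged per
subject-scan; a missing or flagged side drops that subject-scan rather than
imputing.

* **Reproducibility and agreement** use the same statistic, the RMS
  difference $D = \sqrt{\tfrac1n \sum_i (x_i - y_i)^2}$, between A/B
  replicates or between methods; `distance_matrix()` assembles the
  symmetric between-method matrix.
* **Group ANOVA**: the default `pooled` mode runs a one-way ANOVA on the
  pooled A and B observations, reproducing the error-df pattern of the
  reference analysis (F(2, 157) for 160 observations in 3 groups) — the
  printed degrees of freedom are consistent with pooling replicates, not
  with a classical subject-level repeated-measures error term, which is why
  this mode is the default reproduction mode.  The `mixed` mode is the
  principled alternative: group × scan with subject as the between-unit
  error stratum.  Both report Tukey HSD adjusted pairwise contrasts.
* **Power**: Cohen's $d$ uses the *unweighted* pooled SD
  $\sqrt{(\sigma_1^2+\sigma_2^2)/2}$ — the only pooling that reproduces the
  published effect sizes from the published group summaries (df-weighted
  pooling does not, e.g. 0.36 instead of the printed 0.37 for one
  contrast) — and the required per-group sample size is
  $N = 2 (z_{\alpha/2} + z_{1-\beta})^2 / d^2$ rounded to the *nearest*
  integer, not the ceiling: ceiling would contradict two of the published
  values (computed 11.41 printed as 11, computed 29.03 printed as 29).

Two published effect sizes are not recoverable from the published group
summaries at two decimals (they round to one unit away); the package
reproduces what the printed inputs imply and the test suite documents the
two entries explicitly.  Published CTRL-vs-MCI sample sizes are matched to
±5: they were evidently computed from unrounded per-subject data.

## Problem sizes and tolerances in the test suite

The suite runs entirely on generated data: ellipsoids and blobs of 19–41
voxels per axis at 2, 1 and 0.5 mm spacing, twelve (shape, smooth field)
route-equivalence fixtures at 1 mm with half-spacing refinements of the
deterministic contractions, and 2 × 50 simulated cohorts of 80 subjects for
parameter recovery.  Route agreement is asserted at 0.1 percentage points
(the sub-voxel mismatch between a mask and its iso-surface bounds what is
achievable; the observed differences are an order of magnitude smaller),
analytic ellipsoid volumetry at 2%, affine determinant ratios at $10^{-9}$
relative, and Monte-Carlo quantities at three standard errors of their
closed-form sampling distributions.

## Known limitations

* Registration itself, image preprocessing, and segmentation of images are
  out of scope by design; the package starts at labels and fields.
* The Jacobian route requires the field and segmentation on the same grid;
  fields are resampled only inside the synthetic ground-truth oracle.
* Sheared (non-orthogonal) voxel-to-world affines are rejected rather than
  modelled.
* The overlap statistic is intersection-over-union; mask pairs must share a
  grid.
* Meshes are used as extracted: no decimation, smoothing or remeshing, so
  vertex counts grow with surface area at fine spacings.
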