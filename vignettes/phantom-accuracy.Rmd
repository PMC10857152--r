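---
title: "Evaluating navigation accuracy on synthetic head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating navigation accuracy on synthetic head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomreg)
```

## The problem

Mixed-reality neuronavigation overlays holographic anatomy, derived from a
preoperative scan, on the physical patient (or a 3D-printed head phantom).
Its usefulness stands or falls with spatial accuracy: how far is a
holographic structure from its physical counterpart after registration?
This package implements the standard desk-scale audit of that question.
Accuracy is probed at scalp fiducial markers (landmark level) and at the
lesion (target level), and summarized over a cohort of phantom cases with
nonparametric statistics. Because phantom measurement data are rarely
depositable, a synthetic generator reproduces the statistical structure of
such a cohort so the entire analysis is testable end to end.

## Coordinate frames

Medical images live in the reference image coordinate system (RICS): RAS
axes (right–anterior–superior positive), millimetres, right-handed.
Holographic platforms typically work in centimetres and in a left-handed
display frame, and the patient may be positioned supine, prone or lateral
relative to how they were scanned. The package models this with explicit
`frame_transform` objects:

* **FEM** (forward engineering matrix), RICS → IVCS: a rotation about the
  superior (cranio-caudal) axis — 0° supine, 180° prone, ±90° lateral —
  composed with a uniform 0.1 scale (mm → cm), folded into one matrix.
* **HCM** (handedness conversion), IVCS → VCS: `diag(1, 1, −1, 1)`,
  negating the superior axis to enter the left-handed display frame.
* **REM** (reverse engineering matrix), IVCS → ACS: the exact matrix
  inverse of the FEM, bringing platform-reported coordinates back to the
  analysis frame, which is identified with RICS (RAS, mm).

Which lateral side rotates by +90° is a convention with no physical
ground truth; the package defaults to left-lateral = +90° and exposes the
choice (`lateral_sign`), so either convention can be matched. Frames and
units are tags checked on every application — a point set in the wrong
frame or unit is an error, never silently rescaled.

## Landmark metrics

Each case carries three ordered, label-matched point sets in RICS mm: the
ground-truth marker centroids `C`, the perceived virtual markers `V`, and
the perceived physical markers `P`. In the emulated measurement protocol
`V` is acquired before `P`, so the quality-control metric is measured
before any error can accumulate; the summary records this ordering.

* FLE`_i = V_i − C_i` — localization (probe/perception) error;
* TRE`_i = P_i − C_i` — virtual-to-physical accuracy after registration;
* FRE`_i = R*C_i + t* − P_i` — residual after the optimal rigid alignment;
* FN `= ‖T* − I‖_F` over all 16 entries of the homogeneous matrix.

The rigid fit is the classical closed form: demean both sets, SVD of the
cross-covariance, determinant sign correction so the solution is a proper
rotation (no scaling, no reflection) even when the unconstrained optimum
would reflect. Correspondence is strictly by label order — the sets are
indexed by marker, so no point matching or ICP is wanted. At least three
non-collinear points are required (a collinear set leaves the rotation
about its axis unidentifiable and is rejected); the simulated cases carry
6–7. Per-case summaries report mean ± sample SD (n − 1) of the magnitudes.

FN deliberately mixes dimensionless rotation residuals with millimetre
translation entries — that is its definition, and its value is dominated
by the translation for small rotations. `compute_fn(fit, decompose =
TRUE)` optionally separates the rotation-part and translation-part norms
for interpretation; the combined scalar remains the reported metric.

## Lesion metrics

The fitted `T*` is applied to the ground-truth lesion mask; the
transformed model is resampled back onto the ground-truth grid by inverse
mapping with nearest-neighbour interpolation so binary masks stay binary.
The price is up to one voxel of discretization error, which matters when
reading HD95 values close to the voxel spacing (1 mm by default).

* **DSC** compares voxel sets on a common grid; grid mismatch is an error,
  not an implicit resample.
* **HD95** extracts surface points as centres of boundary voxels
  (foreground voxels with at least one background 6-neighbour; the array
  border counts as background) and measures distances in physical mm.
  The default is the *directed* distance from each ground-truth surface
  point to the nearest transformed-model surface point, faithful to the
  metric's defining formula; a `symmetric` mode takes the maximum of both
  directions, matching common segmentation-comparison tools. "Maximum of
  the smallest 95%" is ambiguous at non-integer ranks, so two rules are
  offered: `"lower"` (default) takes the `floor(0.95 n)`-th order
  statistic — on a multiset of 95 distances at 1 mm and 5 at 10 mm it
  returns exactly 1 mm — while `"linear"` interpolates between order
  statistics (type-7 quantile) and would return 1.45 mm on that multiset.
  The lower rule is the default because it is the direct reading of the
  metric's definition.
* **Depth** is the minimum distance from the lesion centroid to the skin
  mesh (the tangent-sphere radius), using exact point-to-triangle
  distances: for each triangle the closest point is the in-plane
  projection when its barycentric coordinates are non-negative, otherwise
  a point on an edge (point-to-segment distance). Vertex-only distances
  overestimate on coarse meshes. Zero-area triangles fall back to edge
  distances; a mesh with only degenerate triangles is an error.
* **L2 norm** is the centroid's distance from the image origin, in cm.

## The synthetic phantom generator

`generate_case()` builds a case from four ingredients, all deterministic
functions of a seed:

* **Head**: a triangulated ellipsoid, semi-axes 80 × 95 × 85 mm (RAS) —
  adult-head half-widths. Any user-supplied mesh can replace it.
* **Fiducials**: 6–7 points on the anterior/superior part of the surface
  with a minimum pairwise separation of 25 mm, emulating scattered skin
  adhesive markers placed where a scanner laser can reach.
* **Lesions**: axis-aligned ellipsoids (volume drawn uniformly from
  8–38 cm³, the range of group means in the emulated cohort; mild shape
  jitter) on a 1 mm isotropic grid bounded around the lesion, strictly
  inside the head. Two-lesion cases are supported; the default 19-case
  cohort places them at cases 8 and 14 so that 19 cases carry 21 lesions.
* **Noise**: `V = C + ε`, `P = T_err(C) + ε'` with ε, ε' isotropic
  Gaussian per coordinate (SD `sigma_probe`), and `T_err` a small rigid
  misregistration — rotation about a uniformly random axis through the
  image origin with angle ~ N(0, `rot_sigma`°), translation ~ N(0,
  `trans_sigma`² I) mm.

The magnitude of an isotropic 3-D Gaussian displacement follows a Maxwell
distribution with mean `2σ√(2/π)`. The defaults are a calibration, chosen
once and not revisited: `sigma_probe = 1.2` mm makes the expected
per-marker FLE ≈ 1.91 mm, and `trans_sigma = 1.35` mm with
`rot_sigma = 0.8°` makes the expected per-marker TRE ≈ 3.0 mm — the scales
reported for head-phantom mixed-reality navigation. They are a statement
about the emulated measurement process, not a claim about any particular
device. Under this simple isotropic family the Frobenius norm of the
fitted transform averages ≈ 2.2–2.3, somewhat below the ≈ 3.4 reported in
the cohort that motivated the calibration: a single isotropic rigid error
family cannot match that FN and a TRE of 3.0 mm simultaneously, and the
TRE (the headline accuracy metric) was chosen as the calibration anchor.

Cohorts derive per-case seeds from the master seed by fixed arithmetic
(`(seed + 104729·i) mod (2³¹ − 1)`), so cases are independent and the
whole cohort is reproducible bit for bit.

What the generator does *not* emulate: realistic scalp geometry and
curvature-dependent registration error (the observation that flatter
regions register worse), marker segmentation error, anisotropic or
spatially correlated probe noise, and lesion shapes beyond smooth
ellipsoids. Passing tests therefore demonstrate the correctness of the
metrics and the pipeline under a known error model — not that any physical
system achieves these accuracies, and not that position-group differences
seen in real cohorts will reproduce here (in the synthetic cohort all
positions share one noise model, so position effects are null by
construction).

## Cohort statistics

Position comparisons use the Kruskal–Wallis test (supine vs prone vs
lateral, the two lateral sides pooled), with two-sided Mann–Whitney U post
hoc tests at a Bonferroni-adjusted threshold `α/k` (0.05/3 = 0.017 for
three pairs). The exact rank-sum distribution is used when the combined
sample is ≤ 20 without ties, the tie-corrected normal approximation
otherwise — group sizes in such cohorts (5–8) sit comfortably in the exact
regime unless metrics tie. Correlations are tie-corrected Spearman rank
correlations with two-sided p-values. Median splits assign ties to the
"≤ median" subgroup; a metric with no variation at all is reported as
p = 1 (no evidence of a difference) rather than NaN. Degenerate cohorts
(for example a zero-noise run, where every accuracy metric is constant)
propagate NA rows through the report rather than failing it.

## Numerical choices and problem sizes

Tolerances follow the quantity's conditioning: frame round trips and fit
identities are checked at 1e−9 to 1e−12; oracle comparisons against an
independent numerical optimizer at 1e−6 (the practical precision of a
numerically polished minimizer). The test suite sizes its simulations to
run in about a minute: 200 zero-noise seeds for exact misregistration
recovery, 10,000 draws for the Maxwell-mean check of simulated FLE (within
5%), a 21-lesion fixed-misregistration volume sweep for the volume–DSC
association, and 30–40 seed replicates for monotonicity properties. The
acceptance script regenerates the full 19-case cohort (≈ 12 s on one
core), dominated by the surface-distance computations for HD95, which are
chunked nearest-neighbour searches over boundary-voxel centres.

## Limitations

The rigid-error framework is the analysis's backbone and also its bound:
non-rigid effects (skin shift, display distortion) appear only as
unstructured probe noise. HD95 inherits one voxel of surface
discretization. The ellipsoid head makes depth and fiducial placement
smooth and well-conditioned; real scalp meshes are noisier and the
point-to-triangle distance is exact precisely to stay robust there. The
statistics layer reports p-values but no effect sizes or power — with
19 cases and 21 lesions such cohorts are descriptive, and the package
follows that practice.
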