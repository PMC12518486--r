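---
title: "Statistical shape modelling and distal-radius shape completion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modelling and distal-radius shape completion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radssm)
```

## The problem

Corrective osteotomy for a malunited distal radius is commonly planned in 3D
against the mirrored contralateral radius. When no healthy contralateral bone
is available — bilateral fracture, prior deformity — a *shape completion
model* can substitute: a statistical shape model (SSM) of healthy radii is
extended into a Gaussian-process (GP) regression that predicts the distal 12%
of the bone from the proximal 88% that the malunion left intact.

`radssm` implements that pipeline end to end: triangle-mesh handling,
anatomical coordinate frames, nonrigid correspondence, generalized Procrustes
analysis (GPA) and PCA model building, GP shape completion with hyperparameter
grid search, the standard SSM quality metrics, and the decomposition of the
prediction error into the clinical six degrees of freedom.

## The model

Each corresponded bone is a vector $x \in \mathbb{R}^{3n}$ of vertex
coordinates (mm) on a shared topology. The SSM is the linear-Gaussian model

$$x = \bar{x} + \sum_{k=1}^{K} c_k \sqrt{\lambda_k}\, b_k, \qquad
  c_k \sim \mathcal{N}(0, 1),$$

with mean $\bar{x}$, orthonormal principal components $b_k$ and eigenvalues
$\lambda_k$ of the sample covariance (divisor $n-1$, computed by SVD of the
centered data matrix). Components below $10^{-12}\lambda_1$ are discarded, so
$m$ shapes in generic position retain exactly $m-1$ components.

For completion, the SSM covariance is augmented with an isotropic Gaussian
kernel evaluated at the reference vertices,

$$k_{\mathrm{iso}}(x, x') =
  \mathrm{scale} \cdot \exp\!\left(-\lVert x - x' \rVert^2 / \sigma^2\right)
  \cdot I_3,$$

note the convention **without** the factor 2 in the denominator: $\sigma$ is
the distance at which correlation falls to $e^{-1}$. The kernel's leading
eigenfunctions are obtained by a Nyström approximation (exact low-rank form
$\hat{K} = K_{nm} K_{mm}^{-1} K_{mn}$ with farthest-point-sampled landmark
vertices) and the combined basis is re-orthonormalized, giving again a
low-rank GP.

Given observed positions $y$ at a subset of vertices, the posterior over
coefficients is ridge regression in the whitened basis
($Q = B\,\mathrm{diag}(\sqrt{\lambda})$ restricted to observed coordinates):

$$\alpha = (Q^\top Q + \tau I)^{-1} Q^\top (y - \bar{x}_{obs}), \qquad
  \mathrm{Cov}(\alpha) = \tau\,(Q^\top Q + \tau I)^{-1},$$

and the completed bone is $\bar{x} + Q_{\mathrm{full}}\,\alpha$.

**Units of the `noise` hyperparameter.** The published tuning grid uses noise
values 5–20 with no unit. This package treats the configured `noise` as the
ridge magnitude $\tau$ directly (a variance-like quantity, mm²); the
equivalent observation-noise SD is $\sqrt{\mathrm{noise}}$ mm. This
interpretation is recorded here as the package's choice, not asserted as the
original authors' intent.

## Correspondence

Dense correspondence is established by progressively-less-regularized
nonrigid ICP: per schedule step a low-rank GP deformation prior on the
reference (default $\sigma$ = 100, 60, 30 mm; amplitude 100 mm²; 60/120/240
basis fields; 20 iterations; observation noise 1 mm) alternates exact
closest-point assignment with GP regression of the residual deformation,
warm-starting each step from the previous one.

Two numerical choices matter and were made after the naive variants failed on
synthetic data:

* **Normal weighting.** A closest-point assignment carries information along
  the target surface normal only; treated as a full 3D observation it biases
  tangential motion towards zero and global modes (bending, lengthening) are
  under-recovered. Observations are therefore weighted by
  $P = n n^\top + w_t (I - n n^\top)$ with $w_t = 0.5$; tangential motion is
  left mostly to the smooth prior. With this weighting a 3 mm smooth bending
  field is recovered to < 0.1 mm RMS; without it the error is ~0.5 mm.
* **Reverse observations.** One-sided (reference → target) matching can never
  discover target regions the deformed reference does not yet cover — a bone
  20 mm longer than the reference was systematically truncated. Target
  vertices farther from the deformed reference than
  $\max(3 \times \mathrm{median}, 1\%\ \mathrm{bbox\ diagonal})$ therefore
  pull their nearest reference vertex towards them.

An outlier guard (drop assignments beyond `outlier_factor` × median distance)
is available for genuinely partial targets but is **off by default**: with
complete training surfaces it misclassifies genuine large deformations (length
variation) as outliers. Completion-time partial inputs do not use this path at
all (below).

Tangential components of deformation on featureless shaft regions are
fundamentally unidentifiable from geometry alone; the recovered field there is
the minimal-norm smooth extension, not the generator's ground truth. The
surface is matched regardless, which is what the downstream PCA consumes.

## Two-pass model building

Pass 1 corresponds all training meshes to an arbitrary downsampled reference,
aligns them by GPA and builds a PCA model. Pass 2 repeats correspondence, GPA
and PCA with the pass-1 mean as the reference, removing the reference bias.
Pass 2 warm-starts each mesh's registration from its pass-1 correspondence
(the pass-1 mean shares the reference topology), so it refines rather than
re-discovers the correspondence.

GPA here is rigid-only — **no scaling step**. Absolute size in mm is
clinically meaningful (lengthening is one of the evaluated errors), and
whether the original study normalized scale is not determinable; rigid-only is
this package's choice.

## Completion of a proximal fragment

`complete_shape()` (and the grid search) processes a proximal 88% fragment in
three stages:

1. **Rigid ICP** of the fragment onto the proximal region of the model mean
   (point-to-plane steps with a point-to-point fallback that keeps the
   objective monotone). A mean residual above 5 mm raises an alignment-failure
   error.
2. **Model-based correspondence**: iterating closest-point assignment from
   the current model estimate's proximal vertices onto the aligned fragment
   with a normal-weighted ridge regression on the model coefficients (60
   iterations; tangential weight annealed 0.5 → 0.1, internal ridge 1 → 0.1;
   pose re-estimated every other iteration). During the tolerant first half,
   fragment regions the current estimate does not yet cover (an input bone
   longer than the model mean) pull their nearest estimated vertex, exactly
   as in the nonrigid registration — without this the length coefficient is
   systematically underestimated. The annealing is part of the
   correspondence machinery, not of the completion regression; its endpoint
   is a set of observed positions for the proximal model vertices. A single
   closest-point pass without this iteration leaves ~1.5 mm RMS
   correspondence error, which propagates to several millimetres of distal
   prediction error.
3. **GP posterior** on the augmented model with the *configured* ridge
   (`noise`), yielding the completed bone, the posterior coefficient
   covariance and a per-vertex predictive SD. The prediction is returned in
   the fragment's original pose.

The hyperparameter grid search evaluates the full published grid (noise 5, 10,
15, 20 × sigma 50–300 × scale 5, 10, 15 = 72 triples), scoring each triple by
the mean one-sided distance of the completed mesh to the reference
(a distal-only scoring mode exists as an option). Correspondence per
validation mesh and augmentation per (sigma, scale) pair are shared across the
grid. Ties break towards smaller noise, then sigma, then scale.

## Clinical 6-DOF error

The predicted and reference distal segments (faces fully within the distal
fraction, 0.12 clinically, 0.5 in the comparison mode used by studies that
register the distal half) are rigidly registered — principal-axes
initialization with sign disambiguation, then ICP. Because both meshes share
the canonical anatomical frame, candidate initializations rotated more than
60° from the identity are discarded: this is the deterministic surrogate for
the planner's "manual adjustment", which would never spin a distal radius by a
half turn even when a grossly wrong prediction makes the flipped fit score
marginally better.

The transform is re-expressed about the centre of gravity of the reference
distal segment (surface-area-weighted centroid — cut segments are open
surfaces, so a volume centroid is undefined) and decomposed in intrinsic
X → Z → Y Euler order: radial inclination φx, volar tilt φz, axial rotation
φy, matching the clinical listing order. Signs: +X dorsal, +Y lengthening,
+Z radial. The 3D angle (axis-angle magnitude) and 3D distance (translation
norm) are convention-free; `dist_3d² = Δx² + Δy² + Δz²` holds exactly. Near
the Euler degeneracy (|φz| → 90°) values are still returned with a
`gimbal_warning` flag. Some sources label lengthening Δz; this package
follows the axis semantics of the anatomical frame (+Y long axis, so Δy is
lengthening) throughout.

## The synthetic population

No clinical CT data ship with the package, so every stage is exercised on a
synthetic population with known ground truth. The template is a closed,
tube-like surface (length 240 mm, shaft radius 8 mm, head bulge 11 mm, distal
flare 30 mm wide) with an azimuthally asymmetric, oval-triangular
cross-section — real radii are not surfaces of revolution, and without this
asymmetry axial rotation would be unobservable to registration. Landmarks
(head centre, distal ridge midpoint, notch-direction point) are exact vertex
positions.

Shapes are `template + Σ c_ik sd_k mode_k + ε` with standard-normal latents
and i.i.d. Gaussian vertex noise (default SD 0.3 mm, about half the
slice thickness of the CT protocols such meshes emulate). The six built-in
unit-RMS modes and their default SDs:

| mode | default SD | anchoring |
|---|---|---|
| lengthening | 7 mm | bone length SD ≈ 12 mm (the normalized field moves the tip 1.73 mm per unit) |
| bowing | 2.5 mm | moderate shaft curvature variation |
| volar tilt | 0.37 mm | ≈ 4° population SD of volar tilt |
| radial inclination | 0.26 mm | ≈ 3° population SD of radial inclination |
| distal width | 0.5 mm | ≈ 1.5 mm local width variation |
| head radius | 0.5 mm | ≈ 1.5 mm local head-size variation |

The rotational modes are linearized small-rotation fields of the distal
segment feathered over 5% of the length; `apply_distal_rotation()` applies an
*exact* feathered rotation instead, so 6-DOF recovery tests have closed-form
ground truth.

What the generator does **not** emulate: cortical/trabecular interior,
segmentation staircase artefacts, intra-articular geometry, and — most
importantly — the proximal–distal *correlation structure* of real anatomy.
The distal modes here are independent of the proximal shaft by construction,
which makes distal completion *harder* than on real bones in exactly the ways
the original clinical evaluation found mattered (length and distal surface).
Passing the self-consistency tests therefore validates the machinery, not the
clinical error magnitudes, which require real CT data.

## Problem sizes and numerical choices

* Default pipeline: 100 shapes at 2000 template/reference vertices, 8:1:1
  split, the 72-triple grid, 200 augmentation basis fields. This runs in
  roughly ten minutes on one CPU; the package's test suite exercises the same
  code paths at 500–1000 vertices and 12–30 shapes, which preserves every
  rank, limit and round-trip property at a fraction of the cost.
* Completion self-consistency is checked with `noise = 1` (ridge 1 mm²):
  the test observations are exact by construction, and the regression noise
  is chosen to match that condition, not tuned; the published optimum
  (noise 20) reflects real segmentation noise.
* Eigen-rank cutoffs: PCA at $10^{-12}\lambda_1$ (relative); Nyström at
  $10^{-8}$ of the leading singular value.
* STL welding is exact-coordinate (deterministic); binary PLY stores float32
  (sub-µm for coordinates < 1000 mm).
* Decimation is grid-based vertex clustering with the resolution chosen by
  bisection against the vertex budget — any method meeting the ≤ 1%
  bounding-box-diagonal deviation contract would do.
* Degenerate inputs error early: landmarks collinear with the long axis,
  empty distal segments, rank-deficient segment scatter, grids or splits
  without a seed.

## Known limitations

* Tangential correspondence on featureless shaft regions is conventional, not
  anatomical; vertex-wise field comparisons inherit that ambiguity.
* The Euler order (intrinsic X → Z → Y) is a declared convention; only the 3D
  angle is convention-free.
* Specificity's "use the test set to generate 10 new models" is ambiguous in
  the field; both readings (`mode = "sample"` vs `"reconstruct"`) are
  implemented and reported explicitly.
* The completion model assumes a linear-Gaussian shape distribution;
  heavy-tailed or multimodal anatomy (e.g. unresected deformity in the
  proximal fragment) violates it and is flagged only through the rigid-ICP
  residual guard.
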