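---
title: "Measuring bone, vasculature and osteolytic metastases in 3D: methods and design"
author: "osteovasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bone, vasculature and osteolytic metastases in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement definitions, the synthetic phantom
model, the numerical choices and the known limitations of `osteovasc`. It
states no empirical result beyond what the package's tests and the
acceptance script compute themselves.

## The measurement chain

The pipeline operates on four-class label volumes (background, bone,
contrast-filled vessel, metastasis) with voxel sizes in micrometres,
possibly anisotropic. The default phantom geometry uses 64³ voxels of
3.5 µm — the scale of synchrotron micro-CT studies of the mouse tibia —
but nothing in the code depends on that choice.

### Total volume (TV)

TV is defined as the volume inside the outer contour of the bone. An
"outer contour" is not a well-defined voxel operation, so it is realised
as a morphological closing of the bone mask with a Euclidean ball
(default radius: 10 voxel edges, exposed as `closing_radius_um`) followed
by 3D hole filling. Two boundary conventions matter here:

- The closing is evaluated on a padded grid and cropped back, so it is the
  true unbounded-domain Euclidean closing: a convex solid closes to
  itself, and the result is always a superset of the bone mask.
- Imaged specimens are cut perpendicular to the bone axis, leaving the
  cortical tube open at the stack faces. Hole filling therefore treats
  the axial (z) faces as sealed cut planes by default
  (`sealed_faces = "z"`): the border flood cannot enter the marrow canal
  through the cut, so the canal counts as interior, exactly as a
  practitioner outlining the bone contour would treat it. Per-slice 2D
  filling was rejected as orientation-dependent.

Compartment volumes are voxel counts times the physical voxel volume;
BV/TV, VV/TV and Me.V/TV divide by TV.

### Distances and VMI

All distances are exact Euclidean distances between voxel centres,
computed with the separable lower-envelope (squared-distance) transform,
which is exact — not an approximation — and handles anisotropic spacings.
Surface-to-surface distances were rejected as under-specified on a voxel
grid. VMI is the mean over vessel voxels of the distance to the nearest
metastasis voxel. When a sample has no metastases, VMI is returned as an
explicit undefined value (`NA` with a flag), never as a silent zero.

### Local thickness (V.Th)

Thickness follows the maximal-inscribed-sphere definition standard in
micro-CT bone morphometry: the thickness at a voxel is the diameter of
the largest sphere entirely inside the structure that contains the voxel.
Discretisation convention: the sphere centred at a voxel extends up to
(strictly below) the distance to the nearest *background voxel centre*,
while its reported radius subtracts half a voxel edge, because the
physical boundary lies halfway between the last foreground and the first
background centre. This convention recovers the diameters of voxelised
cylinders and spheres within one voxel (asserted in the tests for radii
of 3, 5 and 8 voxels) and gives an isolated voxel a thickness of exactly
one voxel diameter — the minimum representable. Spheres are painted in
decreasing radius order; the painting is an exact evaluation of the
definition, verified voxel-by-voxel against a naive all-pairs oracle.

### The VOI restriction

`voi_mask()` selects TV voxels whose distance to the metastasis
compartment is strictly below a threshold ("< 700 µm" is read literally
as a strict inequality). Local VV/TV uses the VOI voxel count as its
denominator (the restricted-TV reading; the alternative — dividing by
global TV — is not what a local fraction means). Local V.Th samples the
thickness map *computed on the full vessel mask* at vessel voxels inside
the VOI: restricting the region of measurement must not truncate the
inscribed spheres, since the structures themselves are not restricted.
A VOI containing no vessel voxels yields local VV/TV = 0 and an explicit
undefined local V.Th.

## The phantom model

The generator emulates the features of a metastatic tibia scan that the
measurement chain is sensitive to, with known ground truth:

- **Cortical shell**: a tube with linear axial taper (default outer
  radius 91 µm, wall 14 µm, taper 0.15 — scaled to the 224 µm default
  grid).
- **Trabecular network**: random rod chords through the marrow (default
  110 rods of radius 7 µm). The density is chosen so the largest marrow
  pore is well below the TV closing scale; bone volume fractions land in
  the dense-metaphysis range.
- **Vessels**: piecewise-linear random walks swept with a circular
  cross-section (default 8 branches, radii uniform in 7–14 µm, i.e. 2–4
  voxels — capillary scale). Branches reflect off the endosteal wall and
  keep an axial margin from the cut faces so every vessel voxel lies
  inside TV. A biologically realistic angiogenesis model is deliberately
  out of scope; a controlled radius distribution is what the thickness
  statistics need.
- **Metastases**: ellipsoids centred on sampled trabecular-bone voxels,
  so lesions always erode bone (semi-axes uniform in 42–56 µm by
  default, above the TV closing scale so they are detectable as
  cavities). Placement retries a bounded number of times before erroring.
- **Label precedence** where primitives overlap is metastasis > vessel >
  bone: lesions are pure bone deficit (and hide vessels crossing them,
  which carry no contrast there), vessels tunnel through bone.
- **Rendering**: compartment mean intensities with background < marrow <
  bone < vessel (the contrast agent makes vessels brighter than bone by
  default; the ordering is configurable), Gaussian blur *then* additive
  Gaussian noise — the physical point-spread function acts before
  detector noise. Metastasis voxels always render at the marrow mean:
  they have no intrinsic contrast and exist in the image only as missing
  bone. Defaults: blur 2 µm, noise SD 0.02 on a 0–1 intensity scale.

Cohorts derive per-sample seeds deterministically from the cohort seed
and sample index, so any single sample can be regenerated in isolation.
Group effects are applied at generation time: a multiplicative
vessel-radius factor inside a stated distance of the metastasis
compartment (the anti-angiogenic signature; sub-voxel radii are rejected
with an error), a lesion-count offset, and a fractional trabecular-rod
offset. The per-segment ground-truth table records each segment's applied
radius and effect-region flag, so the injected effect is verifiable
exactly, by construction.

What the phantom does **not** emulate: beam hardening, ring artifacts,
intensity inhomogeneity across the field, vessel branching topology,
cortical porosity, and realistic lesion texture. Tests passing on
phantoms therefore validate the *measurement chain* — distances,
thickness, volumes, restriction, statistics — not segmentation difficulty
on real scans; the reported Dice of the baseline segmenter on phantoms
says nothing about its performance on real data, where learned
segmentation is the method of choice.

## The baseline segmenter

A classical stand-in used to exercise the evaluation stage end to end:
Gaussian smoothing (default 1 µm), hierarchical two-class Otsu
thresholding (foreground vs background, then bone vs vessel), removal of
small components (26-connected foreground; background connectivity 6 —
the standard 3D duality), then metastasis inference from the only cue these
images offer, missing bone: the bone mask is closed (bounded variant,
so the cut faces stay closed), holes are filled with sealed axial faces
to obtain the bone envelope, and envelope-interior cavities that survive
the closing, are not bone or vessel, and exceed 50 voxels are labelled
metastasis. The second Otsu is computed on the foreground eroded by one
voxel: the partial-volume boundary shell forms an intensity ramp between
marrow and bone that otherwise attracts the split away from the
bone/vessel boundary. The 50-voxel cavity floor suppresses residual
trabecular pores; both scales are configurable.

`training_size_experiment()` reinterprets a training-set-size sweep for
this parameter-free baseline: auto-thresholds are calibrated on k samples
(averaged per-sample thresholds) and Dice is evaluated on a fixed
held-out set. Median Dice is reported, not asserted monotone.

## Statistics

- `anova_f()` implements the one-way F statistic from its sums of
  squares; it is cross-checked in the tests against `stats::aov`/`lm` and
  against the squared pooled t statistic in the two-group case. Zero
  within-group variance with distinct means reports p = 0 with a
  degenerate-data warning.
- `lilliefors_test()` computes the sup-distance between the empirical
  distribution and the normal distribution with sample-estimated mean and
  SD; the p-value comes from a Monte-Carlo null (same n, same estimation
  step, add-one estimator) rather than table lookup, which is exact at
  small n where the study's group sizes live (n = 7). The replicate count
  and seed are exposed.
- Variance homogeneity uses Bartlett's test (`stats::bartlett.test`),
  the classical companion to ANOVA.
- `run_study_comparisons()` runs two families: time point 1 vs 2 on
  BV/TV, VV/TV, V.Th and Me.V/TV, and the second-time-point treatment
  arms on local VV/TV and local V.Th. Assumption-check outcomes are
  recorded per comparison; when they fail the ANOVA is still computed and
  flagged, since no nonparametric fallback is defined for this design.
  Significance tiers are the raw p < 0.05 / 0.01 / 0.001 levels with no
  multiple-testing correction by default (a `p.adjust` method can be
  switched on), mirroring raw-threshold reporting conventions. Two-group
  comparisons use the two-group ANOVA, which is equivalent to the pooled
  t-test.

## Numerical and design notes

- Exact ties in the thickness painting (a voxel exactly at a sphere's
  coverage radius) are resolved by comparing *squared* distances, so no
  square root enters a comparison.
- Morphology on masks uses the exact Euclidean distance transform for
  ball dilation/erosion, never a discrete structuring-element
  approximation.
- Dice of two empty masks is defined as 1 (perfect agreement on
  absence), a case the measurement design never meets but the code must
  define.
- Degenerate inputs error loudly and early: empty bone masks (no TV),
  empty vessel masks (no VMI/V.Th), empty metastasis masks where a VOI is
  requested, constant samples in the normality test, label ids outside
  the vocabulary, shape mismatches.
- Full-volume Dice is computed (no sub-VOI evaluation); whether to
  restrict evaluation regions is left to the caller via masks.
- Problem sizes in the tests and analysis scripts — 64³ phantoms, cohorts
  of 7 samples per arm, 100-cohort power estimates, 2000-replicate
  type-I calibrations — are chosen to exercise every stage at the study's
  own group sizes while keeping the whole suite runnable on a laptop
  core.

## Known limitations

- TV depends on the closing radius where the cortical shell is breached
  by large defects; the radius is exposed rather than estimated.
- The thickness discretisation recovers ideal cylinders aligned with
  voxel centres to within one voxel; arbitrarily aligned thin structures
  (2–3 voxel radii) carry up to about one voxel of negative bias, which
  cancels in the *relative* group comparisons the pipeline is built for.
- The baseline segmenter assumes the vessel compartment is the brightest
  class; with a different contrast ordering, explicit thresholds must be
  supplied.
- The Monte-Carlo Lilliefors p-value is itself an estimate; with the
  default 1000–2000 replicates its standard error at p ≈ 0.05 is about
  0.005–0.007.
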