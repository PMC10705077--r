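# osteovasc

Quantitative 3D morphometry of bone, blood vessels and osteolytic
metastases in contrast-enhanced micro-CT label volumes.

## The problem

In murine models of breast-cancer bone metastasis, high-resolution
contrast-enhanced micro-CT of the tibia resolves three compartments at
once: mineralised bone, blood vessels filled with a radio-opaque contrast
agent, and osteolytic metastases. The metastases carry no intrinsic
contrast — they are visible only as *missing bone structure* — which makes
both their segmentation and the quantification of the vasculature around
them delicate. Given a voxel-wise labelling of the three compartments,
the questions of interest are morphometric:

- **Volume fractions.** With TV the total volume inside the outer bone
  contour, the fractions BV/TV, VV/TV and Me.V/TV (bone, vessel and
  metastasis volume over TV) summarise each sample.
- **Local vessel thickness (V.Th).** The thickness at a vessel voxel is
  the diameter of the largest sphere that fits entirely inside the vessel
  compartment and contains that voxel (the maximal-inscribed-sphere
  definition standard in bone morphometry); V.Th is its mean over the
  vessel compartment.
- **Vascular-metastasis interdistance (VMI).** The mean, over vessel
  voxels, of the Euclidean distance to the nearest metastasis voxel.
- **VOI-restricted local metrics.** The same measures restricted to the
  volume of interest within a stated distance of the metastases
  (e.g. VMI < 700 µm), which is where anti-angiogenic treatment effects
  on the peri-metastatic vasculature are expected to show.
- **Group statistics.** One-way ANOVA F-tests between time points and
  treatment groups, preceded by Lilliefors normality checks (Monte-Carlo
  p-values) and Bartlett variance-homogeneity checks, flagged at the
  p < 0.05 / 0.01 / 0.001 levels.

The package implements this entire measurement chain, a classical
intensity-based baseline segmenter (with the Dice coefficient
`2|A∩B|/(|A|+|B|)` for evaluating any segmentation against a reference),
and — because no public scan data exists for this design — a synthetic
phantom generator that produces tibia-like labelled volumes with known
ground truth: a tapered cortical shell with a trabecular rod network,
tortuous contrast-filled vessel branches, and ellipsoidal lesions that
erode bone. Whole cohorts can be generated with injected group effects
(e.g. vessel radii shrunk 0.6× within 700 µm of lesions in one arm), so
every stage of the pipeline is testable end to end.

All distance-based measures are exact Euclidean (separable lower-envelope
distance transform) and anisotropy-aware; voxel sizes are carried in
micrometres throughout.

## Worked example

```r
library(osteovasc)

spec <- phantom_spec(seed = 1)        # 64^3 voxels of 3.5 um
out  <- generate_labels(spec)         # labels + ground truth
print(morphometry_report(out$labels))
```

```
<morphometry report, scope global>
  TV 0.004999 mm3 | BV/TV 0.4046 | VV/TV 0.0654 | Me.V/TV 0.1896
  V.Th 17.32 um | VMI 18.7 um
```

About 40% of the total volume is bone, 6.5% contrast-filled vessels with
a mean inscribed diameter of 17.3 µm, and 19% osteolytic lesions; vessel
voxels lie on average 18.7 µm from the nearest metastasis voxel
(the VMI). Segmenting a rendered
(blurred + noisy) version of the same phantom with the baseline segmenter
and scoring it against the known labels:

```r
img <- render_intensity(out$labels, spec)
seg <- baseline_segment(img)
dice_report(seg, out$labels)
```

```
       class n_seg n_ref n_intersect      dice
1       bone 53398 47170       47149 0.9376541
2     vessel  6289  7625        6272 0.9015380
3 metastasis 19599 22109       19554 0.9376618
```

The full study-style analysis — cohort simulation, segmentation
evaluation, global morphometry, the 300/700/1000 µm local analysis and
the group statistics — is laid out as numbered drivers under `analysis/`
(`Rscript analysis/01_simulate.R`, …, `analysis/05_stats.R`), each writing
its tables under `results/`. On the default synthetic cohort the treated
arm's local V.Th around metastases drops to 9.1 µm against 15.9–16.4 µm
in the other arms, and the treatment comparison flags it at p < 0.001.
`run_pipeline()` performs the same chain in one call from a
`pipeline_config()` (or a YAML file) and writes CSV reports plus a
checksummed manifest; reruns with the same configuration and seed are
bit-identical.

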