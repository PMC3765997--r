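---
title: "Methods: 3D pericardial fat modelling and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D pericardial fat modelling and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pat3d)
```

## The measurement problem

Pericardial adipose tissue (PAT) — the sum of epicardial fat (inside the
visceral pericardium) and paracardiac fat (outside the parietal
pericardium) — predicts atrial fibrillation risk independently of general
obesity, and its atrial component is the biologically interesting part:
fat abutting the atrial wall can act locally on the underlying myocardium.
Measuring it non-invasively requires (i) a volumetric reconstruction from a
stack of 2D short-axis slices on which fat has been marked, and (ii) a
demonstration that the imaging-derived mass agrees with a reference
standard. `pat3d` implements both halves, plus a synthetic phantom so the
geometric pipeline can be verified against analytic truth.

No attempt is made to separate epicardial from paracardiac fat: clinical
short-axis images often cannot resolve the pericardial layers, especially
at atrial level, so the package quantifies their sum.

## Conventions

One coordinate convention is used throughout. Slices are indexed 0-based,
cranial → caudal (index 0 is the most cranial slice, matching the
acquisition planning direction from the left atrial roof down to the
apex). In-plane pixel coordinates are 0-based `(row, col)` with pixel
centers at integer positions. The center-to-center slice spacing is
`slice_thickness + slice_gap`; slice *i* is centered at
`z = i * spacing`. Geometry is mandatory metadata: readers refuse to
invent a pixel spacing, because a volume computed without it is
meaningless. The default geometry — 6 mm slices, no gap, ~1.5 mm pixels —
matches a standard clinical steady-state free-precession short-axis
protocol, on which fat is bright without fat-specific sequences.

Two stack formats are supported: NIfTI-1 for interchange, and a raw
dialect (JSON header + little-endian float64 payload) that round-trips
bit-exactly and therefore underlies the oracle tests. NIfTI has no header
field separating slice thickness from gap, so their decomposition rides in
`descrip`; only their sum enters any volume.

## Marking fat on each slice

The marking step is deliberately decomposed into three explicit,
deterministic primitives that an operator (or script) composes per slice:

* **Polygon rasterization** — a pixel is inside iff its center satisfies
  the even-odd rule, with points exactly on an edge counted inside.
  Self-intersecting polygons are accepted under the even-odd rule.
* **Thresholding within an ROI** — select pixels ≥ a cutoff, either
  absolute or a nearest-rank percentile of the intensities *inside the ROI
  only*. Ties select (≥), so a constant ROI is selected entirely.
* **Seeded region growing** — the 4-connected component of pixels within
  an intensity tolerance of the seed pixel.

Each rule (pixel-center even-odd, nearest-rank, 4-connectivity, ≥ ties)
was chosen because it is deterministic and checkable against a brute-force
oracle; the test suite does exactly that. `apply_roi_set()` applies
annotations in order — additive polygons/seeds form unions,
`erase_polygon` subtracts — so the result is invariant to reordering the
additive annotations between erasures.

## The 3D model

Marked regions are interpolated linearly between consecutive slices: a
pixel column with values *a*, *b* on slices *i*, *i*+1 takes the value
(1 − *t*)·*a* + *t*·*b* at fractional position *t*. Each interval is
subdivided into `z_refinement` steps (default 8 — sub-millimetre axial
sampling at 6 mm spacing, with discretization error far below biological
variability); the original planes are reproduced exactly and nothing is
extrapolated beyond the first or last slice center, since the compartment
definitions bound the model anatomically.

Binary masks are interpolated as 0/1 intensities and thresholded at 0.5
(ties ≥), which is equivalent to mid-surface shape interpolation: the
model's boundary sits halfway between the marked outlines of adjacent
slices. The threshold is a tunable in the open interval (0, 1) but 0.5 is
the only symmetric choice.

Two volume estimators are provided, since area integration and voxel
counting are both defensible readings of "total volume of the 3D model":

* **Trapezoidal area**: `V = Σ dz (A_i + A_{i+1}) / 2` over the original
  slice areas.
* **Voxel count**: refined voxels are the slabs between consecutive
  refined planes; a slab is occupied iff *both* bounding planes are
  occupied (the slab lies entirely inside the thresholded model), and
  `V = count · dy · dx · dz / z_refinement`.

The entirely-inside rule makes the voxel count a lower bound that
converges monotonically to the trapezoidal value as refinement grows; for
binary masks at threshold 0.5 and even `z_refinement` the two are equal.
(A plane-counting rule instead overcounts every fat boundary by half a
slab and converges only in the limit.) Degenerate inputs are handled
explicitly: a single-slice compartment is measured as
`area × slice_thickness`, an empty one is zero.

## Compartments and mass

Atrial PAT lies above the mitral valve hinge and below the right pulmonary
artery; ventricular PAT runs from the hinge (annulus insertion) down to
the apex, inclusive of the most inferior fat margin. Landmarks are
user-supplied slice indices — identifying them is a visual task and
automating it is out of scope. The hinge-containing slice is assigned to
the ventricle (half-open convention `[rpa, hinge)` / `[hinge, last]`);
whether the boundary slice belongs to atrium or ventricle is genuinely
ambiguous anatomically, and the half-open choice keeps the split an exact
partition. The split happens on the original slice grid *before*
interpolation, so no interpolated voxel straddles compartments and totals
are exact sums; the price is that the single interval bridging the hinge
contributes to neither compartment, an error within the `A_max·dz`
discretization bound.

Mass is volume × 0.9 g/mL, the standard adipose density constant; it is a
parameter of `quantify_fat()` and masses are exactly linear in it.

## Agreement statistics

Validation against a reference uses the single-measures two-way
random-effects ICC. With mean squares from the two-way ANOVA without
replication (subjects × methods):

* consistency: `(MS_R − MS_E) / (MS_R + (k−1) MS_E)`
* absolute agreement: `(MS_R − MS_E) / (MS_R + (k−1) MS_E + k (MS_C − MS_E)/n)`

Consistency is the appropriate primary form when one method is *expected*
to read systematically lower — autopsy cannot retrieve all adherent fat —
because it ignores a fixed method offset; the absolute form, which
penalizes it, is also provided (and is the natural choice for
observer-reliability designs, where no systematic offset is expected).
Single measures, not average measures, because each subject is measured
once per method. The reported p-value is the F test on the subject effect
(`MS_R / MS_E`); it accompanies the ICC but is not itself a headline
quantity.

Bland–Altman analysis reports the bias (mean of differences, oriented
second-method − first so that a positive bias is over-estimation by the
imaging method) and limits of agreement `bias ± k·SD` with sample SD. The
default multiplier is `k = 2`, with 1.96 selectable: published half-widths
are frequently consistent with either, and the bias itself is
multiplier-independent. On the packaged nine-sheep table the recomputed
half-widths at `k = 2` (23.1 / 19.6 / 11.4 g for total / ventricular /
atrial) sit within 0.2 g of values published from unrounded source data —
the packaged integer-gram table cannot reproduce them beyond that.

## The phantom

`generate_phantom()` builds stacks with *known* fat volumes. The heart is
an ellipsoid (default semi-axes 40 × 35 × 45 mm, ovine-sized); fat is the
shell between it and an outer surface whose local thickness is a base
value (4 mm) plus a smooth seeded angular modulation (±1.5 mm), plus
spherical patches seeded on the shell surface within the atrial cap —
emulating the irregular shell and the patchy atrial deposits found between
the appendages and the great arteries. Intensities are three class means
(fat 100 > myocardium 40 > background 0) plus additive Gaussian noise.

Ground truth is computed independently of the pipeline under test: the
analytic region is either integrated in closed form
(`4π/3 [(a+t)(b+t)(c+t) − abc]` for the unmodulated, patch-free shell,
with exact ellipsoid-cap formulas for the compartment split) or voxelized
on a 0.5 mm isotropic grid — truth masks are sampled from the analytic
region at slice planes, never painted through the interpolation code, so
validation cannot be circular. The continuous atrial/ventricular truth is
split at the midplane between the hinge slice and the slice above it, the
continuous analogue of the half-open slice rule. The phantom emulates
geometry and contrast only: no bias fields, motion, partial-volume
blurring, chemical shift or cine dynamics, so passing tests demonstrate
geometric fidelity of marking → interpolation → quantification, not
robustness to MR physics artifacts.

## What the tests establish

* Rasterization, thresholding, region growing, interpolation, ICC and
  Bland–Altman each match an independently coded brute-force oracle
  (exhaustive pixel scans, BFS flood fill, `approx()` per column,
  sums-of-squares ANOVA) to 1e-12 or exactly.
* The packaged validation table reproduces the published agreement
  statistics: means to the nearest gram, total bias 26 g, atrial bias
  7.7 g, consistency ICC > 0.80 for every compartment.
* On 20 random noise-free phantoms at 6 mm slices the recovered total
  volume stays within the `A_max·dz` bound (in practice ~1% relative
  error), and the mean absolute error roughly halves when slices are
  re-sampled at 3 mm — first-order behaviour dominated by per-column axial
  quantization of the fat boundary.
* With intensity noise at 10% of the fat–myocardium contrast, threshold
  segmentation at the class midpoint recovers total volume within 10% on
  20/20 seeds: at that noise level misclassification is negligible and the
  error is still discretization-dominated.

Test problem sizes (72 × 72 grids at 2 mm pixels, 20 phantoms per
property) keep the suite fast while leaving the slice geometry — the
quantity under test — at the clinical 6 mm.

## Known limitations

* Landmark slices are supplied, not detected; mis-identifying the hinge by
  one slice moves `~A_hinge·dz` of fat between compartments.
* The marking primitives realize a semi-automated workflow but do not
  attempt learned fat classification; threshold choice on real images
  remains an operator decision.
* ICC confidence intervals and k > 2 repeated-session designs are out of
  scope (the ICC accepts k ≥ 2 raters, but no CI machinery is provided).
* The observer-reliability tables of a validation study require repeated
  human readings, which cannot be simulated; the statistics for them are
  implemented and oracle-tested instead.
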