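---
title: "Methods: SEM cell morphometry with semquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SEM cell morphometry with semquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semquant)
```

semquant quantifies cell size, shape, complexity and texture from calibrated
scanning electron micrographs. This vignette documents the models and
estimators, the tunable parameters and their defaults, the numerical choices
made where several reasonable options existed, and what the synthetic
validation fixtures do and do not demonstrate about real data.

## Input model and calibration

A `micrograph` is a rectangular raster of 8- or 16-bit intensities with a
pixel size in µm supplied by the user. SEM vendors store scale information in
nonstandard TIFF tags, so semquant deliberately does not parse metadata: the
calibration is an explicit argument everywhere and is carried through to all
physical outputs (µm, µm², µm³, µm⁻¹, degrees). Multi-channel inputs are
reduced by the unweighted channel mean, since the SEM signal is physically
single-channel. Coordinates are row-major with the origin at the top-left;
angles are measured from the +x (column) axis, counterclockwise with y
pointing up the image. Because alignment angles are folded into [0°, 90°],
this convention only fixes the meaning of the reference axis.

## Segmentation

Thresholding uses Otsu's method by default — it is parameter-free and
reproducible, which matters more than optimality for a measurement pipeline —
with a manual override for low-contrast material. A blank image makes Otsu's
criterion undefined and raises a typed error rather than guessing.
Components are labeled at 8-connectivity by default because thin neurites
rasterize with diagonal steps that 4-connectivity would fragment; the
component-size filter and hole filling are off by default (0 px, `FALSE`) so
that cleaning is always an explicit decision recorded in the mask's
`method_record`. Border-touching cells are excluded from morphometry by
default (their dimensions are censored by the field of view) but should be
kept for whole-field fractal or texture analysis.

## Rod morphometry

Rod-shaped bacteria are modeled as spherocylinders of width $W$ and
cap-to-cap length $L$:

$$V = \frac{\pi W^2}{4}\left(L - \frac{W}{3}\right), \qquad S = \pi W L,$$

so $V$ degenerates exactly to $\pi W^3/6$ and $S$ to $\pi W^2$ when $L = W$.
The automated estimator replaces manual tracing: the silhouette is thinned to
its medial axis, $L$ is the longest geodesic path through the skeleton
extended at both ends by the local medial radius, and $W$ is twice the mean
distance-transform radius along the axis. The mean (not maximum) caliber is
used because the constant-width spherocylinder underlies the volume model.
This estimator is orientation-independent and follows curved rods, unlike
bounding-box Feret diameters, which are nevertheless available
(`feret = TRUE`) as a cross-check. Distance-map values measure to background
pixel centers, so radii subtract 0.5 px; instances under 25 px (configurable)
are rejected because width quantization error exceeds ~10% below that size.
Cells measuring wider than long cannot be force-fitted to the rod model and
are rejected with a reason, and aspect ratios marginally above 1 (noise on
near-circular cells) are clipped with a warning.

Thinning uses the Guo–Hall two-subiteration algorithm. Zhang–Suen thinning —
the other standard choice — progressively erodes the end pixels of oblique
one-pixel lines (tip configurations with two neighbors and one transition are
deletable on every pass), which collapses the medial axis of rods oriented
near 45°/135° and was observed to destroy length recovery entirely for such
cells; Guo–Hall's $\min(N_1, N_2) \ge 2$ condition preserves those line ends.

## Neuronal descriptors

The soma is operationalized as the maximal inscribed disc (distance-transform
argmax), a parameter-free reading of "cell body"; ties are broken
deterministically (lowest row, then column). Neurites are the connected
skeleton subtrees left after removing skeleton pixels inside the soma disc,
each anchored at the soma boundary; a branched subtree counts as one neurite
whose length is its longest geodesic branch (the alternative — one count per
tip — is defensible but inflates counts from rasterization side branches).
Traces shorter than `min_neurite_um` (default 5 px at the image calibration)
are discarded as skeleton spurs. The traced tip is extended by the local
medial radius and the base projected onto the soma boundary, so lengths refer
to the boundary-to-edge extent of the process — consistent with tracing "to
its edge". Note the synthetic generator records centerline arc length, so
recovered lengths exceed generator truth by about half the arm width
(2–3% for the fixtures used here); this convention difference is intentional
and documented rather than hidden in a correction.

Radial distance is the Euclidean base-to-tip distance; straightness is kept
as the literal difference (length − radial, in µm), with a dimensionless
tortuosity (length/radial) additionally emitted as a labeled extension.
Alignment uses the base-to-tip chord folded into [0°, 90°] against a
reference axis (default 0°; a seeded random axis mode exists for unpatterned
substrates). Classes are strict: parallel below 15°, perpendicular above
75°, and the unnamed middle band is reported as "intermediate" — 15° and
75° exactly are intermediate.

Area is the pixel count times pixel area. For the perimeter in
$C = 4\pi A/P^2$, the naive chain-code estimator (axial steps 1, diagonal
steps $\sqrt 2$) overestimates smooth digitized boundaries by ≈5% on
average over orientations, which would give a large rasterized disc
$C \approx 0.90$ and contradict the calibration point that round cells score
1. The default is therefore the Vossepoel–Smeulders calibrated chain
(0.980 per axial step, 1.406 per diagonal, −0.091 per direction change),
under which a disc of radius 200 px measures $C = 1.00 \pm 0.01$. The naive
chain (`"chain"`) and the literal boundary-pixel count (`"pixel_count"`) are
available for comparison with software that uses them. Convex-corner shapes
such as axis-aligned squares are the worst case for the calibrated weights
(a square reads $C \approx 0.83$ vs the analytic $\pi/4 \approx 0.785$);
the calibration targets smooth biological outlines.

A cell is differentiated when at least one neurite is as long as the soma
diameter; cells without neurites are never counted.

## Fractal descriptors

The box-counting dimension is the least-squares slope of $\log N(\varepsilon)$
against $\log 1/\varepsilon$, with box sizes defaulting to powers of 2 from
2 px to a quarter of the smaller image dimension (≥ 4 sizes enforced; on a
256-px image this gives 2–64 px). $N(\varepsilon)$ is minimized over 4
diagonal grid translations to reduce grid-phase bias; increasing the offset
count can only decrease the reported counts. The fit $R^2$ is always
reported and a warning is raised below 0.98, the conventional flag for a poor
scaling regime. Weighted regressions and mass–radius estimators are out of
scope; box counting is the de facto standard for 2-D silhouettes.

Lacunarity uses the gliding-box estimator,
$\Lambda(r) = E[M^2]/E[M]^2 = \mathrm{var}(M)/\mathrm{mean}(M)^2 + 1$,
over all box positions, so a translationally uniform pattern scores exactly 1
and clumped patterns score higher; a non-overlapping grid mode exists for
speed on large fields. Analyses run on filled silhouettes by default, with a
one-pixel outline mode available since outline-based workflows are common.

One caution established during validation: for star-shaped cells a large
filled soma dominates the box counts and can *reverse* the intuitive
branching-vs-D ordering; comparisons of D between cells are only meaningful
on a common canvas and box-size range, as `silhouette_pipeline()` records.

## GLCM texture

Intensities are quantized to `levels` bins (default 16) uniformly over the
full bit-depth range — not the observed min–max — so that descriptors are
comparable across images from one acquisition session. Co-occurrences are
accumulated over the four standard distance-1 offsets
{(0,1), (1,0), (1,1), (1,−1)}, symmetrized and normalized by default. The
five descriptors follow the Haralick conventions: ASM $\sum p^2$, entropy
$-\sum p \log p$ (natural log, $0\log 0 = 0$, log₂ optional), contrast
$\sum (i-j)^2 p$, correlation
$\sum (i-\mu_i)(j-\mu_j)p / \sigma_i\sigma_j$, and inverse difference
moment $\sum p / (1 + (i-j)^2)$. For a constant image the gray-level
variance is zero and correlation is reported as an explicit undefined value
(`NA` with a reason attribute), never silently propagated as NaN.
`texture_map()` evaluates the descriptors in sliding windows (default 64 px
window, 32 px stride) to produce the per-window feature rasters a classifier
would consume; classification itself is out of scope.

## Synthetic fixtures and what they show

The generators produce geometry with exact ground truth under a single
explicit seed (no global RNG state is disturbed, and regeneration is
bit-identical): spherocylinder rod populations placed without overlap by
rejection sampling on segment–segment distances (E. coli preset:
L ~ U(2, 4) µm, W/L = 0.25, 0.02 µm/px, foreground 180 on background 20);
soma-plus-arms neurons with optional sinusoidal tortuosity (0.2 µm/px keeps
≥ 10 px across a 2 µm process); exact fractal patterns (1-px line, filled
square, Sierpinski triangle on a $2^k$ grid, whose foreground count is
exactly $3^k$ and whose similarity dimension $\log 3/\log 2$ anchors the D
estimator); and textures whose GLCMs are known in closed form (a constant
image and a period-1 checkerboard).

These fixtures validate geometry and statistics, not rendering: they contain
no charging artifacts, topographic shading, focus gradients, or touching
cells. Passing the recovery suites therefore shows that the estimators are
unbiased on clean, separable silhouettes at the stated calibrations; it does
not certify segmentation quality on low-contrast or crowded micrographs,
where manual thresholds and the mask-cleaning parameters must be chosen by
the analyst. Overlapping bacteria in biofilms are measured as the connected
components they form — no watershed splitting is attempted.

## Problem sizes and determinism

The validation suite runs on desk-scale problems chosen to exercise each
estimator's asymptotic regime while completing in seconds: 50-rod fields at
0.02 µm/px (~2000² px), single neurons at 0.2 µm/px (~500² px), 512² fractal
canvases, and 64–96 px texture tiles. Every stochastic step takes an explicit
seed, the orchestrator (`run_command()`) serializes the full configuration
next to every output, and identical (input, config, seed) triples produce
byte-identical CSVs.

## Known limitations

- Eq. (1) is undefined for cells wider than long; such instances are
  rejected, not force-fitted.
- The model surface $S = \pi W L$ is a 3-D geometric idealization reported
  alongside, and clearly distinguished from, the 2-D projected area; an SEM
  projection cannot measure true 3-D surface.
- Perimeter calibration assumes smooth outlines; polygonal cells with long
  axis-aligned edges are measured slightly long.
- Neurite radial distance is taken from the soma boundary (switchable
  reading of "from the cell"); measuring from the soma center would add one
  soma radius.
- No dendrite/axon discrimination, Sholl analysis, multifractal spectra,
  3-D fractal analysis, Gabor decompositions, or texture classification.
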