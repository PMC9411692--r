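---
title: "Measuring positional skull deformities from vertex-view contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring positional skull deformities from vertex-view contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioview)
```

## The measurement problem

Positional plagiocephaly (oblique flattening of an infant's skull) and
positional brachycephaly (disproportionate widening) are routinely quantified
from the head's outline seen from directly above — the vertex view. Two
families of indices are in clinical use:

* **CVAI** (cranial vault asymmetry index): the two oblique skull diameters
  are measured at 30° either side of the anteroposterior midline and compared
  as `(long − short) / short × 100%`. A symmetric head scores 0.
* **CI** (cranial index): skull width over skull length, `EarEar /
  NoseOcciput × 100%`.

Plagiocephalometry (PCM), an established band-molding method, reports the
analogous **ODDI** (oblique diameter difference index, measured at 40°) and
**CPI** (cranial proportional index). PCM's published formulas are not part
of this package's sources; `cranioview` adopts the ratio form `long / short ×
100%` for ODDI (so a symmetric head scores 100, consistent with its
published severity thresholds 104/108/112, all slightly above 100) and the
width/length form for CPI (its thresholds 90/95/100 coincide with CI's).
Both are *digital emulations* computed on the same photographed contour, not
reproductions of the physical band workflow: the thermoplastic band uses
tragus and posterior landmarks that a vertex-view photograph does not
expose. On identical geometry CPI equals CI by construction.

## Frame construction

Given a closed contour of the outer skull outline and three landmarks — the
highest point of the nasal dorsum and the anterior helical border of each
ear — the measurement frame is built literally from the published recipe:

1. A **mediolateral line** is drawn through the two ear landmarks and
   extended to the skull outline: the *EarEar* chord. Its midpoint is `m1`.
2. The **anteroposterior line** runs through the nose landmark and `m1`,
   again extended to the outline: the *NoseOcciput* chord (anterior endpoint
   on the nose side). Its midpoint is `m2`.
3. From `m2`, two full skull chords are measured at ±30° from the
   anteroposterior axis (for CVAI) and ±40° (for ODDI), rotating toward the
   subject's right and left.

Three choices here were genuinely open and are resolved as follows:

* The anteroposterior axis is **not** forced perpendicular to the ear line;
  it is the unit vector from `m1` toward the nose, exactly as the
  construction sentence reads. For symmetric landmark placements the two are
  perpendicular anyway.
* The oblique chords originate at `m2`, the midpoint of the full
  nose–occiput skull chord (not `m1`), following the literal sentence order
  of the construction; the oblique angles are measured from the midline, the
  convention used throughout the CVAI literature.
* *EarEar* and *NoseOcciput* are skull-contour chords ("the outside of the
  skull … marked"), not inter-landmark distances.

All indices are ratios of chord lengths, hence unit-agnostic and invariant
under rotation, translation, uniform scaling and left–right mirroring — each
of these is asserted to 1e−9 relative tolerance in the test suite.

### Numerical choices

Chord endpoints are segment–line intersections in double precision. Each
polygon vertex is classified by its signed perpendicular distance to the
line, with vertices exactly on the line assigned to the positive side: a
line through a vertex therefore yields exactly one crossing and a
tangential touch none. For non-convex contours the crossing **farthest**
from the interior origin point is taken on each side — the measured chord
always ends on the outermost skull boundary. Input polygons are re-oriented
counterclockwise; consecutive vertices closer than 1e−9 × diameter are
merged; self-intersecting polygons and polygons with fewer than 32 vertices
are rejected. If the two oblique chords tie, CVAI is 0 and ODDI is 100 and
no sidedness is reported.

## Severity scales

The five published scales ship as `builtin_scales()`:

| scale | cut-offs | levels |
|---|---|---|
| CVAI-5 | 3.5 / 6.25 / 8.75 / 11 | normal … very severe |
| NewCVAI-4 | 3.5 / 7.5 / 11 | normal … severe |
| ODDI-4 | 104 / 108 / 112 | normal … severe |
| CI-4, CPI-4 | 90 / 95 / 100 | normal … severe |

Intervals are closed on the left ("mild ≥ 3.5 and < 6.25"), so a value
exactly at a cut-off takes the higher level. `reduce_five_to_four()`
implements the published 5→4 reduction — the middle level is split at its
midpoint, `(6.25 + 8.75)/2 = 7.5`, and the halves merged into the
neighbours — which reproduces the NewCVAI-4 cut-offs exactly. Values are
classified at full precision; because values near a cut-off flip levels
under tiny perturbations, any rounding is an explicit caller/CLI option
(default: none).

## The synthetic generator and what it does (not) show

No real photographs ship with the package, so every measurement path is
exercised on a parametric model: an ellipse with half-width `a` and
half-length `b` (brachycephaly axis: CI ≈ 100·a/b), deformed by a Gaussian
angular dent of depth `d` centered at `theta0` with width `sigma`
(plagiocephaly axis: CVAI increases strictly with `d`), plus seeded uniform
radial jitter emulating segmentation noise:

```
r(theta) = r_ellipse(theta; a, b) · (1 − d·exp(−angdist(theta, theta0)² / 2σ²)) + noise
```

Defaults emulate an infant head: `a = 70`, `b = 85` model units (CI ≈ 82),
dent centered posterolaterally (`theta0 = 140°`, `sigma = 0.5` rad), 512
contour vertices, jitter amplitude 0.5% of local radius — chosen once as
plausible magnitudes for segmentation output of a vertex-view photograph.
Landmarks are placed on the dented, noise-free outline (nose at θ = 0, ears
at ±90°, pulled 0.5% inside so they stay inside the jittered polygon):
the jitter models boundary-segmentation error, which does not move
anatomical landmarks.

Ground truth comes from `true_indices()`, an independent oracle that never
touches the production chord code: each chord is found by marching a ray
across a dense (1e5-sample) rendering of the noise-free radius function and
bisecting the outermost inside-to-outside crossing. Noise-free measurement
agrees with this oracle to ~0.003 CVAI points at 512 vertices, and measured
ellipse chords agree with the closed form `2·(sin²φ/a² + cos²φ/b²)^(−1/2)`
to better than 0.1%.

**Measurement-noise floor.** With 0.5% radial jitter the information in the
data itself bounds the achievable accuracy: a chord endpoint is the line
crossing of an edge between two independently jittered vertices, so its
position carries noise with a standard deviation near 0.2% of the radius
regardless of estimator, and CVAI (which combines four endpoints) inherits
a noise floor of roughly 0.3 points standard deviation. Across 50 random
cases the worst-case deviation from oracle truth is therefore typically
0.5–0.8 CVAI points and 0.6–0.8 CI points — the *mean* absolute deviations
are ≈ 0.2 points. Severity classification is robust to this: in the 50-case
study set, measured and oracle severity agree exactly in ≥ 90% of
classifications and never differ by more than one level, mirroring the
agreement structure reported for the two clinical methods. The synthetic
model does not emulate hair or cap occlusion, perspective or lens
distortion, or landmark placement error by the photographer, so passing
tests demonstrate correctness of the geometry and robustness to boundary
jitter — not field accuracy of a phone app.

The mask path (`rasterize_mask()` → `extract_contour_from_mask()`) stands in
for a segmented photograph: scanline polygon fill at a chosen resolution,
then sub-pixel boundary recovery at the 0.5 iso-level (marching squares)
and arc-length resampling. At 4 px/unit the full
rasterize→extract→measure round trip reproduces oracle CVAI within 0.5
points. Pixel coordinates are column/row with the origin at the top-left
pixel center; the stored affine transform makes the convention explicit.

## Agreement statistics

`crosstab()` / `match_summary()` reproduce the published comparison layout:
k×k cross-tabulation of paired ordinal levels with exact, one-level and
larger-discrepancy proportions (stored at full precision, displayed rounded
half-up to whole percent, as the published tables print). The two published
4×4 tables ship as plain-CSV fixtures via `published_crosstab()`; feeding
their 60 reconstructed pairs through `crosstab()` yields 37/60 = 62% exact
and 23/60 = 38% one-level matches for the plagiocephaly comparison, and
44/60 = 73% / 16/60 = 27% for brachycephaly, with no discrepancy beyond one
level in either.

`pearson_cor()` reports the sample correlation with a two-tailed p value
from the t transform with n−2 degrees of freedom (the reference distribution
is not stated in the source material; the t transform is the standard
choice). `interpret_r()` applies the conventional qualitative bands on |r|
(negligible < 0.30 ≤ low < 0.50 ≤ moderate < 0.70 ≤ high < 0.90 ≤ very
high); the published band ranges overlap at their endpoints, so boundary
values are assigned to the higher band. `mann_whitney_u()` compares two
independent samples by rank sums with midranks for ties; the p value is
exact (equivalent to full enumeration, verified in the tests) when `n1·n2 ≤
400` and tie-free, otherwise a normal approximation with tie and continuity
correction — the variant switch is overridable since only the test, not the
variant, is named in the source. The study's own correlation coefficients
(r = 0.849, r = 0.938) and timing comparison depend on unpublished
per-infant data and are not reproducible here; the band classification of
those printed coefficients is asserted instead.

## Problem sizes used in the checks

The packaged checks run on 512-vertex contours (2048–4096 for convergence
checks), a 50-case synthetic study set for recovery properties, 4 px/unit
masks (~450×450 px), and sample sizes ≤ 10 per group for the exact
rank-test enumeration — sizes at which every closed-form oracle is sharp
and the whole suite completes in well under a minute.

## Worked example

```{r example}
params <- skull_params(a = 62, b = 80, flat_depth = 0.18,
                       flat_center_deg = 150, noise_amp = 0.005, seed = 7)
case <- generate_contour(params)
res <- measure_all(case$contour, case$landmarks)
res
c(truth_cvai = case$truth$cvai, truth_ci = case$truth$ci)

scales <- builtin_scales()
classify_severity(res$cvai, scales[["CVAI-5"]])
classify_severity(res$ci, scales[["CI-4"]])
```

## Limitations

* Landmark coordinates must be supplied; automatic landmark detection from
  photographs is out of scope, as are camera calibration and perspective
  correction.
* ODDI and CPI are geometric emulations on the photographed contour; they
  are not measurements of the physical band method.
* Severity levels are descriptive. The source material is explicit that
  severity scales can support, but never solely determine, treatment
  decisions.
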