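---
title: "Rib cross-sectional corridors: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rib cross-sectional corridors: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribmorph)
```

## The measurement model

A rib cross-section is represented by two closed planar contours in
millimetres: the periosteal (outer) and endosteal (inner) borders of the
cortical bone. All section properties are exact polygon quantities computed
by Green's-theorem vertex summation:

* areas and centroids from the shoelace formula;
* second moments of the solid lamina from the standard cubic vertex sums;
* the hollow (cortical ring) section as outer-minus-inner, evaluated about
  the ring's *composite centroid* — the area-weighted centroid of the ring
  itself, not of the periosteal lamina. `Imax`/`Imin` are the eigenvalues of
  the resulting 2×2 moment tensor, `theta_max` the direction (in
  (−π/2, π/2]) of the axis about which the moment is maximal, and
  `Irat = ln(Imax/Imin)` uses the natural logarithm.

The reference point for the moments is a genuine modelling choice: an
imaging pipeline could equally report moments about image axes. We use
centroidal axes, the mechanics convention, because bending stiffness about
principal centroidal axes is the quantity of structural interest; this is
configurable downstream only by transforming contours before measurement.

Contours are validated on entry: at least three distinct vertices, simple
(non-self-intersecting, checked by an O(n) convexity shortcut with an O(n²)
segment-intersection fallback), nonzero area; orientation is normalised to
counter-clockwise, so input winding never changes a result. Degenerate ties
(`Imax = Imin` to relative 1e−12) report `theta_max = 0` and `Irat = 0`
exactly, since the orientation is undefined for round sections.

## Stations and frames

Positions along a rib are percentages of midline arc length: 0% at the
vertebral (costovertebral) end and 100% at the sternal end, the direction in
which upper-rib sections elongate. The default grid is 2.5%, 5%, …, 97.5% —
39 stations, endpoints excluded. The endpoint convention is not universal;
we exclude the ends because section planes at the very tips of a rib are
ill-defined, and the grid is a plain numeric argument everywhere, so other
conventions are a one-line change.

Section planes carry an orthonormal basis with `e_north` toward the
superior aspect (an up-hint projected off the midline tangent) and `e_east`
toward the cutaneous aspect, with `(e_east, e_north, tangent)` right-handed.
The handedness is a fixed package convention; left and right ribs are
mirrored explicitly by the caller's choice of hint.

## Two offset conventions

Contour offsetting appears twice with different physics, and the package
deliberately implements both corner rules:

* **Mitered offset** (`offset_contour(..., corner = "miter")`, the default):
  each vertex moves `delta / cos(theta/2)` along the bisector of its edge
  normals, so every edge line moves outward by exactly `delta`. This is the
  polygon analogue of dilating the *boundary*, which is what a biased
  segmentation does; for convex sections the area increase is
  `delta·P + delta²·Σ tan(theta/2)`, within a fraction of a percent of the
  rounded Minkowski value `delta·P + π·delta²` for finely sampled borders.
* **Node displacement** (`corner = "vertex"`): each vertex moves exactly
  `delta` along the unit bisector. This is the shell-element convention —
  the node carries the thickness — and is what ring extraction uses: a
  regular 16-node ring with vertex radius 5 mm and 0.7 mm shells maps to
  periosteal/endosteal vertex radii of exactly 5.35/4.65 mm. The price is a
  corner deficit of order `1 − cos(π/n)` against the thin-shell estimate
  `Ct.Ar ≈ perimeter × t` (≈1.9% for 16-node rings, ≈3.4% for 12-node).

Erosions that would invert or self-intersect the polygon are rejected
("offset collapses contour"), detected by requiring every edge to keep its
direction — simplicity alone does not catch a fully inverted polygon.

Whether HBM node rings sit on the shell midsurface or on one face is not
standardised across model families; the package defaults to the midsurface
(±t/2) and exposes `node_surface = "mid" | "outer" | "inner"`. Per-ring
projection uses the least-squares plane of the ring's nodes, since FE rings
need not be planar; rigid transforms of a whole mesh therefore do not change
extracted properties.

## Corridors and audits

Corridors are per (sex, rib, property, station) sample means and SDs
(n − 1 denominator) over subjects, with the contributing `n` recorded per
station; no cross-station smoothing is applied, and corridors pool the whole
population of each sex rather than demographic subsets. Audits compute
per-station z-scores against the sex-matched corridor, excluding stations
with zero or undefined SD, and summarise each (model, rib, property) as the
signed mean z and the percentages of stations with z > 1, |z| ≤ 1 and
z < −1. The boundary |z| = 1 counts as inside (with a 1e−9 absolute
tolerance so traces constructed exactly at mean + 1 SD are "in", not
"high"); percentages are exact multiples of 100/n_stations and are rounded
to integers only in the formatted report, which is why printed rows can sum
to 99–101.

## The synthetic cohort

No subject-level rib contour data are publicly deposited, so the generator
is a first-class module that emulates the statistical structure the analysis
assumes — it is a synthetic stand-in, not a shape model of real ribs.
Sections are elliptical annuli: the outer border is an affine image of a
regular 64-gon (area-normalised so the polygon area equals the sampled
Tt.Ar exactly), the inner border a similar copy scaled so the cortical
thickness at the semi-minor axis matches the thickness profile. Similar
ellipses make `Imax/Imin` equal the squared aspect ratio exactly, giving
closed-form oracles for every property.

Default conditions (chosen once as field-realistic adult values; the
magnitudes of published corridor figures are not extractable from text):

* 118 male and 122 female subjects, ages uniform by decade in 20–90;
  demographics (height, weight, BMI) mimic the reported cohort marginals and
  are metadata only.
* Female vertebral-end Tt.Ar `max(80 − 1.7(rib − 7)², 40)` mm², declining
  linearly by 55% toward the sternal end; male profile multiplied so the
  male–female gap is 1.5 female-SD.
* Aspect ratio ρ = Imax/Imin rising (log-Gaussian bump, width 30%) to a peak
  at station 90% of 15 (M) / 18 (F) for ribs 2–5, falling off to 4 by
  rib 11; baseline ρ = 1.8.
* Cortical thickness 0.85 − 0.003·station mm, ×1.15 in males.
* Between-subject size: lognormal, `sdlog = 0.15`, `meanlog = −sdlog²/2` so
  the multiplier has mean exactly 1. Station noise: normal(1, 0.05) clipped
  symmetrically to [0.5, 1.5]. Log-aspect noise: additive N(0, 0.05) on
  ln√ρ, giving Irat an SD of 0.10 — without it Irat would have zero
  population variance and z-scores for shape would be undefined. Small
  N(0, 0.08 rad) tilts randomise `theta_max`. Noise is independent across
  stations (the station-level correlation of real measurement noise is not
  quantified in the source material; it is configurable by post-processing).

These choices make the generator's station means *exactly* the profile for
Tt.Ar and Irat (unit-mean multiplicative noise; symmetric additive log
noise), which is what the corridor-recovery checks exploit: across 20 seeds,
estimated per-station means must fall within 3σ/√n of the profile at ≥99% of
the 780 (sex × rib × station) cells, and a zero-noise spec must reproduce
the profile to relative 1e−9 with zero SD. Means of the other four
properties differ from the noise-free family values only at second order in
the noise CVs (≈2–3%). A rare validity clamp keeps the endosteal semi-minor
axis positive (b ≥ 1.1·t); it never engaged in the default-seed runs
reported by the tests.

What passing these checks does **not** show: real rib sections are
asymmetric (thicker cutaneous cortex, blade-like sternal ends), their noise
is spatially correlated along the rib, and cortical thinning has age
structure. Results on real data depend on the upstream segmentation, which
is out of scope here.

## Corridor-tracing meshes

`simulate_hbm_mesh()` inverts the extraction pipeline: per ring it solves
(fixed-point iteration through the actual node-offset-and-measure
arithmetic, to relative 1e−12, typically <50 iterations) for the node
ellipse and thickness such that the extracted Tt.Ar, Es.Ar and Irat equal
`corridor mean + offset·SD`. Three targets, three degrees of freedom
(a, b, t); `Ct.Ar` follows by additivity and `Imax`/`Imin` by the family,
tracking corridor means to ~0.1 SD at zero offset. With a fixed uniform
thickness (the 0.7 mm THUMS/VIVA+ convention) only Tt.Ar and Irat are
matched. Rings are placed at the grid stations plus both rib ends (end
targets clamped to the nearest station) so that re-measuring the mesh by
arc length reproduces the targets at every grid station despite the 0%/100%
terminal rings.

## Problem sizes and runtime

The test suite measures ~94,000 sections per simulated cohort through a
vectorised batch of the same Green's-theorem arithmetic as the scalar path
(the two are asserted identical bit-for-bit); a full 240-subject cohort
simulates and pools in a few seconds. Oracle-equivalence checks rasterise 50
randomised star-convex hollow sections at 0.05 mm pixels and require all
six properties within 0.5%; corridor recovery runs 20 full-cohort seeds.
The complete suite runs in about two minutes on one CPU.

## Known limitations

* Elliptical-annulus sections only in the generator; no statistical shape
  model, no cortical asymmetry.
* Ribs 1 and 12 are out of scope (excluded from the underlying measurement
  scheme), as are fracture modelling, age-stratified corridors and
  significance testing of model-population differences.
* Native FE keyword decks (LS-DYNA, ABAQUS) are not parsed; meshes enter
  through the neutral JSON ring format (schema in
  `inst/extdata/ring_mesh_schema.json`).
* The rasterisation oracle is for testing, not production: it is
  deliberately brute-force and slow.
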