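---
title: "stalkscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stalkscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stalkscan)
```

## The measurement problem

Transverse cuts through grass stalks (maize, sorghum, *Miscanthus*) show
three tissues a flatbed scanner can resolve: a darker outer **rind**
(epidermis plus lignified sclerenchyma/collenchyma), the bright
parenchymatous **pith**, and the **vascular bundles** scattered through the
pith as small bright elliptical spots. Five traits summarize this anatomy:
stalk diameter, rind thickness, pith area, bundle count/density, and
individual bundle size. stalkscan measures all five from RGB scans of
hand-cut sections laid on a scanner bed with the lid open (dark
background), at a known resolution (typically 800 dpi, i.e.
`800/2.54 ≈ 315` px/cm; the conversion always uses exactly 2.54 cm/inch and
is never rounded internally).

## Pipeline

### Section segmentation and morphometry

The grayscale image (Rec. 601 luminance) is thresholded with Otsu's method:
the level maximizing between-class variance over the 256-level histogram,
with foreground *strictly greater than* the threshold — strictness makes
the contract bit-exact and testable against an exhaustive scan of all 256
candidate levels. Holes are filled before anything else because bright pith
highlights can fall below the global level and would corrupt areas. Debris
is removed by two rules acting on 8-connected components: area below
15 000 px (far smaller than any stalk section at 800 dpi) or
moments-ellipse eccentricity above 0.99 (scratch- and hair-like objects).
8-connectivity is used because hand-cut sections can hang together by
single-pixel diagonal necks. The filter is idempotent.

Surviving objects are ordered top-to-bottom then left-to-right by centroid,
with *row banding*: centroid rows closer than half a typical section
diameter count as one bed row, so sub-pixel jitter cannot scramble the
within-row order on which override files rely. Per object:

* **area** — pixel count / (px/cm)², exact by construction;
* **mean diameter** — twice the mean distance from the area centroid to the
  outer boundary pixels (pixels with a background 4-neighbor). The
  alternative 4·area/perimeter was rejected as perimeter-noise-sensitive;
* **perimeter** — corrected chain length of the traced outer contour
  (0.980 per axial step, 1.406 per diagonal step, −0.091 per corner, after
  Vossepoel & Smeulders). A naive √2-weighted chain overestimates smooth
  digitized outlines by ≈5%; the corrected estimator is within ≈0.3% of the
  true perimeter of circles and ellipses at the sizes scanned here.

### Rind thickness

The green channel — where the pith/rind contrast is strongest — is smoothed
inside the object with an isotropic Gaussian of standard deviation
`filter_width × sigma0_frac × mean diameter`. Two numerical choices matter:

* Smoothing uses **normalized masked convolution** (the blur of `g·m`
  divided by the blur of `m`): out-of-object pixels carry zero weight, so
  the dark background cannot bleed in and pull the pith boundary inward.
  Filling the outside with the in-object mean, an alternative we measured,
  biases the recovered annulus thickness by ≈2 px at the default width.
* `sigma0_frac = 0.012` of the section diameter. The width multiplier
  (default 1.5, useful range 1–2.5) is deliberately dimensionless so the
  same setting transfers from maize to the much thinner *Miscanthus*. At
  0.012 the recovered thickness of a clean synthetic annulus stays within
  1 px of truth over the whole 1–2.5 range; at 0.02 the largest width
  biases by ≈4 px, which is why the smaller base was chosen.

Otsu thresholding runs on the in-object filtered intensities only (the
background would otherwise dominate the histogram), over 256 levels
spanning their observed range. The pith is the largest above-threshold
component, hole-filled. Two degeneracy guards reject sections without a
usable boundary: pith/rind class means closer than `min_contrast = 10`
gray levels (a uniform interior measures ≈6 through its antialiased edge;
a real boundary ≈75), and a "pith" covering more than 95% of the section.
A pith touching more than 20% of the outer boundary is kept but flagged.

Rind thickness is the mean Euclidean distance from each outer-boundary
pixel to the nearest pith-boundary pixel, computed with an exact Euclidean
distance transform and verified in the tests against an O(N²) all-pairs
oracle to 10⁻⁶ relative error. The direction (outer → pith) follows the
definition used for the trait; it matters only for non-concentric shapes.

### Bundle counting

The grayscale crop is convolved with a Gaussian whose full width matches a
typical bundle (`bundle_width_cm = 0.03`, ≈9 px at 315 px/cm; σ = width/2),
merging each bundle's internal structure into one peak. Perona–Malik
anisotropic diffusion (exponential conduction, `kappa = 30` on the 8-bit
scale, 20 explicit Euler steps of `dt = 0.2`; `dt ≤ 0.25` enforced for
stability) then flattens parenchyma texture while preserving bundle-scale
edges. The scheme is flux-conservative with reflecting boundaries, so total
intensity is preserved to floating-point accuracy and constant images are
fixed points — both are tested. The paper-era defaults for κ and the
iteration count are not published anywhere we could consult; these values
preserve edges several times above the post-smoothing noise level and are
all exposed in `pipeline_config()`.

Peaks are found by non-maximum suppression over a *disc* of radius equal to
the bundle width: a pixel is kept if it lies in the pith mask, is maximal
within its disc, and exceeds the in-pith Otsu level (computed over the
observed range, which makes detection invariant to adding a constant).
Plateau ties break toward the smaller (row, col) and no two peaks are
closer than the radius, so detection is fully deterministic. Manual centers
(from the JSON sidecar, replacing the original interactive clicks) are
dropped if outside the pith or within the suppression radius of an existing
center. Density is count / pith area (cm⁻²); a zero pith area is written as
density 0 with a warning rather than NaN.

### Bundle size

A 40 × 40 px patch around each center is enhanced by homomorphic filtering:
`exp(IDFT(H · DFT(log(1+x)))) − 1` with a Gaussian high-emphasis transfer
function (gain 0.5 at DC rising to 1.5, cutoff 8% of the patch side). The
patch is mirror-extended before the transform; without this the DFT's
periodic wrap turns any illumination ramp into a sawtooth whose ringing
dominates a 40-px patch. Two consequences worth knowing: with the default
gains an illumination ramp is attenuated relative to the bundle by ≈16%
(log-domain gains act multiplicatively, and a σ≈4 bundle overlaps the ramp
spectrally in so small a patch), and fitting enhanced rather than raw
patches biases the area measure by ≈3% on ideal blobs. The enhancement step
follows the original protocol; `homomorphic = FALSE` fits raw patches.

A full-covariance 2D Gaussian with constant baseline is fitted by
Levenberg–Marquardt, initialized from intensity moments. The reported
bundle area is the 2σ level-contour ellipse, `π·(2σ_major)·(2σ_minor)`;
"the outermost contour" has no unique numeric meaning, so the multiplier
(default 2) is a config parameter. A fit counts as converged only when the
optimizer succeeds, the center stays inside the patch, the shape matrix is
positive definite, and the amplitude is positive and exceeds three times
its standard error — the significance test is what makes a pure-noise patch
report "no bundle" instead of a tiny spurious ellipse. The per-section
summary averages converged fits only.

### Orchestration

`run_scan()` chains the stages and isolates failures: a section whose rind
segmentation degenerates is reported with its morphometry and NA anatomy
fields instead of aborting the batch, because phenotyping batches must
survive individual damaged sections. `run_batch()` processes every page of
every input (multi-page TIFFs hold one scan per page), writes the trait CSV
(6 significant digits, fixed column order) and one JSON sidecar per scan
with every effective parameter, crop box and bundle center — each CSV
number is reproducible from the sidecar alone, and identical reruns are
byte-identical. Manual intervention is a re-run with an edited sidecar.
Sidecar coordinates are 0-based (row, col) half-open; the in-memory R API
is 1-based. A thin command-line wrapper lives at
`inst/scripts/stalkscan.R`.

## The synthetic generator

`synthetic_spec()`/`generate()` render scanner-like sections with exact
ground truth so every stage is testable without real scans: an antialiased
disc (4× supersampled edges; hard edges make perimeters unstable and are
unlike scanner optics) with a darker rind annulus, rotated-Gaussian
bundles placed by rejection sampling (up to 10⁴ draws per bundle) under a
minimum-spacing constraint, low-amplitude smoothed parenchyma texture, a
planar multiplicative illumination gradient, i.i.d. Gaussian pixel noise,
8-bit quantization, and debris shaped to exercise both filter clauses
(thin strokes with eccentricity > 0.99; blobs below 15 000 px).
`composite_scene()` reproduces the 12-sections-per-scan bed layout.
Identical seeds give bit-identical images and the caller's RNG state is
untouched.

Default realism (one 700×700 px section at 800 dpi): background 18, rind
80, pith 120, bundle peak boost 130 (bundle cores near saturation, roughly
twice parenchyma brightness, as in real scans), σ_major 3.5–5 px with
minor/major 0.7–1, minimum spacing 20 px (= 2 × bundle radius, radius taken
as 2σ), illumination ±15%, noise σ 5, texture amplitude 4. The background
split must dominate the rind/pith split for whole-section Otsu segmentation
to behave as it does on real scans, which constrains the rind level to be
only moderately darker than pith. Bundle centers stay ≥15 px inside the
true pith boundary by default; placing them into the rind band (negative
margin) reproduces the tool's characteristic undercounting, since counting
is pith-restricted by design.

What the generator does **not** emulate: cell-scale tissue texture, the
halo effect of too-thick sections, channel-dependent color, staining, or
damaged/cropped sections. Passing the synthetic validation therefore shows
the algorithmic chain is correct under controlled optics, not that every
real scan will segment cleanly — the per-object failure isolation and the
override mechanism exist for exactly that gap.

## Validation summary

The test suite (all sizes chosen to keep a full run within a few minutes on
one CPU) checks, among others: Otsu against an exhaustive 256-level scan;
thickness against the O(N²) oracle; recovered annulus thickness within 2 px
of truth across filter widths; circle/square/ellipse morphometry against
closed forms; 2D Gaussian recovery over 200 seeded blobs (σ within 1%
noiseless; median area error < 10% at 5% noise); diffusion conservation;
byte-identical reruns; and mean bundle detection recall ≥ 90% over 20
default-realism sections (scripts/acceptance.R recomputes this from
scratch; measured ≈100% at these conditions, the margin coming from the
enforced spacing and the pith margin of the default scene).
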