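---
title: "Methods: membrane geometry, edge dynamics, and fluorescence enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane geometry, edge dynamics, and fluorescence enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the estimators memcurve implements, the synthetic
data they are validated against, and the numerical and design choices behind
the defaults. It is the package's methods reference; the README shows the
user-facing workflow.

## The measurement problem

Curvature-sensing cytoskeletal regulators concentrate at membrane regions
defined by *geometry* — highly curved rims of closing transendothelial
macroapertures (TEMs), saddle-shaped necks, flattening segments of a
lamellipodial edge — rather than by any fixed marker. Quantifying that
preference requires estimating, from segmented fluorescence time-lapse data:
local boundary curvature and its time derivative, local edge velocity, and
fluorescence intensity referenced to the membrane amount, all on a common
angular coordinate; then scoring enrichment in a way whose null behaviour is
known. Each of those steps has failure modes at the pixel scale, which is
why the package ships a generator with closed-form ground truth.

## Boundaries

Segmentation is the classical three-step pipeline: Gaussian smoothing
(default sd 2 px), intensity thresholding (per-frame Otsu by default, a
fixed threshold optionally — both are supported because a global threshold
is preferable when bleaching is negligible and frames must stay strictly
comparable), and optional binary erosion (disc; default radius 0, because
with a symmetric edge-spread the half-maximum threshold already places the
binary edge on the membrane edge; erosion exists for data where the
threshold must be conservative). Interior holes are preserved so TEMs stay
detectable; the largest connected component is kept.

Boundaries are the 0.5 iso-level of the mask, traced by marching squares
with bilinear interpolation (sub-pixel), smoothed by a periodic Gaussian
filter acting in arc length, and resampled to N = 1000 points at equal arc
length. The smoothing stiffness is proportional to contour length. Two
scales are used:

* **Perimeter measurement** (`contour_perimeter`): sd = max(0.5 px,
  0.0055 × perimeter). This balances the two opposing errors of contour
  length estimation — staircase residue (inflates) and curvature shrinkage
  under smoothing, which scales as σ²/r (deflates) — keeping rasterized
  disks of radius 20–50 px within 1–2 % of their analytic perimeter and
  axis-aligned squares within 2 %.
* **TEM curvature profiles** (`tem_edge_profile`): sd = 0.045 × perimeter.
  The osculating-circle fit at scale S = 10 on a 1000-point contour of a
  ~20 px hole spans only ±1.3 px; its sagitta is ~0.01 px, so pixel-scale
  contour noise must be suppressed well below that of the geometric signal.
  The default was chosen by comparing estimated per-bin curvature against
  the generator's analytic curvature (correlation ≈ 0.94, sign agreement of
  the per-bin curvature derivative ≈ 93 % under the default noise model).
  Stronger smoothing begins to displace the boundary at lag lobes and
  biases the normalized fluorescence profile; weaker smoothing lets noise
  dominate the curvature derivative.

Boundaries are stored so the segmented region's interior lies to the left
of the traversal; the outward normal is then the rightward perpendicular.
Orientation is established empirically by sampling the mask a fixed offset
to the left and reversing if needed — robust to any contour-tracer
convention.

## Curvature

At each point P the unique circle through P and the points S indices before
and after it approximates the osculating circle; κ = 1/radius with sign
positive when the center lies on the non-region side. A circular hole in a
cell therefore has κ = +1/r everywhere and a convex cell outline −1/r;
exactly collinear triplets return κ = 0 (infinite radius), not an error.
S defaults to 10 in the 50-bin TEM mode and 44 in the 1000-bin cell-edge
mode. The estimator is exact on analytically sampled circles (the circle
through three of its own points), scale-equivariant (κ → κ/a under
coordinate scaling by a) and rigid-motion invariant to 1e-9 — all covered
by tests against an independent three-point circumcircle oracle.

## Edge velocity

The velocity at boundary point P of frame t is the central difference of
the inside-positive signed Euclidean distance transforms of the masks at
t−1 and t+1, bilinearly interpolated at P, in px/frame (positive = edge
advancing, i.e. cell protruding or hole closing). Two numerical details
matter. First, distance transforms of binary images measure to pixel
centers, overshooting the 0.5-level mask edge by half a pixel on each side;
the signed transform is therefore recentred by −0.5·sign(d). Without this
correction a moving edge (where P flips from inside one mask to outside the
other) picks up a systematic +0.5 px/frame. Second, a literal *average* of
the two transforms (available as `method = "average"`) is ~0 for steady
motion — only the difference form recovers growing/shrinking/static disks
within 0.5 px/frame, which is the accuracy the raster quantization supports.
Conversion to µm/min happens only at reporting, from the stack's
calibration; all estimation is calibration-free in px/frame.

## Angular profiles and the normalized probe

All per-boundary quantities are averaged into equal bins of angle around
the structure's center — 50 bins of 7.2° for TEMs, 1000 bins for a cell
edge. Empty bins propagate as missing values, never zero, and are excluded
from downstream means (zero-filling would bias enrichment scores toward the
null). The normalized probe signal is the per-bin ratio of
background-corrected probe to background-corrected membrane fluorescence
measured in a band obtained by expanding the boundary both ways
(half-width default 2 px).

Two details here were genuinely open and were settled by measuring the
estimator's null behaviour on uniform probes:

* **Background correction.** A rolling-ball top-hat is offered, but on
  frames dominated by a filled-cell plateau an opening cannot remove the
  constant camera offset, and a residual offset makes the probe/membrane
  ratio depend on the local membrane level — which couples to geometry and
  biases the fold-enrichment null upward by ~2 %. The default is therefore
  a scalar local background: the eroded hole interior for TEMs (off-cell by
  construction) and the region beyond a 3 px dilation of the cell for the
  edge mode. With it, a probe proportional to the membrane scores a fold
  enrichment of 1.000 ± noise.
* **Band sampling for open fronts.** For a near-circular TEM, assigning
  band *pixels* to angular bins is well-posed. For an open leading edge,
  1000 bins around the cell centroid leave ≈1 band pixel per bin, sampled
  at a geometry-dependent depth; this produced a spurious negative
  correlation between normalized signal and velocity on uncoupled synthetic
  data. The edge mode therefore samples fluorescence per boundary point by
  averaging bilinear reads at offsets −hw…+hw along the point's normal —
  the per-point realization of the same band — and bins those values.

## Flattening, lagging, and the rotation null

Bins with κ > 0 are classified by the sign of the per-bin curvature time
derivative: flattening (becoming less positively curved, dκ/dt < 0) versus
lagging (becoming more positively curved, dκ/dt > 0); κ ≤ 0 or dκ/dt = 0 is
neither. The derivative defaults to the *central* difference
(κ(t+1) − κ(t−1))/2. The forward difference is available, but it shares the
frame-t segmentation noise with the frame-t fluorescence measurement: a bin
whose contour fluctuates at frame t moves both its label and its normalized
value, a selection effect that inflates the uniform-probe fold enrichment
by ~2 % (isolated by ablating noise sources; Poisson noise alone reproduces
it). The central difference uses only frames t−1 and t+1 for the label and
restores a spread-dominated null.

The pooled fold enrichment of one TEM is mean(normalized | flattening) /
mean(normalized | lagging) over all (frame, bin) samples — one score per
TEM, 1 meaning no preference. Significance comes from a rotation null: at
each offset k the fluorescence bins are circularly shifted by k increments
(7.2° each in the 50-bin mode) while the geometric labels stay fixed, the
per-TEM scores are recomputed, and a two-tailed one-sample t test compares
them with 1 at each offset, with no multiple-testing correction. Offset 0
and a full turn reproduce each other exactly (tested). A genuine spatial
coupling appears as a fold-enrichment peak at zero rotation; the test's
false-positive rate on 200 uniform-probe synthetic TEMs (50 cohorts of 4,
every offset tested) lies within the binomial 95 % bounds of the nominal
5 % — the calibration the test suite re-runs.

## Doughnut enrichment and per-perimeter trends

The signal band is the TEM mask dilated by d1 (default 3 px, exact
Euclidean disc via the distance transform) minus the mask; the background
band is a further d2 dilation minus the first. The enrichment factor E is
the ratio of *raw* per-area band intensities, so a spatially uniform
fluorescence anchors at exactly E = 1; background correction (subtracting
the background per-area mean times the signal-band area) is applied only to
the intensity-per-unit-perimeter quantity that is followed across closure.
Per TEM and channel, the Spearman rank correlation of intensity per
perimeter against frame index (or against perimeter, configurable — the
closure coordinate is a reporting choice) is the unit of between-channel
comparisons.

## Ring diameters

Candidate rings are segmented by white top-hat (disc radius default 8 px),
Otsu threshold and an area filter — a deliberate classical replacement for
trained segmentation, adequate because the synthetic fields are controlled.
Each particle is then re-thresholded at half its peak background-subtracted
intensity (the FWHM band of a PSF-blurred annulus is symmetric about the
ring center line), and the perimeter is measured on the sub-pixel contour:
the mean of outer and inner contour lengths when the particle retains its
hole, the outer contour otherwise. The diameter is d = C/π, reported in nm
via the pixel size. The center-line choice matters: the outer contour alone
overestimates d by roughly the segmented band width (tens of nm at these
scales). Generated 230-nm rings come back with a median within a few
percent and a histogram mode of 230 nm at the stated 20-nm bin width (the
mode is always reported together with its bin width, since it is
binning-dependent).

## The synthetic generator

`make_closing_tem` draws a hole whose boundary is the polar curve
ρ(θ,t) = r(t)·(1 + a·cos(mθ)·g(t)), with r(t) = r0 − c·(t−1) and
g(t) = exp(−(t−1)/τ). The decaying mode-m lag supplies both flattening and
lagging regions — a perfectly circular closing hole is everywhere lagging,
since κ = 1/r only rises. Curvature, its exact time derivative, and the
normal edge speed are closed-form; the test suite checks the curvature
formula against a dense finite-difference oracle to 0.5 % (relative to the
mean curvature scale — pointwise κ touches zero at the lobe troughs when
a·g·(m²−1) approaches 1). The probe deposits b0 + b1·max(κ,0) +
b2·max(−∂κ/∂t,0) per unit arc length along the rim (bilinear splatting), or
is exactly proportional to the membrane channel for null studies. Channels
are blurred by a unit-sum Gaussian PSF (default σ 2 px; total intensity is
conserved to 1e-6, tested), then Poisson shot noise (scale 1 photon per
intensity unit), Gaussian read noise (sd 2) and a constant background (5)
are applied. One master seed spawns named substreams (placement, Poisson,
read, scramble), so switching one noise source off does not shift another's
draws, and identical parameters + seed give bit-identical stacks.

Default study conditions: 128×128 px at 110 nm/px and 5 s/frame, cell disc
radius 45 % of the field, r0 = 22 px, closure 1.5 px/frame over 8 frames,
lag mode 3 with amplitude 0.1 and τ = 3 frames, membrane density 100,
b0 = 60. The parameter-recovery scenario (a cohort generated to have an
analytic pooled fold enrichment of exactly 1.5, solved in closed form from
the geometry via `tem_coupling_for_fold`) uses a slower closure
(1.0 px/frame) with a = 0.15, τ = 2.5, so that the flattening drive is not
swamped by the secular curvature increase of closure — a scenario-design
choice, not a fit to data. The probe has no cytosolic pool by default (a
`cytosol_level` parameter exists); real probes always have one, which
dilutes fold enrichments toward 1, so recovered effect sizes on real data
should be read as lower bounds.

`make_leading_edge` advances a front y(x,t) with a developing sinusoidal
lag, giving per-column analytic speeds (guards reject retreating columns
and overhanging fronts), and deposits c0 + coupling·v per unit front
length. `make_ring_field` places non-overlapping annuli with truth-table
diameters drawn from a normal distribution (default 230 ± 25 nm at
23 nm/px, thickness 2 px).

What the generator does **not** emulate: membrane mechanics or actin
biochemistry (the geometry is purely kinematic), probe residence time on
the membrane (no temporal convolution of the deposit — an instantaneous
coupling), intensity inhomogeneity across the cell, depth effects, drift,
or segmentation-adversarial clutter. Passing tests therefore demonstrate
estimator correctness under a known forward model, not robustness to every
property of real acquisitions.

## Problem sizes and determinism

The test suite validates on 128×128 (TEM) and 256×256 (rings) fields,
cohorts of 3–4 TEMs, and a 200-TEM calibration of the rotation null —
sizes at which every ground-truth comparison is exact or tightly bounded
and the whole suite runs in a few minutes. All pipelines are pure functions
of (inputs, config, seed); rerunning a persisted config reproduces output
CSVs byte-for-byte, and each CSV carries a provenance header with the
package version and a hash of the analysis-relevant config fields.

## Known limitations

* Velocity accuracy is quantization-limited near points where the edge
  moves tangentially (worst-case pointwise error ≈ 0.5 px/frame).
* The curvature derivative at S = 10 on holes much smaller than ~15 px
  radius is noise-dominated at realistic photon budgets; the boundary
  smoothing default assumes hole radii of roughly 10–60 px.
* The fold-enrichment estimator normalizes by the membrane channel;
  membrane-channel artifacts (e.g. local dye
  inhomogeneity) propagate into the score. The rotation null controls for
  geometry-linked artifacts but not for artifacts that co-rotate with the
  fluorescence.
* Protrusion width is a one-pixel-thick chord count at half the extension
  length; for protrusions narrower than ~2 px it is quantized.
* No 3-D geometry: the saddle interpretation of TEM rims is biological
  framing; only in-plane curvature is computed.
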