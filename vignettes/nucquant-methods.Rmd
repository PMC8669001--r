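---
title: "Methods: nuclear architecture and adhesion quantification in nucquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear architecture and adhesion quantification in nucquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucquant)
```

`nucquant` quantifies three image-derived phenotypes of nuclear-envelope
perturbation — heterochromatin redistribution away from the nuclear
periphery, repositioning of gene loci, and a blunted adhesion/spreading
mechanoresponse — and ships a phantom generator with exact ground truth
so that every stage can be validated without access to original
micrographs. This vignette documents the measurement models, the
parameters that matter, the numerical choices, and what validation on
phantoms does and does not establish.

## Coordinate and intensity conventions

Arrays are indexed `[y, x]` (2D) or `[y, x, z]` (3D); pixel `i` along an
axis has its center at `(i − 0.5) · pixel_size` µm, so all exported
coordinates and distances are physical. Intensities are arbitrary
nonnegative units; every readout below is either dimensionless (a ratio
of means, a relative position) or carries µm units, so calibration of
the intensity axis is never required.

## The peripheral band and intensity ratios

The nucleus mask comes from the DNA stain: Gaussian smoothing
(`smoothing_scale`, default 0.5 µm — about two pixels at typical 60×
sampling), Otsu's threshold, hole filling, 8-connected labeling,
removal of border-touching objects (their band and centroid geometry is
truncated) and of objects under `min_area` (default 20 µm²).

The *nuclear periphery* is defined as the band of pixels lying within a
fixed fraction of the equivalent radius from the nuclear edge:

> band = { p in nucleus : d(p, edge) ≤ f · r_eq },  r_eq = √(area/π)

with `band_fraction` f = 0.25 by default, i.e. the region 25% towards
the interior from the nuclear edge. The depth is realized on the exact
Euclidean distance transform of the mask complement, which makes the
band rotation-invariant and shape-robust; for a 4 µm-radius nucleus the
default depth is 1 µm, the magnitude reported for such bands in
practice. The phrase "25% towards the interior" admits a second reading
— 25% of each pixel's own centroid-to-edge distance — which is exposed
as `partition_periphery(method = "ray")` but is not the default: it is
an order of magnitude slower and less stable for elongated nuclei,
while agreeing with the distance-transform band on near-circular ones.

Two numerical details matter. First, pixel-center-to-pixel-center
distances overshoot the true mask edge by about half a pixel, so the
band test subtracts `0.5 · min(pixel_size)`; on an analytic disk of
radius ≥ 50 px this brings the band-area fraction within about 1% of the
exact annulus value `1 − 0.75² = 0.4375`. Second, the band is defined
*identically* at synthesis and at analysis: the phantom generator calls
`partition_periphery()` itself when distributing marker signal, so the
specified peripheral fraction is recoverable exactly (to float
precision) on noiseless phantoms, rather than up to a second,
inconsistent band definition.

The readouts are ratios of *mean* (not integrated) intensities —
band/whole-nucleus, and focus-union/whole-nucleus — so they are
invariant to exposure and to nuclear size. A spatially uniform channel
gives exactly 1. No background subtraction is applied by default
(phantoms are background-free and the measurement is a ratio of means
over the same nucleus); nuclei with a degenerate band (interior
swallowed) or zero total intensity are excluded and counted in a QC
log rather than contributing sentinel values. A nucleus with no
detected focus records a *missing* foci ratio, never zero.

Heterochromatic foci are segmented per nucleus: a white top-hat at
`focus_scale` (default 1 µm, slightly above the expected focus radius)
suppresses the nucleoplasm plateau, and Otsu's threshold is applied to
the top-hat response *within each nucleus*. Per-nucleus thresholding was
chosen over a global one because inter-nuclear brightness differences
otherwise leak into focus calls; the choice is invisible on phantoms
(identical nuclei) but safer on real data.

## FISH spot metrics

Spots are detected by a scale-normalized Laplacian-of-Gaussian
(implemented as a difference of Gaussians at σ and 1.6σ,
`spot_scale` default 0.3 µm), restricted to nuclear masks. Local maxima
count plateaus as candidates — a blob centered between pixel centers
ties across neighbors and would otherwise vanish — and duplicates are
suppressed by a window around each accepted peak. Peaks must exceed
`snr_min` (default 3) times the robust noise level, estimated as
1.4826 × MAD of the intranuclear response about zero. Centers are then
refined to subpixel precision by an intensity-weighted centroid in a
small window of the raw channel; on phantoms at SNR ≥ 10 the centroid
error is below 0.5 px.

The relative radial position of a spot normalizes out nuclear size:

> r = d(centroid, spot) / d(centroid, P)

where P is the first crossing of the nuclear boundary by the ray from
the (unweighted mask) centroid through the spot — the three-point
centroid → spot → periphery construction. The denominator is found by
marching along the ray in 0.1 px steps with the exit interpolated
midway between the last inside and first outside sample, and r is
clamped to [0, 1]. A spot at the centroid returns 0 by definition; for
non-convex masks the *first* crossing is used. The centroid is
geometric, not intensity-weighted, so the metric does not couple to
staining intensity. Uniformly rescaling nucleus and spot coordinates
leaves r unchanged, which is the point of the normalization; on disks,
r is exact to within boundary pixelization (± 0.02 at R = 100 px).

Distance to the nearest heterochromatic focus is read off the Euclidean
distance transform of the focus-mask complement, evaluated at the
spot's pixel: 0 inside a focus, and within one pixel diagonal of the
brute-force minimum over focus pixels otherwise. The transform is the
exact separable (Felzenszwalb–Huttenlocher) algorithm with per-axis
spacing, so 3D stacks with Z spacing ≫ XY are handled without
resampling; when a field has no focus the metric is recorded as
missing, not zero. Positions are reported per condition as empirical
cumulative distribution frequencies (ties share a step), and group
comparisons are performed on the r values themselves with the
Mann–Whitney test, not on the ECDF curves.

## Focal adhesions and cell spreading

Cell bodies are segmented from the cell-body (phalloidin) channel like
nuclei (smooth, Otsu, fill, size-filter ≥ 50 µm²), with border-touching
cells excluded so spreading areas are whole-cell quantities. The
adhesion channel is band-pass filtered with a difference of Gaussians,
σ_low = 0.2 µm to σ_high = 1.0 µm, bracketing typical punctum radii;
the response is exactly zero-mean on constant input and linear.

Segmentation thresholds the response per cell at `mean + k·SD` computed
inside that cell, an adaptive rule that absorbs per-cell background
differences. The default is `k_threshold = 1.5`. This value is a
deliberate design choice: the per-cell SD of the response is inflated
by the puncta themselves, so large multipliers (e.g. 3) cut each
punctum far above its half-maximum and shrink recovered areas by 40%
and more, while k = 1.5 keeps per-cell counts exact on noiseless
phantoms, within ±1 at SNR 5, and areas within about 15% of truth for
puncta of radius ≥ 4 px. Raising k always *shrinks* the above-threshold
pixel set (a guaranteed monotonicity), but the object *count* is only
monotone while puncta stay isolated — a higher threshold can split two
puncta whose response lobes merged at a lower one, which is why the
count property is validated on isolated-punctum configurations.
Adhesions touching the cell border are kept; each adhesion belongs to
exactly one cell by construction. Per-cell summaries report count,
total and mean adhesion area, and the spreading area; a cell with no
adhesions is a valid all-zero row.

## The statistics layer

Per-object measurements tie frequently (pixel-derived values) and are
skewed, so all group comparisons are rank-based, reported with
median, IQR and per-group n:

- **Two groups** — two-tailed Mann–Whitney U. The p-value is the exact
  enumeration value when min(n₁, n₂) ≤ 8 and the pooled sample is
  tie-free (verified in tests against an independent enumeration over
  all C(N, n₁) assignments), and otherwise the normal approximation on
  mid-ranks with tie-corrected variance and continuity correction. Its
  type-I error at α = 0.05 is calibrated to within Monte-Carlo error
  (1000 null simulations land in [0.03, 0.07]).
- **Three or more groups** — Kruskal–Wallis H with tie correction,
  followed by Dunn's pairwise z-tests on the pooled mid-ranks with the
  same tie-corrected variance. The family-wise adjustment is Bonferroni
  over all pairs — the multiplicity rule is recorded in the output —
  chosen because it is the conventional family-wise control applied to
  Dunn's test and requires no distributional assumptions. When the
  pooled data are entirely constant there is no rank variation and H is
  defined as 0 (the textbook formula degenerates to 0/0).
- **One group** — descriptive output only, no test.

No outliers are excluded anywhere; exclusions happen only at the QC
stage (degenerate geometry, zero intensity) and are logged with
reasons, so reported n means "objects analyzed".

## What the phantoms emulate — and what they do not

A `phantom_spec()` describes: elliptical nuclei (semi-axes drawn from
`nucleus_radii`, random orientation) with a nucleoplasm level and
`focus_gain`-fold brighter circular foci; a marker channel whose
integrated per-nucleus signal is split exactly `f_p` : (1 − f_p)
between the peripheral band and the interior; FISH spots rendered as
Gaussian blobs centered at analytically exact relative positions on
their azimuth rays; cells with disk puncta at `adhesion_gain`-fold over
cytoplasm; and Poisson–Gaussian noise,
`I → Poisson(I·photon_scale)/photon_scale + N(0, σ)`, applied last so
the ground truth is noiseless. Defaults emulate a 60× confocal field:
0.2 µm pixels, nuclei of 3.5–5 µm semi-axis, four chromocenter-like
foci per nucleus at 3× gain, a dozen adhesion puncta per 10 µm cell at
5× gain, photon noise at a scale giving SNR ≈ 10 on a level-100
channel plus σ = 2 read noise.

Two RNG streams are derived from the master seed — one for geometry,
one for noise — so geometry can be held fixed while noise realizations
vary (`noise_seed`), and two-condition experiments derive independent
per-field seeds from one master seed, making every dataset bit-for-bit
reproducible.

Geometric validity constraints are part of the generator's contract:
nuclei/cells keep a 5 px clearance from the field border (so
analysis-time smoothing cannot push a segmented object into the
border-exclusion rule) and an 8 px clearance from each other (so
smoothing cannot fuse two objects into one component); puncta keep a
minimum edge-to-edge gap (`punctum_gap`, default 1 µm) so that discrete
ground-truth counts are resolvable in principle. Without these, "the
field contains N objects" would be false as a statement about the
rendered image, not merely hard to measure. Placement is by rejection
sampling with whole-set restarts; infeasible requests fail with a
placement error rather than silently overlapping.

The phantoms deliberately omit: optical PSF simulation (blobs are
rendered Gaussians, edges are hard), chromatin texture inside the
nucleoplasm, touching or overlapping nuclei, drift and photobleaching,
and 3D rendering (phantoms are 2D; the distance transform, the radial
position and the focus-distance metric accept 3D masks with
anisotropic voxels, but segmentation operates on 2D fields). Passing
tests on phantoms therefore establishes correctness of the *geometry
and measurement chain* — band definitions, distance maps, ratios,
normalizations, statistics — not robustness to PSF blur, clumped
nuclei, or uneven illumination on real micrographs. Touching nuclei on
real data are out of scope by design: they would require watershed
splitting, and the border/merging rules here simply exclude or flag
pathological objects.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on generated
data at desk scale: analytic disks of 50–100 px radius for geometric
exactness; 100 random focus configurations for the distance-map oracle;
2000 area-uniform spots in a disk for the closed-form `F(r) = r²`
radial law (KS distance ≤ 0.05); 200 noisy nuclei across a
`f_p ∈ [0.2, 0.8]` sweep for rank-correlation recovery (Spearman
ρ ≥ 0.9); 10 cells × 12 puncta for count recovery; 1000 null
simulations for type-I calibration; and 20 seeded replicates per
readout for two-condition directionality. These sizes were chosen so
that the full suite completes in a couple of minutes while keeping
Monte-Carlo error well inside each criterion's margin.

## Known limitations

- Segmentation is threshold-based (Otsu); heavily textured or dim real
  data may need the smoothing and minimum-area parameters retuned, and
  genuinely touching nuclei are not split.
- The band depth uses the global equivalent radius; for strongly
  non-convex nuclei the "ray" variant may be preferable, at cost.
- The DoG scales and threshold multiplier are stated defaults, not
  values inferred from any particular instrument; they should be
  checked against punctum sizes in new data.
- TIFF export is 32-bit float with a YAML sidecar for pixel size and
  channel names; proprietary microscope containers (CZI/ND2) are not
  read.
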