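---
title: "Methods: PA/US quantification of hypopigmented skin lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PA/US quantification of hypopigmented skin lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paskin)
```

## Scope and model

`paskin` quantifies hypopigmented skin lesions (vitiligo, idiopathic
guttate hypomelanosis) from co-registered 3D photoacoustic (PA) and
ultrasound (US) volumes. At 680 nm the PA amplitude of skin is dominated
by epidermal melanin, with a secondary contribution from dermal
hemoglobin. The pipeline turns one scan into four scalar lesion metrics:

* **mean PA amplitude** of the lesion (residual pigment load),
* **local SD** of the amplitude inside the lesion (pigment granularity,
  e.g. focal "skip areas"),
* **mean PA slope** across the lesion boundary (abruptness of
  demarcation),
* **relative PA peak depth** `d_L - d_N` (how far pigment loss exposes
  deeper absorbers).

The scan model assumes: (i) frames are acquired at sinusoidal
(Scotch-yoke) elevational positions `y_k = (L/2) (1 - cos(pi k/(K-1)))`,
uniform in motor angle, so the native grid must be resampled before any
isotropic 2D analysis; (ii) the US channel shows the skin surface as the
shallowest strong echo in each column; (iii) within a shallow window below
the surface the PA maximum reflects skin pigment rather than vasculature.

## Pipeline stages and their parameters

All fixed constants live in `pipeline_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `us_threshold_frac` | 0.5 | fraction of frame max | surface candidate threshold; relative so per-frame gain cancels |
| `surface_min_component_px` | 50 | px | smallest 8-connected US component kept (≈ 40 % of a 128-column contour one row thick); scale down for narrower frames |
| `max_jump_px` | 5 | px | lateral continuity bound; outlier columns re-interpolated |
| `window_mm` | 1.0 | mm | depth retained below the surface; covers epidermis plus superficial dermis while excluding deeper vessels |
| `saturation_percentiles` | (1, 99) | % | robust range for amplitude normalization |
| `blur_sigma_px` | 2 | px (0.2 mm) | pre-Otsu smoothing against an overfitted boundary |
| `otsu_bins` | 256 | — | fixed equal-width histogram on [0, 1] |
| `min_component_px` | 100 | px (1 mm²) | mask cleanup: smaller lesion islands / normal holes reassigned |
| `slope_offset_px` | 5 | px (0.5 mm) | inward/outward sampling distance for the boundary slope |
| `sd_window_px` | 5 | px (0.5 mm) | local-SD filter window |
| `depth_tail_frac` | 0.15 | — | tail fraction for `d_N` (shallowest normal) and `d_L` (deepest lesion) |
| `iqr_bounds` | (0.25, 0.75) | — | trimmed range of sorted boundary slopes |
| `min_lesion_contrast` | 0.2 | — | minimum raw-amplitude deficit for a scan to count as lesion-bearing |

The window size, boundary offset, depth tails, and slope trimming are the
published analysis constants; thresholds, blur, and component sizes are
this package's documented choices where the published account names a step
but not a value.

## Numerical choices

* **Otsu threshold**: between-class variance is maximized over the 255
  interior bin edges of a fixed 256-bin histogram on [0, 1]; ties (within
  1e-12) break toward the *smallest* edge. Fewer than two distinct values
  is a degenerate error, which `segment_lesion()` converts into a
  lesion-free flag.
* **Lesion polarity**: the lesion is the *low*-amplitude Otsu class by
  construction; the code asserts the below-threshold class is darker and
  errors otherwise rather than silently swapping.
* **Lesion-free guard**: normalization stretches even pure noise to
  [0, 1], so Otsu always "finds" a split. A scan is only lesion-bearing if
  the candidate lesion's mean *raw* amplitude is at most
  `1 - min_lesion_contrast` (default 80 %) of the normal class mean. A
  uniformly pigmented scan therefore returns a flagged empty segmentation
  and `NA` metrics.
* **Argmax ties** in the depth projection break toward the shallowest
  sample; all-zero columns get amplitude 0, depth 0, and a flag.
* **Resampling** is separable 1D linear interpolation (elevation first,
  then lateral), which reproduces linear fields exactly and cannot
  overshoot; the uniform grid covers exactly the native extent with end
  values clamped (no extrapolation).
* **Boundary normals** come from the gradient of the smoothed lesion
  mask, negated to point outward; boundary pixels with a degenerate
  gradient are dropped from slope sampling. Slope sampling uses
  nearest-pixel rounding at ±5 px (no sub-pixel interpolation), and the
  pair is kept only if the inward sample lands in the lesion and the
  outward sample in normal skin.
* **Local SD** uses the sample SD (n−1) and averages only interior
  pixels: the full 5 × 5 window must lie inside the lesion and contain no
  boundary pixel, implementing the stated exclusion of boundary-driven
  outliers. Whether to average over all lesion pixels instead was an open
  choice; interior-only is the reading consistent with that exclusion.
* **Tail counts** for the depth metric use the ceiling (`⌈0.15 n⌉`), and
  IQR membership for slopes uses inclusive linear-rank bounds
  (`(i-1)/(n-1)` within [0.25, 0.75]); neither rounding is prescribed by
  the published description, so both are fixed here and tested against
  sorting oracles.
* **Rank-sum test**: exact enumeration of all rank assignments (mid-ranks
  for ties) when `n1 + n2 <= 12`; otherwise a normal approximation with
  tie correction and continuity correction. Full enumeration of the
  untied 6 + 6 null shows the approximation's worst-case two-sided error
  is 0.0155 with continuity correction (0.069 without), which is why the
  correction is the default and why the cross-check test uses a 0.016
  bound. Two-sided p-values are `min(1, 2·min(P(W ≤ w), P(W ≥ w)))`. No
  multiplicity correction is applied across the four metrics, and reports
  say so.
* **Storage**: volumes are written as multi-page TIFF (PA pages then US
  pages) with a YAML geometry sidecar. Samples sit on a fixed-point grid
  after exact power-of-two rescaling; on load they are snapped to a
  24-bit fraction grid — the precision of a 32-bit float mantissa — which
  makes repeated save/load cycles bit-stable. Sidecar numerics are
  serialized as `%.17g` strings so geometry round-trips exactly.
* **Indexing** is 1-based throughout (R convention); depth windows are
  half-open `[surface, surface + window)`.

## What the phantom emulates — and what it does not

`generate_phantom()` renders: a curved (optionally tilted) skin surface;
a Gaussian epidermal melanin band (FWHM `epidermis_thickness_mm`,
default 0.2 mm) truncated at the surface; an elliptical lesion whose
pigment falls to `residual_fraction` through a logistic edge whose 10–90 %
width is `border_width_mm`; optional focal pigment islands (Poisson count
from `island_density_per_cm2`, Gaussian radial profiles, radii drawn
around `island_radius_mm`), confined to the lesion; a dermal vessel sheet
(superficial vascular plexus) at `vessel_depth_mm` (default 0.8 mm, inside
the default 1.0 mm analysis window) at 10 % of the melanin amplitude; and
additive Gaussian noise clipped at zero. The US channel is Rayleigh
speckle below a sharp specular surface echo six times the speckle mean —
bright enough that a relative threshold always isolates the contour, which
is the only property the pipeline consumes. All randomness flows from one
seeded generator per scan.

The two presets encode the study conditions:

* `vit_phantom_config()` — near-total pigment loss (residual 0.05), wide
  2.0 mm border, no islands: depigmentation exposes the vessel sheet, so
  the PA peak moves deep.
* `igh_phantom_config()` — residual 0.2, sharply demarcated 0.3 mm
  border, islands at 40/cm², mean radius 0.25 mm, 80 % amplitude.
  The island scale follows histology reports of skip areas from ~100 µm
  upward; the density is chosen so islands cover roughly 10 % of the
  lesion — several per biopsy-sized field, making island texture (not
  projection noise) the dominant source of local SD, as the clinical
  account attributes it.

The phantom deliberately omits: acoustic propagation and reconstruction
artifacts, optical fluence decay with depth, motion, discrete vessel
trees (the plexus is a uniform sheet), epidermal thickness variation, and
any absolute calibration of PA amplitude. Passing phantom tests therefore
demonstrates the *pipeline's* correctness and the metrics' directional
behavior under controlled contrast — not clinical performance on real
tissue, where speckle statistics, fluence, and anatomy are richer.

Residual fractions for the two presets are modeling choices, not measured
facts: the clinical source reports metric outputs, not generative tissue
parameters. They were fixed from the disease descriptions (vitiligo:
near-total melanocyte loss; IGH: partial loss with retained foci) and the
requirement that each preset's dominant absorber (vessel sheet vs
epidermal residue) match the described peak-depth behavior.

One direction is intentionally not engineered: with these presets the
vitiligo-like mean amplitude comes out slightly *above* the IGH-like one
(the normalization maps each scan's own 1st percentile to zero, which
penalizes the group whose lesion fills more of the low tail), whereas the
clinical report found IGH slightly higher. The clinical difference was
the weakest of the four metrics; the three that the cohort-level checks
rely on (slope, local SD, peak depth) reproduce their directions.

## Problem sizes

Tests run phantoms at two scales: a small 21 × 60 × 40 geometry (6 mm
sweep) for unit-level properties, and the full 83 × 80 × 128 geometry
(25 mm sweep, 251 × 382 uniform grid) for end-to-end recovery. The
directional cohort check uses 10 + 10 full-size scans; simulated-cohort
significance uses 200 replicates of 36 + 17 normal draws per metric; null
calibration uses 2000 replicates. These sizes were chosen as the smallest
that exercise every code path with stable statistics.

## Known limitations

* ROI handling on real data (`detect_roi()`) assumes the tape band is
  near-zero in amplitude; irregular taping needs a manual mask.
* The boundary slope uses per-pixel gradient normals; a very ragged
  boundary yields noisy normals, mitigated but not eliminated by mask
  smoothing and IQR trimming.
* Multiple lesion components pool their boundary slopes before trimming;
  per-component metrics are available but the headline metric is pooled.
* The exact rank-sum path enumerates all `C(N, n1)` subsets and is
  restricted to `N <= 12`; beyond that the corrected normal approximation
  is used regardless of ties.
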