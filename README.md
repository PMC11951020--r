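# paskin

Quantitative analysis of hypopigmented skin lesions from co-registered 3D
photoacoustic (PA) and ultrasound (US) scans.

## The problem

Distinguishing early vitiligo from idiopathic guttate hypomelanosis (IGH)
by eye is hard: both present as pale macules, and conventional adjuncts
(Wood's lamp, dermoscopy) are qualitative. PA imaging at 680 nm is
dominated by melanin absorption, so a 3D PA/US sweep over a lesion carries
quantitative information about how much epidermal pigment remains, how it
is spatially distributed, how abruptly it changes at the lesion border, and
whether pigment loss exposes deeper (dermal, hemoglobin) absorbers.

`paskin` implements that analysis as a reusable pipeline for volumes
acquired with a linear-array scanner swept elevationally by a Scotch-yoke
mechanism (frames at sinusoidal positions), plus a parametric phantom
generator so the entire pipeline can be exercised, validated, and power-
analyzed without clinical data.

## The method

For a scan with PA/US volumes indexed (frame *Y*, depth *Z*, lateral *X*):

1. **Surface detection** — per US frame, threshold at a fraction of the
   frame maximum, clean by 8-connected component analysis, take the
   shallowest surviving candidate per column, interpolate gaps:
   the skin contour *z*ₛ(*x*, *y*).
2. **Depth windowing** — keep PA samples in [*z*ₛ, *z*ₛ + *w*), default
   *w* = 1.0 mm, discarding deeper vascular signal.
3. **Projection** — maximum amplitude projection A(*x*, *y*) =
   max_*z* PA and peak depth D(*x*, *y*) = argmax depth − *z*ₛ (mm), then
   separable linear interpolation from the sinusoidal frame positions and
   0.3 mm pitch onto a uniform 0.1 mm grid.
4. **Segmentation** — normalize/saturate A within the ROI to [0, 1],
   Gaussian-blur, Otsu-threshold (256 fixed bins); the lesion is the
   low-amplitude class; components below 100 px are reassigned; boundary
   pixels and outward unit normals are extracted.
5. **Metrics** (per lesion):
   - *mean PA amplitude*: mean of the normalized A over lesion pixels;
   - *local SD*: mean of a 5 × 5 sample-SD filter over interior lesion
     pixels (windows touching the boundary excluded);
   - *mean PA slope*: at each boundary pixel, sample A at ±5 px along the
     normal, slope = ΔA / 1.0 mm, then average the inter-quartile range
     (25–75 %) of the sorted slopes;
   - *relative PA peak depth*: d_L − d_N, where d_N is the mean of the
     shallowest 15 % of normal-skin peak depths and d_L the mean of the
     deepest 15 % of lesion peak depths.
6. **Group comparison** — two-sided Wilcoxon rank-sum per metric (exact
   enumeration for small samples, tie- and continuity-corrected normal
   approximation otherwise).

## Worked example

Generate an IGH-like phantom (sharply demarcated lesion, 20 % residual
pigment, focal pigment islands) and push it through the pipeline:

```r
library(paskin)
ph  <- generate_phantom(igh_phantom_config(seed = 42))
res <- analyze_scan(ph$volume)
print(res)
#> lesion_segmentation: 1 component(s), 9374 lesion px / 86508 normal px, thr 0.5234
#> lesion_metrics 'phantom-42'
#>   mean amplitude    0.0829
#>   local SD          0.0398
#>   mean slope        0.9077 /mm
#>   rel peak depth    0.0385 mm (d_L 0.1362 - d_N 0.0978)
```

The lesion covers ~9400 px of the 0.1 mm grid (≈ 94 mm², matching the
configured 6 × 5 mm semi-axis ellipse). The steep border gives a high mean
slope (0.91 normalized units/mm), the pigment islands a high local SD, and
the retained pigment keeps the PA peak near the epidermis (relative depth
≈ 0.04 mm).

A two-group phantom cohort separates the diseases the same way the metrics
are designed to:

```r
coh <- generate_cohort(n_vit = 5, n_igh = 5, seed = 1)
run_cohort(coh)
#> cohort_result: 10 lesions
#>             metric group n       mean           sd
#>     mean_amplitude   IGH 5 0.08663864 0.0072037920
#>     mean_amplitude   VIT 5 0.10699277 0.0036714422
#>           local_sd   IGH 5 0.04040919 0.0027266100
#>           local_sd   VIT 5 0.02097425 0.0006419708
#>         mean_slope   IGH 5 0.91515024 0.0044636992
#>         mean_slope   VIT 5 0.49827144 0.0041322193
#>  rel_peak_depth_mm   IGH 5 0.03769227 0.0013414626
#>  rel_peak_depth_mm   VIT 5 0.73195730 0.0025984091
#>
#> Two-sided Wilcoxon rank-sum tests (no multiplicity correction):
#>             metric     p_value
#>     mean_amplitude 0.007936508
#>           local_sd 0.007936508
#>         mean_slope 0.007936508
#>  rel_peak_depth_mm 0.007936508
```

IGH-like scans score a higher boundary slope and local SD and a much
shallower relative peak depth than vitiligo-like scans — full rank
separation at n = 5 + 5 (p = 2/C(10,5) · 2, the exact-test floor).

A thin CLI wrapping these functions ships in `inst/scripts/paskin`
(`simulate`, `run`, `report` subcommands).

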