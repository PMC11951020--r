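#' Elevational frame positions of a Scotch-yoke scanner
#'
#' The handheld scanner steps its linear array along the elevation (Y) axis
#' with a Scotch-yoke mechanism, which converts uniform motor rotation into
#' sinusoidal linear motion. Frames are therefore acquired at uniform motor
#' angle, i.e. at positions on a cosine ramp: spacing is densest at the two
#' ends of the sweep and coarsest in the middle.
#'
#' @param K number of frames (>= 2).
#' @param span_mm total elevational sweep in mm (> 0).
#' @return Numeric vector of `K` strictly increasing positions in mm,
#'   `y_k = (span_mm / 2) * (1 - cos(pi * k / (K - 1)))` for `k = 0..K-1`;
#'   the first is 0 and the last is `span_mm`.
#' @examples
#' y <- elevational_positions(83, 25)
#' range(diff(y))          # dense at the ends, coarse in the middle
#' @export
elevational_positions <- function(K, span_mm) {
  if (length(K) != 1L || !is.finite(K) || K < 2 || K != round(K))
    stop("invalid geometry: K must be an integer >= 2", call. = FALSE)
  if (length(span_mm) != 1L || !is.finite(span_mm) || span_mm <= 0)
    stop("invalid geometry: span_mm must be > 0", call. = FALSE)
  k <- seq_len(K) - 1
  (span_mm / 2) * (1 - cos(pi * k / (K - 1)))
}

#' Scan geometry of a co-registered PA/US volume
#'
#' Describes the acquisition grid of one 3D scan: `n_frames` elevational
#' (Y) frames, each a B-mode image of `n_axial` depth (Z) samples by
#' `n_lateral` array elements (X). Defaults follow an 8.5 MHz, 128-element
#' linear array with 0.3 mm pitch sweeping 25 mm in 83 frames at 680 nm.
#'
#' @param n_frames number of elevational frames (K).
#' @param n_lateral number of lateral array elements.
#' @param n_axial number of axial (depth) samples per frame.
#' @param lateral_pitch_mm element pitch along X, in mm.
#' @param axial_spacing_mm axial sample spacing along Z, in mm.
#' @param elevation_span_mm total elevational sweep along Y, in mm.
#' @param elevation_positions_mm frame positions along Y; defaults to the
#'   Scotch-yoke cosine ramp ([elevational_positions()]). Must be strictly
#'   increasing from 0 to `elevation_span_mm`.
#' @param wavelength_nm optical excitation wavelength (melanin-weighted
#'   default 680 nm); informational.
#' @param uniform_step_mm target step of the uniform projection grid, in mm.
#' @return An object of class `scan_geometry` (a validated list).
#' @export
scan_geometry <- function(n_frames = 83L,
                          n_lateral = 128L,
                          n_axial = 80L,
                          lateral_pitch_mm = 0.3,
                          axial_spacing_mm = 0.05,
                          elevation_span_mm = 25.0,
                          elevation_positions_mm =
                            elevational_positions(n_frames, elevation_span_mm),
                          wavelength_nm = 680,
                          uniform_step_mm = 0.1) {
  g <- structure(list(
    n_frames = as.integer(n_frames),
    n_lateral = as.integer(n_lateral),
    n_axial = as.integer(n_axial),
    lateral_pitch_mm = as.numeric(lateral_pitch_mm),
    axial_spacing_mm = as.numeric(axial_spacing_mm),
    elevation_span_mm = as.numeric(elevation_span_mm),
    elevation_positions_mm = as.numeric(elevation_positions_mm),
    wavelength_nm = as.numeric(wavelength_nm),
    uniform_step_mm = as.numeric(uniform_step_mm)
  ), class = "scan_geometry")
  validate_scan_geometry(g)
}

validate_scan_geometry <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  if (g$n_frames < 2L)
    stop("invalid geometry: n_frames must be >= 2", call. = FALSE)
  sp <- c(g$lateral_pitch_mm, g$axial_spacing_mm, g$elevation_span_mm,
          g$uniform_step_mm)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("invalid geometry: all spacings must be positive", call. = FALSE)
  p <- g$elevation_positions_mm
  if (length(p) != g$n_frames || any(diff(p) <= 0))
    stop("invalid geometry: elevation positions must be strictly increasing ",
         "with one entry per frame", call. = FALSE)
  if (abs(p[1]) > 1e-9 || abs(p[length(p)] - g$elevation_span_mm) > 1e-9)
    stop("invalid geometry: elevation positions must run from 0 to the span",
         call. = FALSE)
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan_geometry: %d frames x %d axial x %d lateral\n",
              x$n_frames, x$n_axial, x$n_lateral))
  cat(sprintf("  pitch %.3g mm (X), axial %.3g mm (Z), span %.3g mm (Y), %g nm\n",
              x$lateral_pitch_mm, x$axial_spacing_mm, x$elevation_span_mm,
              x$wavelength_nm))
  invisible(x)
}

#' Pipeline configuration
#'
#' Fixed constants of the quantification pipeline. Defaults reproduce the
#' published analysis where it states a value (5 x 5 SD window, 5-pixel
#' boundary offset, 15% depth tails, 25-75% slope trimming) and make
#' documented choices where it does not (relative US threshold, component
#' sizes, blur width, saturation percentiles).
#'
#' @param us_threshold_frac per-frame surface threshold, as a fraction of
#'   that frame's US maximum.
#' @param surface_min_component_px minimum 8-connected component size (px)
#'   a US candidate region must reach to contribute to the surface contour.
#' @param max_jump_px largest lateral surface jump (px) tolerated before a
#'   column is treated as an outlier and re-interpolated.
#' @param window_mm depth window retained below the detected surface, mm.
#' @param saturation_percentiles length-2 percentiles (0-100) used to
#'   saturate the amplitude map before normalization to `[0, 1]`.
#' @param blur_sigma_px Gaussian blur sigma (px) applied before Otsu
#'   thresholding, preventing an overfitted boundary.
#' @param otsu_bins number of equal-width histogram bins on `[0, 1]`.
#' @param min_component_px minimum component size (px) kept during mask
#'   cleanup; smaller lesion islands or normal holes are reassigned.
#' @param slope_offset_px offset (px) of the inward/outward samples used by
#'   the boundary slope, measured along the boundary normal.
#' @param sd_window_px side (px) of the square local-SD filter; odd.
#' @param depth_tail_frac tail fraction for the peak-depth metric (bottom
#'   tail of normal skin, top tail of the lesion).
#' @param iqr_bounds length-2 rank fractions retained when trimming the
#'   boundary-slope samples.
#' @param min_lesion_contrast minimum fractional raw-amplitude deficit the
#'   candidate lesion class must show against normal skin (lesion mean at
#'   most `1 - min_lesion_contrast` times the normal mean) before a scan
#'   counts as lesion-bearing; guards against segmenting pure noise
#'   texture on uniformly pigmented skin.
#' @param rng_seed optional integer seed recorded for provenance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(us_threshold_frac = 0.5,
                            surface_min_component_px = 50L,
                            max_jump_px = 5L,
                            window_mm = 1.0,
                            saturation_percentiles = c(1, 99),
                            blur_sigma_px = 2,
                            otsu_bins = 256L,
                            min_component_px = 100L,
                            slope_offset_px = 5L,
                            sd_window_px = 5L,
                            depth_tail_frac = 0.15,
                            iqr_bounds = c(0.25, 0.75),
                            min_lesion_contrast = 0.2,
                            rng_seed = NULL) {
  cfg <- structure(list(
    us_threshold_frac = us_threshold_frac,
    surface_min_component_px = as.integer(surface_min_component_px),
    max_jump_px = as.integer(max_jump_px),
    window_mm = window_mm,
    saturation_percentiles = saturation_percentiles,
    blur_sigma_px = blur_sigma_px,
    otsu_bins = as.integer(otsu_bins),
    min_component_px = as.integer(min_component_px),
    slope_offset_px = as.integer(slope_offset_px),
    sd_window_px = as.integer(sd_window_px),
    depth_tail_frac = depth_tail_frac,
    iqr_bounds = iqr_bounds,
    min_lesion_contrast = min_lesion_contrast,
    rng_seed = rng_seed
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$us_threshold_frac <= 0 || cfg$us_threshold_frac >= 1)
    stop("us_threshold_frac must be in (0, 1)", call. = FALSE)
  if (cfg$depth_tail_frac <= 0 || cfg$depth_tail_frac >= 0.5)
    stop("depth_tail_frac must be in (0, 0.5)", call. = FALSE)
  if (length(cfg$iqr_bounds) != 2L || cfg$iqr_bounds[1] >= cfg$iqr_bounds[2] ||
      cfg$iqr_bounds[1] < 0 || cfg$iqr_bounds[2] > 1)
    stop("iqr_bounds must satisfy 0 <= lower < upper <= 1", call. = FALSE)
  if (cfg$sd_window_px %% 2L != 1L || cfg$sd_window_px < 1L)
    stop("sd_window_px must be odd and positive", call. = FALSE)
  if (length(cfg$saturation_percentiles) != 2L ||
      cfg$saturation_percentiles[1] >= cfg$saturation_percentiles[2])
    stop("saturation_percentiles must be an increasing pair", call. = FALSE)
  if (cfg$window_mm <= 0) stop("window_mm must be > 0", call. = FALSE)
  if (cfg$min_lesion_contrast < 0 || cfg$min_lesion_contrast >= 1)
    stop("min_lesion_contrast must be in [0, 1)", call. = FALSE)
  cfg
}
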