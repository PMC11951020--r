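#' Run the full quantification pipeline on one scan
#'
#' Stages: skin-surface detection from the US channel; PA depth windowing
#' below the surface; maximum-amplitude and peak-depth projection;
#' resampling to the uniform grid; amplitude normalization/saturation
#' within the ROI; lesion segmentation; and the four lesion metrics.
#'
#' @param volume a [pa_us_volume()].
#' @param cfg a [pipeline_config()].
#' @param roi logical ROI matrix on the uniform grid; `NULL` (default)
#'   uses the full grid, `"auto"` runs [detect_roi()].
#' @return An object of class `pa_scan_analysis`: `surface`, `windowed_pa`
#'   is not retained, `native`, `maps`, `norm_map`, `segmentation`,
#'   `metrics`, `cfg`.
#' @examples
#' ph <- generate_phantom(phantom_config(seed = 7))
#' res <- analyze_scan(ph$volume)
#' res$metrics
#' @export
analyze_scan <- function(volume, cfg = pipeline_config(), roi = NULL) {
  volume <- validate_pa_us_volume(volume)
  g <- volume$geometry
  surface <- detect_surface(volume$us, cfg)
  wpa <- window_pa(volume$pa, surface, cfg$window_mm, g)
  native <- project_maps(wpa, surface, g)
  maps <- resample_uniform(native, g)
  if (is.null(roi)) {
    roi <- matrix(TRUE, nrow(maps$amplitude), ncol(maps$amplitude))
  } else if (identical(roi, "auto")) {
    roi <- detect_roi(maps)
  }
  norm_map <- normalize_saturate(maps$amplitude, roi,
                                 cfg$saturation_percentiles)
  seg <- segment_lesion(norm_map, roi, cfg, raw_map = maps$amplitude)
  metrics <- compute_lesion_metrics(maps, norm_map, seg, cfg,
                                    scan_id = volume$scan_id,
                                    group_label =
                                      if (is.null(volume$group_label)) NA
                                      else volume$group_label)
  structure(list(surface = surface, native = native, maps = maps,
                 norm_map = norm_map, segmentation = seg,
                 metrics = metrics, cfg = cfg),
            class = "pa_scan_analysis")
}

#' @export
print.pa_scan_analysis <- function(x, ...) {
  print(x$segmentation)
  print(x$metrics)
  invisible(x)
}

#' Run the pipeline over a cohort
#'
#' @param scans either a list of [pa_us_volume()] objects, a list of
#'   phantom `(volume, truth)` pairs from [generate_cohort()], or the
#'   path of a cohort manifest CSV ([read_cohort_manifest()]).
#' @param cfg a [pipeline_config()].
#' @param roi as in [analyze_scan()], applied to every scan.
#' @return A `cohort_result` ([cohort_summary()]), whose `per_lesion`
#'   table has one row per scan.
#' @export
run_cohort <- function(scans, cfg = pipeline_config(), roi = NULL) {
  if (is.character(scans)) {
    man <- read_cohort_manifest(scans)
    scans <- lapply(man$path, load_scan)
  }
  vols <- lapply(scans, function(s)
    if (inherits(s, "pa_us_volume")) s else s$volume)
  metrics <- lapply(vols, function(v) analyze_scan(v, cfg, roi)$metrics)
  cohort_summary(metrics_table(metrics))
}
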