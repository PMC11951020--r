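# Shared fixtures. Heavy objects are computed once per test session.

small_geometry <- function(n_frames = 21L, n_lateral = 40L, n_axial = 60L,
                           span = 6.0) {
  scan_geometry(n_frames = n_frames, n_lateral = n_lateral,
                n_axial = n_axial, elevation_span_mm = span)
}

small_phantom_config <- function(...) {
  args <- list(geometry = small_geometry(),
               lesion_center_mm = c(5.85, 3.0),
               lesion_semiaxes_mm = c(3, 1.8),
               surface_curvature_mm = 0.1)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

# hand-built straight-edge segmentation: lesion = columns <= split,
# boundary at column `split`, normals pointing toward +col (normal side)
straight_edge_segmentation <- function(nr, nc, split, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nr, nc)
  lesion <- matrix(FALSE, nr, nc); lesion[, seq_len(split)] <- TRUE
  lesion <- lesion & roi
  normal <- roi & !lesion
  pts <- cbind(seq_len(nr), rep(split, nr))
  nrm <- cbind(rep(0, nr), rep(1, nr))
  structure(list(roi_mask = roi, lesion_mask = lesion, normal_mask = normal,
                 boundary = list(pts), normals = list(nrm),
                 threshold_used = NA_real_, lesion_free = FALSE,
                 n_components = 1L),
            class = "lesion_segmentation")
}

# component threshold scaled to the 40-column small-geometry frames
small_surface_cfg <- function(...) {
  pipeline_config(surface_min_component_px = 20L, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default-geometry noise-free phantom with a sharp border, and its analysis
sharp_phantom <- function() cached("sharp_phantom", {
  generate_phantom(phantom_config(noise_sd_frac = 0, border_width_mm = 0.2,
                                  residual_fraction = 0.05, seed = 5))
})

sharp_analysis <- function() cached("sharp_analysis", {
  suppressMessages(analyze_scan(sharp_phantom()$volume))
})
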