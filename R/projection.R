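#' Project the windowed PA volume to native-grid amplitude and depth maps
#'
#' For each (frame, lateral) column, the amplitude map holds the maximum
#' PA value inside the depth window (maximum amplitude projection) and the
#' depth map holds the depth of that peak below the detected surface, in
#' mm. Argmax ties break toward the shallowest sample. Columns that are
#' all zero get amplitude 0 and depth 0 and are flagged.
#'
#' @param windowed_pa windowed PA array from [window_pa()].
#' @param surface the `surface_map` used for windowing.
#' @param geometry the [scan_geometry()].
#' @return An object of class `native_maps`: `amplitude` and `depth_mm`
#'   matrices `[frame, lateral]`, logical `zero_flag`, and the native
#'   `x_positions_mm` / `y_positions_mm`.
#' @export
project_maps <- function(windowed_pa, surface, geometry) {
  stopifnot(length(dim(windowed_pa)) == 3L, inherits(surface, "surface_map"))
  K <- dim(windowed_pa)[1]; nz <- dim(windowed_pa)[2]
  nlat <- dim(windowed_pa)[3]
  m <- matrix(aperm(windowed_pa, c(1, 3, 2)), K * nlat, nz)
  j <- max.col(m, ties.method = "first")
  amp <- m[cbind(seq_len(K * nlat), j)]
  zero <- amp <= 0
  j[zero] <- NA
  amplitude <- matrix(amp, K, nlat)
  depth <- (matrix(j, K, nlat) - round(surface$surface_idx)) *
    geometry$axial_spacing_mm
  depth[matrix(zero, K, nlat)] <- 0
  structure(list(
    amplitude = amplitude,
    depth_mm = depth,
    zero_flag = matrix(zero, K, nlat),
    x_positions_mm = (seq_len(nlat) - 1) * geometry$lateral_pitch_mm,
    y_positions_mm = geometry$elevation_positions_mm
  ), class = "native_maps")
}

# separable 1D linear interpolation from native positions to uniform grid
resample_matrix <- function(m, y_pos, x_pos, y_out, x_out) {
  if (any(diff(y_pos) <= 0) || any(diff(x_pos) <= 0))
    stop("geometry error: native positions must be strictly increasing",
         call. = FALSE)
  tmp <- apply(m, 2, function(col)
    stats::approx(y_pos, col, xout = y_out, rule = 2)$y)
  t(apply(tmp, 1, function(row)
    stats::approx(x_pos, row, xout = x_out, rule = 2)$y))
}

#' Resample native maps to the uniform projection grid
#'
#' Interpolates first along the elevation (Y) axis — converting the
#' sinusoidal Scotch-yoke frame spacing into a uniform step — and then
#' along the lateral (X) axis from the array pitch to the same step
#' (default 0.1 mm). Interpolation is linear and separable; the uniform
#' grid covers exactly the native extent (no extrapolation), and the depth
#' map goes through the identical operator as the amplitude map.
#'
#' @param native a `native_maps` from [project_maps()].
#' @param geometry the [scan_geometry()].
#' @return An object of class `map_images`: `amplitude`, `depth_mm`
#'   (matrices `[Y, X]` on the uniform grid), `grid_step_mm`,
#'   `grid_origin_mm`, and the grid axes `x_mm`, `y_mm`.
#' @export
resample_uniform <- function(native, geometry) {
  stopifnot(inherits(native, "native_maps"))
  step <- geometry$uniform_step_mm
  y_out <- seq(0, geometry$elevation_span_mm, by = step)
  x_out <- seq(0, (geometry$n_lateral - 1) * geometry$lateral_pitch_mm,
               by = step)
  amp <- resample_matrix(native$amplitude, native$y_positions_mm,
                         native$x_positions_mm, y_out, x_out)
  dep <- resample_matrix(native$depth_mm, native$y_positions_mm,
                         native$x_positions_mm, y_out, x_out)
  structure(list(
    amplitude = amp,
    depth_mm = dep,
    grid_step_mm = step,
    grid_origin_mm = c(0, 0),
    x_mm = x_out,
    y_mm = y_out
  ), class = "map_images")
}

#' @export
print.map_images <- function(x, ...) {
  cat(sprintf("map_images: %d x %d (Y x X) at %.3g mm step\n",
              nrow(x$amplitude), ncol(x$amplitude), x$grid_step_mm))
  invisible(x)
}
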