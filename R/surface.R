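#' Detect the skin surface from the US channel
#'
#' Per frame, candidate surface pixels are those at or above a relative
#' intensity threshold (`us_threshold_frac` times the frame maximum, so
#' detection is invariant to per-frame gain). Candidates are refined by
#' 8-connected component analysis — components smaller than
#' `surface_min_component_px` are discarded as speckle/outliers — and the
#' surface is the shallowest surviving candidate in each lateral column.
#' Columns without a candidate are filled by linear interpolation from
#' valid neighbours (nearest value at the edges), and columns that jump
#' more than `max_jump_px` from the local running median are treated as
#' outliers and re-interpolated, so the contour is laterally continuous.
#'
#' @param us 3D US array `[frame, axial, lateral]` (or a
#'   [pa_us_volume()], whose US channel is used).
#' @param cfg a [pipeline_config()].
#' @return An object of class `surface_map`: `surface_idx` (numeric matrix
#'   `[frame, lateral]` of 1-based axial indices) and `frame_valid`
#'   (logical per frame; frames with no candidate anywhere are filled from
#'   neighbouring frames and flagged invalid).
#' @export
detect_surface <- function(us, cfg = pipeline_config()) {
  if (inherits(us, "pa_us_volume")) us <- us$us
  stopifnot(length(dim(us)) == 3L)
  K <- dim(us)[1]; nz <- dim(us)[2]; nlat <- dim(us)[3]
  surf <- matrix(NA_real_, K, nlat)
  frame_valid <- rep(TRUE, K)

  for (k in seq_len(K)) {
    fr <- us[k, , ]
    thr <- cfg$us_threshold_frac * max(fr)
    cand <- fr >= thr
    if (!any(cand) || max(fr) <= 0) {
      frame_valid[k] <- FALSE
      message("detect_surface: frame ", k, " has no surface candidate")
      next
    }
    lab <- label8(cand)
    sizes <- component_sizes(lab)
    keep <- which(sizes >= cfg$surface_min_component_px)
    if (length(keep) == 0L) {
      frame_valid[k] <- FALSE
      message("detect_surface: frame ", k,
              " has no component >= surface_min_component_px")
      next
    }
    cand <- matrix(lab %in% keep, nz, nlat)
    idx <- rep(NA_real_, nlat)
    hit <- which(cand, arr.ind = TRUE)
    if (nrow(hit)) {
      first <- tapply(hit[, 1], hit[, 2], min)
      idx[as.integer(names(first))] <- as.numeric(first)
    }
    surf[k, ] <- fill_and_refine(idx, cfg$max_jump_px)
  }

  if (!any(frame_valid))
    stop("detect_surface: no frame yields a surface", call. = FALSE)
  if (any(!frame_valid)) {
    ok <- which(frame_valid)
    for (j in seq_len(nlat)) {
      surf[!frame_valid, j] <- stats::approx(ok, surf[ok, j],
                                             xout = which(!frame_valid),
                                             rule = 2)$y
    }
  }
  structure(list(surface_idx = surf, frame_valid = frame_valid),
            class = "surface_map")
}

# interpolate missing columns, then suppress jumps against a running median
fill_and_refine <- function(idx, max_jump_px) {
  n <- length(idx)
  interp <- function(v) {
    ok <- which(!is.na(v))
    if (length(ok) == 0L) return(v)
    if (length(ok) == 1L) return(rep(v[ok], n))
    stats::approx(ok, v[ok], xout = seq_len(n), rule = 2)$y
  }
  v <- interp(idx)
  med <- stats::runmed(v, k = min(5L, n - (1 - n %% 2)))
  bad <- abs(v - med) > max_jump_px
  if (any(bad) && !all(bad)) {
    v[bad] <- NA_real_
    v <- interp(v)
  }
  v
}

#' Window the PA volume to the skin layer
#'
#' Keeps PA samples in the half-open axial window
#' `[surface_idx, surface_idx + window_px)` below the detected surface of
#' each column and zeroes everything else, removing deeper signal such as
#' dermal blood vessels. `window_px = round(window_mm / axial_spacing_mm)`
#' (at least 1); windows running past the bottom of the volume are
#' truncated with a message.
#'
#' @param pa 3D PA array `[frame, axial, lateral]`.
#' @param surface a `surface_map` from [detect_surface()].
#' @param window_mm window depth in mm.
#' @param geometry the [scan_geometry()].
#' @return The windowed 3D array, with attribute `window_px`.
#' @export
window_pa <- function(pa, surface, window_mm, geometry) {
  stopifnot(length(dim(pa)) == 3L, inherits(surface, "surface_map"))
  K <- dim(pa)[1]; nz <- dim(pa)[2]; nlat <- dim(pa)[3]
  wpx <- max(1L, as.integer(round(window_mm / geometry$axial_spacing_mm)))
  s <- round(surface$surface_idx)                     # [K, nlat]
  if (any(s + wpx - 1L > nz))
    message("window_pa: window truncated at the bottom of the volume for ",
            sum(s + wpx - 1L > nz), " column(s)")
  z_idx <- aperm(array(seq_len(nz), dim = c(nz, K, nlat)), c(2, 1, 3))
  s_arr <- aperm(array(s, dim = c(K, nlat, nz)), c(1, 3, 2))
  keep <- z_idx >= s_arr & z_idx < s_arr + wpx
  out <- pa * keep
  attr(out, "window_px") <- wpx
  out
}
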