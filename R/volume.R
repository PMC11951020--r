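#' Co-registered PA/US volume
#'
#' Bundles the photoacoustic and ultrasound intensity grids of one scan
#' with its geometry. Both arrays are indexed `[frame (Y), axial (Z),
#' lateral (X)]`, 1-based, and must be finite and non-negative.
#'
#' @param pa,us 3D numeric arrays of identical dimension
#'   `c(n_frames, n_axial, n_lateral)`.
#' @param geometry a [scan_geometry()].
#' @param scan_id character scan identifier.
#' @param group_label optional group label (e.g. `"VIT"`, `"IGH"`).
#' @return An object of class `pa_us_volume`.
#' @export
pa_us_volume <- function(pa, us, geometry, scan_id = "scan",
                         group_label = NULL) {
  v <- structure(list(pa = pa, us = us, geometry = geometry,
                      scan_id = as.character(scan_id),
                      group_label = group_label),
                 class = "pa_us_volume")
  validate_pa_us_volume(v)
}

validate_pa_us_volume <- function(v) {
  stopifnot(inherits(v, "pa_us_volume"))
  g <- validate_scan_geometry(v$geometry)
  dpa <- dim(v$pa); dus <- dim(v$us)
  if (length(dpa) != 3L || length(dus) != 3L || !identical(dpa, dus))
    stop("format error: PA and US grids must be 3D arrays of identical shape",
         call. = FALSE)
  if (!identical(dpa, c(g$n_frames, g$n_axial, g$n_lateral)))
    stop("format error: grid shape ", paste(dpa, collapse = "x"),
         " does not match geometry ",
         paste(c(g$n_frames, g$n_axial, g$n_lateral), collapse = "x"),
         call. = FALSE)
  if (anyNA(v$pa) || anyNA(v$us) || any(!is.finite(v$pa)) ||
      any(!is.finite(v$us)))
    stop("data error: PA/US values must be finite (no NaN/NA/Inf)",
         call. = FALSE)
  if (min(v$pa) < 0 || min(v$us) < 0)
    stop("data error: PA/US values must be non-negative", call. = FALSE)
  v
}

#' @export
print.pa_us_volume <- function(x, ...) {
  cat(sprintf("pa_us_volume '%s'%s: %d x %d x %d (frame x axial x lateral)\n",
              x$scan_id,
              if (is.null(x$group_label)) "" else paste0(" [", x$group_label, "]"),
              dim(x$pa)[1], dim(x$pa)[2], dim(x$pa)[3]))
  invisible(x)
}

# exact %.17g serialization so sidecar numerics round-trip bit-for-bit
.num_out <- function(x) vapply(as.numeric(x), function(z) sprintf("%.17g", z), "")
.num_in <- function(x) as.numeric(x)

sidecar_path <- function(path) sub("\\.tiff?$", ".yaml", path)

#' Save a PA/US volume as multi-page TIFF plus YAML sidecar
#'
#' Writes one multi-page TIFF (`n_frames` PA pages followed by `n_frames`
#' US pages, each an axial-by-lateral frame) and a YAML sidecar carrying
#' the geometry, identifiers, and amplitude scaling. Samples are stored on
#' a fixed-point `[0, 1]` grid; amplitudes are first divided by a
#' power-of-two scale (recorded in the sidecar) so the rescaling itself is
#' exact. The canonical stored precision is a 24-bit fraction (the
#' precision of a 32-bit float mantissa): one save/load cycle quantizes to
#' that grid and every further cycle is bit-identical.
#'
#' @param volume a [pa_us_volume()].
#' @param path output path ending in `.tif`; the sidecar is written next
#'   to it with extension `.yaml`.
#' @return `path`, invisibly.
#' @export
save_scan <- function(volume, path) {
  volume <- validate_pa_us_volume(volume)
  if (!grepl("\\.tiff?$", path)) path <- paste0(path, ".tif")
  g <- volume$geometry
  pow2_scale <- function(x) {
    m <- max(x)
    if (m <= 1) 0L else as.integer(ceiling(log2(m)))
  }
  kpa <- pow2_scale(volume$pa); kus <- pow2_scale(volume$us)
  pages <- c(
    lapply(seq_len(g$n_frames), function(k) volume$pa[k, , ] / 2^kpa),
    lapply(seq_len(g$n_frames), function(k) volume$us[k, , ] / 2^kus)
  )
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("I/O error: cannot write '", path, "'", call. = FALSE)
  side <- list(
    format = "paskin-scan",
    scan_id = volume$scan_id,
    group_label = if (is.null(volume$group_label)) "" else volume$group_label,
    pa_scale_log2 = kpa,
    us_scale_log2 = kus,
    geometry = list(
      n_frames = g$n_frames, n_lateral = g$n_lateral, n_axial = g$n_axial,
      lateral_pitch_mm = .num_out(g$lateral_pitch_mm),
      axial_spacing_mm = .num_out(g$axial_spacing_mm),
      elevation_span_mm = .num_out(g$elevation_span_mm),
      elevation_positions_mm = .num_out(g$elevation_positions_mm),
      wavelength_nm = .num_out(g$wavelength_nm),
      uniform_step_mm = .num_out(g$uniform_step_mm)
    )
  )
  writeLines(yaml::as.yaml(side), sidecar_path(path))
  invisible(path)
}

#' Load a PA/US volume saved by [save_scan()]
#'
#' @param path path to the `.tif` written by [save_scan()]; the YAML
#'   geometry sidecar must sit next to it.
#' @return A validated [pa_us_volume()].
#' @export
load_scan <- function(path) {
  if (!file.exists(path))
    stop("I/O error: '", path, "' does not exist", call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("format error: geometry sidecar '", sp, "' is missing", call. = FALSE)
  side <- yaml::yaml.load_file(sp)
  if (is.null(side$geometry))
    stop("format error: sidecar lacks geometry", call. = FALSE)
  gs <- side$geometry
  geometry <- scan_geometry(
    n_frames = gs$n_frames, n_lateral = gs$n_lateral, n_axial = gs$n_axial,
    lateral_pitch_mm = .num_in(gs$lateral_pitch_mm),
    axial_spacing_mm = .num_in(gs$axial_spacing_mm),
    elevation_span_mm = .num_in(gs$elevation_span_mm),
    elevation_positions_mm = .num_in(gs$elevation_positions_mm),
    wavelength_nm = .num_in(gs$wavelength_nm),
    uniform_step_mm = .num_in(gs$uniform_step_mm)
  )
  pages <- tiff::readTIFF(path, all = TRUE)
  K <- geometry$n_frames
  if (length(pages) != 2L * K)
    stop("format error: expected ", 2L * K, " TIFF pages, found ",
         length(pages), call. = FALSE)
  to_array <- function(pp, scale) {
    a <- array(0, dim = c(K, geometry$n_axial, geometry$n_lateral))
    for (k in seq_len(K)) {
      pg <- pp[[k]]
      if (!identical(dim(pg)[1:2],
                     c(geometry$n_axial, geometry$n_lateral)))
        stop("format error: page shape does not match geometry", call. = FALSE)
      # snap to the 24-bit fraction grid: the canonical stored precision,
      # stable under repeated save/load cycles
      a[k, , ] <- round(as.vector(pg) * 2^24) / 2^24 * scale
    }
    a
  }
  pa <- to_array(pages[seq_len(K)], 2^side$pa_scale_log2)
  us <- to_array(pages[K + seq_len(K)], 2^side$us_scale_log2)
  grp <- side$group_label
  if (is.null(grp) || identical(grp, "")) grp <- NULL
  pa_us_volume(pa, us, geometry, scan_id = side$scan_id, group_label = grp)
}

#' Read / write a cohort manifest
#'
#' A cohort manifest is a CSV with columns `scan_id`, `path`,
#' `group_label`; `path` entries are interpreted relative to the manifest
#' location when not absolute.
#'
#' @param scans data frame with columns `scan_id`, `path`, `group_label`.
#' @param file CSV path.
#' @return `read_cohort_manifest` returns the data frame with `path`
#'   resolved; `write_cohort_manifest` returns `file` invisibly.
#' @export
write_cohort_manifest <- function(scans, file) {
  stopifnot(all(c("scan_id", "path", "group_label") %in% names(scans)))
  utils::write.csv(scans[, c("scan_id", "path", "group_label")], file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort_manifest
#' @export
read_cohort_manifest <- function(file) {
  m <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("scan_id", "path", "group_label") %in% names(m)))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(file), m$path[rel])
  m
}
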