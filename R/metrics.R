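#' Mean PA amplitude of the lesion
#'
#' Arithmetic mean of the normalized amplitude over lesion pixels; tracks
#' the overall amount of residual pigment.
#'
#' @param norm_map normalized `[0, 1]` amplitude map.
#' @param lesion_mask logical lesion mask.
#' @return Scalar mean.
#' @export
mean_amplitude <- function(norm_map, lesion_mask) {
  if (!any(lesion_mask))
    stop("undefined metric: empty lesion mask", call. = FALSE)
  mean(norm_map[lesion_mask])
}

#' Sliding-window local SD image
#'
#' Sample standard deviation (denominator n-1) of each `window_px` x
#' `window_px` neighbourhood; `NA` where the full window does not fit.
#'
#' @param x numeric matrix.
#' @param window_px odd window side.
#' @return Matrix of local SDs.
#' @export
local_sd_image <- function(x, window_px = 5L) {
  stopifnot(window_px %% 2L == 1L)
  n <- window_px^2
  s1 <- box_sum(x, window_px)
  s2 <- box_sum(x * x, window_px)
  v <- (s2 - s1^2 / n) / (n - 1)
  v[!is.na(v) & v < 0] <- 0
  sqrt(v)
}

#' Local-SD metric of the lesion interior
#'
#' Mean of the local SD image over interior lesion pixels: pixels whose
#' full window lies inside the lesion and contains no boundary pixel, so
#' boundary-driven outliers never enter the average. Captures the
#' granularity of residual pigment (e.g. focal "skip areas").
#'
#' @param norm_map normalized amplitude map.
#' @param lesion_mask logical lesion mask.
#' @param boundary_px n x 2 matrix of `[row, col]` boundary pixels (or a
#'   `lesion_segmentation`, whose boundary pixels are pooled).
#' @param window_px odd SD-filter window side.
#' @return Scalar metric; errors when the lesion has no interior pixel.
#' @export
local_sd_metric <- function(norm_map, lesion_mask, boundary_px,
                            window_px = 5L) {
  if (inherits(boundary_px, "lesion_segmentation"))
    boundary_px <- do.call(rbind, boundary_px$boundary)
  bmask <- matrix(FALSE, nrow(norm_map), ncol(norm_map))
  if (!is.null(boundary_px) && NROW(boundary_px) > 0)
    bmask[boundary_px] <- TRUE
  n <- window_px^2
  full_lesion <- box_sum(lesion_mask * 1.0, window_px)
  any_boundary <- box_sum(bmask * 1.0, window_px)
  interior <- !is.na(full_lesion) & full_lesion == n & any_boundary == 0 &
    lesion_mask
  if (!any(interior))
    stop("undefined metric: lesion too small for an interior window",
         call. = FALSE)
  sd_img <- local_sd_image(norm_map, window_px)
  mean(sd_img[interior])
}

#' Boundary-slope metric
#'
#' At each boundary pixel, samples the normalized amplitude `offset_px`
#' pixels inward (along the inward normal, in the lesion) and `offset_px`
#' pixels outward (in normal skin), with nearest-pixel rounding. Pairs
#' whose inward sample is not in the lesion mask or whose outward sample
#' is not in the normal mask are discarded. Each slope is the amplitude
#' difference divided by the 2 x `offset_px` x `grid_step_mm` separation;
#' samples are pooled over all components, sorted, and averaged over the
#' inter-quartile range (inclusive linear-rank bounds).
#'
#' @param norm_map normalized amplitude map.
#' @param segmentation a `lesion_segmentation`.
#' @param offset_px sampling offset in pixels.
#' @param iqr_bounds length-2 rank fractions retained.
#' @param grid_step_mm uniform grid step, mm.
#' @return List with `mean_slope` (normalized units per mm; positive when
#'   normal skin outranks the lesion), `slope_samples`, `n_used`.
#' @export
boundary_slope_metric <- function(norm_map, segmentation, offset_px = 5L,
                                  iqr_bounds = c(0.25, 0.75),
                                  grid_step_mm = 0.1) {
  stopifnot(inherits(segmentation, "lesion_segmentation"))
  nr <- nrow(norm_map); nc <- ncol(norm_map)
  slopes <- numeric(0)
  for (i in seq_along(segmentation$boundary)) {
    pts <- segmentation$boundary[[i]]
    nrm <- segmentation$normals[[i]]
    if (NROW(pts) == 0L) next
    outp <- round(pts + offset_px * nrm)
    inp <- round(pts - offset_px * nrm)
    ok <- outp[, 1] >= 1 & outp[, 1] <= nr & outp[, 2] >= 1 & outp[, 2] <= nc &
      inp[, 1] >= 1 & inp[, 1] <= nr & inp[, 2] >= 1 & inp[, 2] <= nc
    outp <- outp[ok, , drop = FALSE]; inp <- inp[ok, , drop = FALSE]
    if (nrow(outp) == 0L) next
    valid <- segmentation$normal_mask[outp] & segmentation$lesion_mask[inp]
    if (!any(valid)) next
    d_mm <- 2 * offset_px * grid_step_mm
    slopes <- c(slopes,
                (norm_map[outp[valid, , drop = FALSE]] -
                 norm_map[inp[valid, , drop = FALSE]]) / d_mm)
  }
  if (length(slopes) < 4L)
    stop("undefined metric: fewer than 4 usable boundary pixels",
         call. = FALSE)
  s <- sort(slopes)
  n <- length(s)
  f <- (seq_len(n) - 1) / (n - 1)
  keep <- f >= iqr_bounds[1] - 1e-12 & f <= iqr_bounds[2] + 1e-12
  list(mean_slope = mean(s[keep]), slope_samples = slopes,
       n_used = sum(keep))
}

#' Relative PA peak-depth metric
#'
#' `d_N` is the mean of the shallowest `tail_frac` fraction (ceiling
#' count) of normal-skin peak depths; `d_L` the mean of the deepest
#' `tail_frac` fraction of lesion peak depths. Their difference
#' `d_L - d_N` grows when epidermal pigment loss exposes deeper (dermal)
#' absorbers inside the lesion.
#'
#' @param depth_mm peak-depth map (mm below the surface).
#' @param lesion_mask,normal_mask logical masks.
#' @param tail_frac tail fraction in `(0, 0.5)`.
#' @return List with `rel_depth_mm`, `d_N_mm`, `d_L_mm`.
#' @export
peak_depth_metric <- function(depth_mm, lesion_mask, normal_mask,
                              tail_frac = 0.15) {
  if (!any(lesion_mask) || !any(normal_mask))
    stop("undefined metric: empty lesion or normal mask", call. = FALSE)
  dn <- sort(depth_mm[normal_mask])
  dl <- sort(depth_mm[lesion_mask], decreasing = TRUE)
  kn <- ceiling(tail_frac * length(dn))
  kl <- ceiling(tail_frac * length(dl))
  d_N <- mean(dn[seq_len(kn)])
  d_L <- mean(dl[seq_len(kl)])
  list(rel_depth_mm = d_L - d_N, d_N_mm = d_N, d_L_mm = d_L)
}

#' Compute the four lesion metrics of one scan
#'
#' @param maps a `map_images` ([resample_uniform()]).
#' @param norm_map the normalized amplitude map used for segmentation.
#' @param segmentation a `lesion_segmentation`.
#' @param cfg a [pipeline_config()].
#' @param scan_id,group_label identifiers carried into the result.
#' @return An object of class `lesion_metrics` with fields
#'   `mean_amplitude`, `local_sd`, `mean_slope`, `rel_peak_depth_mm`,
#'   `d_N_mm`, `d_L_mm`, `slope_samples`, pixel counts, and identifiers.
#'   Metrics that are undefined for the scan (e.g. lesion-free) are `NA`
#'   and listed in `undefined`.
#' @export
compute_lesion_metrics <- function(maps, norm_map, segmentation,
                                   cfg = pipeline_config(),
                                   scan_id = "scan", group_label = NA) {
  res <- list(mean_amplitude = NA_real_, local_sd = NA_real_,
              mean_slope = NA_real_, rel_peak_depth_mm = NA_real_,
              d_N_mm = NA_real_, d_L_mm = NA_real_,
              slope_samples = numeric(0),
              n_lesion_px = sum(segmentation$lesion_mask),
              n_normal_px = sum(segmentation$normal_mask),
              n_boundary_px = sum(vapply(segmentation$boundary, NROW, 0L)),
              scan_id = scan_id, group_label = group_label,
              undefined = character(0))
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$undefined <<- c(res$undefined, name)
      message("metric '", name, "' undefined for ", scan_id, ": ",
              conditionMessage(e))
      NULL
    })
  }
  if (!segmentation$lesion_free) {
    v <- grab("mean_amplitude",
              mean_amplitude(norm_map, segmentation$lesion_mask))
    if (!is.null(v)) res$mean_amplitude <- v
    v <- grab("local_sd",
              local_sd_metric(norm_map, segmentation$lesion_mask,
                              segmentation, cfg$sd_window_px))
    if (!is.null(v)) res$local_sd <- v
    v <- grab("mean_slope",
              boundary_slope_metric(norm_map, segmentation,
                                    cfg$slope_offset_px, cfg$iqr_bounds,
                                    maps$grid_step_mm))
    if (!is.null(v)) {
      res$mean_slope <- v$mean_slope
      res$slope_samples <- v$slope_samples
    }
    v <- grab("rel_peak_depth",
              peak_depth_metric(maps$depth_mm, segmentation$lesion_mask,
                                segmentation$normal_mask,
                                cfg$depth_tail_frac))
    if (!is.null(v)) {
      res$rel_peak_depth_mm <- v$rel_depth_mm
      res$d_N_mm <- v$d_N_mm
      res$d_L_mm <- v$d_L_mm
    }
  } else {
    res$undefined <- c("mean_amplitude", "local_sd", "mean_slope",
                       "rel_peak_depth")
  }
  structure(res, class = "lesion_metrics")
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf("lesion_metrics '%s'%s\n", x$scan_id,
              if (is.na(x$group_label)) "" else paste0(" [", x$group_label, "]")))
  cat(sprintf("  mean amplitude    %.4f\n", x$mean_amplitude))
  cat(sprintf("  local SD          %.4f\n", x$local_sd))
  cat(sprintf("  mean slope        %.4f /mm\n", x$mean_slope))
  cat(sprintf("  rel peak depth    %.4f mm (d_L %.4f - d_N %.4f)\n",
              x$rel_peak_depth_mm, x$d_L_mm, x$d_N_mm))
  invisible(x)
}
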