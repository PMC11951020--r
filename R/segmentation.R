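#' Normalize and saturate an amplitude map within a region of interest
#'
#' Clips the map to the given lower/upper ROI percentiles, then affinely
#' maps that range to `[0, 1]`, making the lesion/normal contrast explicit
#' and absorbing any positive affine rescaling of the raw amplitudes.
#' Pixels outside the ROI are set to 0.
#'
#' @param amplitude 2D amplitude map.
#' @param roi logical matrix of the same shape (tape-marked region).
#' @param percentiles length-2 percentiles (0-100).
#' @return Matrix in `[0, 1]`, zero outside the ROI. A constant ROI maps
#'   to 0.5 everywhere inside, with a warning.
#' @export
normalize_saturate <- function(amplitude, roi, percentiles = c(1, 99)) {
  stopifnot(is.matrix(amplitude), identical(dim(amplitude), dim(roi)))
  v <- amplitude[roi]
  if (length(v) == 0L) stop("empty ROI", call. = FALSE)
  q <- stats::quantile(v, percentiles / 100, names = FALSE)
  out <- matrix(0, nrow(amplitude), ncol(amplitude))
  if (diff(q) < 1e-12) {
    warning("constant ROI: normalized map set to 0.5")
    out[roi] <- 0.5
    return(out)
  }
  out[roi] <- pmin(1, pmax(0, (amplitude[roi] - q[1]) / (q[2] - q[1])))
  out
}

#' Otsu threshold on a fixed [0, 1] histogram
#'
#' Builds an `n_bins` equal-width histogram over `[0, 1]` and returns the
#' bin edge maximizing the between-class variance; ties break toward the
#' smallest threshold. Inputs are expected (and clipped) to `[0, 1]`.
#'
#' @param values numeric vector with at least two distinct values.
#' @param n_bins number of histogram bins.
#' @return The threshold, a bin edge in `(0, 1)`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("degenerate input: Otsu needs at least two distinct values",
         call. = FALSE)
  values <- pmin(1, pmax(0, values))
  bin <- pmin(n_bins, floor(values * n_bins) + 1L)
  counts <- tabulate(bin, n_bins)
  n <- sum(counts)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * mids)
  mu <- s0[n_bins] / n
  t_idx <- seq_len(n_bins - 1L)
  w0t <- w0[t_idx]; w1t <- n - w0t
  valid <- w0t > 0 & w1t > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  mu0 <- s0[t_idx][valid] / w0t[valid]
  mu1 <- (s0[n_bins] - s0[t_idx][valid]) / w1t[valid]
  sigma_b[valid] <- (w0t[valid] / n) * (w1t[valid] / n) * (mu0 - mu1)^2
  best <- which(sigma_b >= max(sigma_b) - 1e-12)[1]   # smallest optimal edge
  best / n_bins
}

#' Rectangular region of interest on a uniform map grid
#'
#' @param maps a `map_images` (or any matrix, for its shape).
#' @param margin_mm margin stripped from every edge, mm (requires
#'   `map_images` input for its grid step).
#' @return Logical matrix.
#' @export
roi_rectangle <- function(maps, margin_mm = 0) {
  if (inherits(maps, "map_images")) {
    d <- dim(maps$amplitude)
    mpx <- round(margin_mm / maps$grid_step_mm)
  } else {
    d <- dim(maps); mpx <- 0L
  }
  roi <- matrix(FALSE, d[1], d[2])
  r <- (1 + mpx):(d[1] - mpx); c <- (1 + mpx):(d[2] - mpx)
  roi[r, c] <- TRUE
  roi
}

#' Auto-detect the tape-marked ROI from signal support
#'
#' The marking tape blocks both light and sound, so the taped band
#' carries almost no PA/US signal. The ROI is taken as the largest
#' 8-connected component of pixels above a small fraction of the robust
#' (99th percentile) amplitude, after Gaussian smoothing, with interior
#' holes filled.
#'
#' @param maps a `map_images`.
#' @param threshold_frac fraction of the robust maximum regarded as
#'   signal.
#' @param blur_sigma_px smoothing applied before thresholding.
#' @return Logical ROI matrix.
#' @export
detect_roi <- function(maps, threshold_frac = 0.05, blur_sigma_px = 2) {
  sm <- gaussian_blur(maps$amplitude, blur_sigma_px)
  thr <- threshold_frac * stats::quantile(sm, 0.99, names = FALSE)
  lab <- label8(sm > thr)
  if (max(lab) == 0L) stop("no signal support found for ROI", call. = FALSE)
  sizes <- component_sizes(lab)
  roi <- lab == which.max(sizes)
  # fill holes: background components not touching the image border
  bg <- label8(!roi)
  border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole <- !roi & !(bg %in% setdiff(border_labs, 0L))
  roi | matrix(hole, nrow(roi), ncol(roi))
}

#' Segment the lesion from the normalized amplitude map
#'
#' Pipeline: ROI-weighted Gaussian blur (sigma `blur_sigma_px`) to prevent
#' an overfitted boundary; Otsu threshold over the blurred ROI values;
#' lesion = below-threshold pixels (hypopigmented lesions are the dark
#' class — asserted, not assumed); connectivity cleanup in which lesion
#' components and normal holes smaller than `min_component_px`
#' (8-connected) are reassigned; boundary pixels (lesion pixels 4-adjacent
#' to normal) traced in consistent counter-clockwise order per component;
#' outward unit normals estimated from the gradient of the smoothed mask.
#'
#' Because normalization stretches even pure noise over `[0, 1]`, a scan
#' only counts as lesion-bearing if the candidate lesion class shows a
#' real amplitude deficit on the raw map: when `raw_map` is supplied, the
#' lesion-class raw mean must be at most `1 - min_lesion_contrast` times
#' the normal-class raw mean, otherwise the scan is flagged lesion-free.
#'
#' @param norm_map normalized `[0, 1]` amplitude map
#'   ([normalize_saturate()]).
#' @param roi logical ROI matrix.
#' @param cfg a [pipeline_config()].
#' @param raw_map optional raw (pre-normalization) amplitude map used for
#'   the minimum-contrast check; omit to skip that check.
#' @return An object of class `lesion_segmentation`: `roi_mask`,
#'   `lesion_mask`, `normal_mask`, `boundary` (list, per component, of
#'   n x 2 matrices of `[row, col]` pixels in counter-clockwise order),
#'   `normals` (matching list of unit `[drow, dcol]` vectors pointing from
#'   lesion toward normal skin), `threshold_used`, `lesion_free`,
#'   `n_components`.
#' @export
segment_lesion <- function(norm_map, roi, cfg = pipeline_config(),
                           raw_map = NULL) {
  stopifnot(is.matrix(norm_map), identical(dim(norm_map), dim(roi)))
  empty <- function(thr) structure(list(
    roi_mask = roi, lesion_mask = roi & FALSE, normal_mask = roi,
    boundary = list(), normals = list(), threshold_used = thr,
    lesion_free = TRUE, n_components = 0L), class = "lesion_segmentation")

  sm <- gaussian_blur_roi(norm_map, roi, cfg$blur_sigma_px)
  vals <- sm[roi]
  if (diff(range(vals)) < 1e-6) {
    message("segment_lesion: no amplitude contrast in ROI; lesion-free scan")
    return(empty(NA_real_))
  }
  thr <- tryCatch(otsu_threshold(vals, cfg$otsu_bins),
                  error = function(e) NA_real_)
  if (is.na(thr)) {
    message("segment_lesion: degenerate histogram; lesion-free scan")
    return(empty(NA_real_))
  }
  lesion <- roi & sm < thr

  # cleanup: drop small lesion components, then fill small normal holes
  lab <- label8(lesion)
  if (max(lab) > 0L) {
    sizes <- component_sizes(lab)
    lesion[lab %in% which(sizes < cfg$min_component_px)] <- FALSE
  }
  normal <- roi & !lesion
  labn <- label8(normal)
  if (max(labn) > 0L) {
    sizes <- component_sizes(labn)
    small <- labn %in% which(sizes < cfg$min_component_px)
    lesion[small & roi] <- TRUE
    normal <- roi & !lesion
  }
  if (!any(lesion)) {
    message("segment_lesion: no lesion component survives cleanup")
    return(empty(thr))
  }
  # the lesion must be the low-amplitude class
  if (mean(sm[lesion]) >= mean(sm[normal]))
    stop("segmentation error: below-threshold class is not the darker class",
         call. = FALSE)
  # ... and show a real depigmentation contrast, not stretched noise
  if (!is.null(raw_map) && any(normal)) {
    if (mean(raw_map[lesion]) >
          (1 - cfg$min_lesion_contrast) * mean(raw_map[normal])) {
      message("segment_lesion: candidate lesion lacks amplitude contrast; ",
              "lesion-free scan")
      return(empty(thr))
    }
  }

  bset <- boundary_mask(lesion, normal)
  lab <- label8(lesion)
  ncomp <- max(lab)
  # outward normals from the gradient of the smoothed lesion mask
  msm <- gaussian_blur(lesion * 1.0, 2)
  gy <- matrix(0, nrow(msm), ncol(msm)); gx <- gy
  gy[2:(nrow(msm) - 1), ] <- (msm[3:nrow(msm), ] - msm[1:(nrow(msm) - 2), ]) / 2
  gx[, 2:(ncol(msm) - 1)] <- (msm[, 3:ncol(msm)] - msm[, 1:(ncol(msm) - 2)]) / 2

  boundary <- list(); normals <- list()
  for (cc in seq_len(ncomp)) {
    comp <- lab == cc
    ord <- ordered_contour(comp)
    keep <- bset[ord]
    pts <- ord[keep, , drop = FALSE]
    # boundary pixels not on the outer contour (e.g. around retained
    # normal holes) are appended after the ordered ring
    extra <- which(bset & comp, arr.ind = TRUE)
    in_ring <- paste(pts[, 1], pts[, 2])
    extra <- extra[!(paste(extra[, 1], extra[, 2]) %in% in_ring), ,
                   drop = FALSE]
    pts <- rbind(pts, extra)
    if (nrow(pts) == 0L) next
    g <- cbind(gy[pts], gx[pts])
    gn <- sqrt(rowSums(g^2))
    ok <- gn > 1e-9
    pts <- pts[ok, , drop = FALSE]
    nrm <- -g[ok, , drop = FALSE] / gn[ok]
    if (nrow(pts) == 0L) next
    boundary[[length(boundary) + 1L]] <- unname(pts)
    normals[[length(normals) + 1L]] <- unname(nrm)
  }

  structure(list(
    roi_mask = roi, lesion_mask = lesion, normal_mask = normal,
    boundary = boundary, normals = normals, threshold_used = thr,
    lesion_free = FALSE, n_components = ncomp),
    class = "lesion_segmentation")
}

# lesion pixels 4-adjacent to at least one normal pixel
boundary_mask <- function(lesion, normal) {
  nr <- nrow(lesion); nc <- ncol(lesion)
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  touch <- pad(normal, 1, 0) | pad(normal, -1, 0) |
    pad(normal, 0, 1) | pad(normal, 0, -1)
  lesion & touch
}

# ordered outer contour of one component, counter-clockwise in (x = col,
# y = row) axes; EBImage::ocontour returns 0-based (x, y) pairs.
ordered_contour <- function(comp) {
  oc <- EBImage::ocontour(EBImage::Image(t(comp * 1.0)))[[1]] + 1L
  pts <- cbind(oc[, 2], oc[, 1])            # -> [row, col]
  if (nrow(pts) >= 3L) {
    xs <- pts[, 2]; ys <- pts[, 1]
    area2 <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
    if (area2 < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  }
  pts
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  if (x$lesion_free) {
    cat("lesion_segmentation: lesion-free scan\n")
  } else {
    cat(sprintf(
      "lesion_segmentation: %d component(s), %d lesion px / %d normal px, thr %.4f\n",
      x$n_components, sum(x$lesion_mask), sum(x$normal_mask),
      x$threshold_used))
  }
  invisible(x)
}
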