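# Report-style overlays (MAP + boundary, depth map). Base graphics; these
# are conveniences for inspection, not part of the quantitative path.

#' Plot the amplitude MAP with the segmented lesion boundary
#'
#' @param maps a `map_images`.
#' @param segmentation optional `lesion_segmentation` whose boundary is
#'   overlaid.
#' @param file optional PNG path; when given, the plot is written there.
#' @param ... passed to [graphics::image()].
#' @return `NULL`, invisibly.
#' @export
plot_map_overlay <- function(maps, segmentation = NULL, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 620)
    on.exit(grDevices::dev.off())
  }
  graphics::image(maps$x_mm, maps$y_mm, t(maps$amplitude),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "X (mm)", ylab = "Y (mm)",
                  main = "PA maximum amplitude projection", useRaster = TRUE,
                  ...)
  if (!is.null(segmentation) && !segmentation$lesion_free) {
    for (pts in segmentation$boundary)
      graphics::points(maps$x_mm[pts[, 2]], maps$y_mm[pts[, 1]],
                       col = "red", pch = ".", cex = 2)
  }
  invisible(NULL)
}

#' Plot the PA peak-depth map
#'
#' @inheritParams plot_map_overlay
#' @export
plot_depth_map <- function(maps, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 620)
    on.exit(grDevices::dev.off())
  }
  graphics::image(maps$x_mm, maps$y_mm, t(maps$depth_mm),
                  col = grDevices::hcl.colors(256, "viridis"),
                  xlab = "X (mm)", ylab = "Y (mm)",
                  main = "PA peak depth below surface (mm)", useRaster = TRUE,
                  ...)
  invisible(NULL)
}
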