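# exhaustive between-class-variance search over all bin edges, computed
# naively from the histogram (independent of the cumulative-sum path)
otsu_oracle <- function(values, n_bins = 256L) {
  values <- pmin(1, pmax(0, values))
  bin <- pmin(n_bins, floor(values * n_bins) + 1L)
  counts <- tabulate(bin, n_bins)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  best_t <- NA; best_v <- -Inf
  for (t in seq_len(n_bins - 1L)) {
    lo <- seq_len(t); hi <- (t + 1L):n_bins
    w0 <- sum(counts[lo]); w1 <- sum(counts[hi])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[lo] * mids[lo]) / w0
    mu1 <- sum(counts[hi] * mids[hi]) / w1
    v <- (w0 / sum(counts)) * (w1 / sum(counts)) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t / n_bins
}

test_that("Otsu threshold matches the exhaustive oracle on random mixtures", {
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(50:400, 1); n2 <- sample(50:400, 1)
    v <- c(rbeta(n1, 2, 8), rbeta(n2, 8, 2))
    expect_equal(otsu_threshold(v), otsu_oracle(v))
  }
})

test_that("Otsu splits well-separated modes at the smallest optimal edge", {
  v <- c(rep(0.2, 100), rep(0.9, 100))
  t <- otsu_threshold(v)
  expect_gt(t, 0.2); expect_lte(t, 0.9)
  expect_equal(t, 52 / 256)          # first edge above the low mode
  # three-level image: threshold separates the two heavy modes
  v3 <- c(rep(0.1, 50), rep(0.5, 10), rep(0.9, 50))
  t3 <- otsu_threshold(v3)
  expect_gt(t3, 0.1); expect_lt(t3, 0.9)
  expect_equal(t3, otsu_oracle(v3))
  # histogram scale invariance: duplicating every pixel changes nothing
  expect_equal(otsu_threshold(c(v3, v3)), t3)
  expect_error(otsu_threshold(rep(0.4, 10)), "degenerate")
})

test_that("normalize/saturate clips at the percentiles and maps to [0,1]", {
  amp <- matrix(seq(0, 100, length.out = 10201), 101, 101)
  roi <- matrix(TRUE, 101, 101)
  nm <- normalize_saturate(amp, roi, c(1, 99))
  expect_true(all(nm >= 0 & nm <= 1))
  expect_equal(nm[amp == 50], 0.5, tolerance = 1e-2)
  expect_equal(min(nm[amp <= 0.5]), 0)   # below the low percentile: exactly 0
  expect_equal(max(nm), 1)
  # non-ROI pixels forced to zero
  roi2 <- roi; roi2[1:10, ] <- FALSE
  nm2 <- normalize_saturate(amp, roi2, c(1, 99))
  expect_true(all(nm2[1:10, ] == 0))
  expect_warning(normalize_saturate(matrix(3, 5, 5), matrix(TRUE, 5, 5)),
                 "constant")
})

test_that("segmentation masks partition the ROI with a valid boundary", {
  res <- sharp_analysis()
  seg <- res$segmentation
  expect_false(seg$lesion_free)
  expect_true(!any(seg$lesion_mask & seg$normal_mask))
  expect_identical(seg$lesion_mask | seg$normal_mask, seg$roi_mask)
  # every boundary pixel is lesion and 4-adjacent to >= 1 normal pixel
  for (ci in seq_along(seg$boundary)) {
    pts <- seg$boundary[[ci]]
    expect_true(all(seg$lesion_mask[pts]))
    nr <- nrow(seg$lesion_mask); nc <- ncol(seg$lesion_mask)
    for (i in seq_len(nrow(pts))) {
      r <- pts[i, 1]; c <- pts[i, 2]
      nb <- rbind(c(r + 1, c), c(r - 1, c), c(r, c + 1), c(r, c - 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
               drop = FALSE]
      expect_true(any(seg$normal_mask[nb]))
    }
    # unit normals
    expect_equal(rowSums(seg$normals[[ci]]^2), rep(1, nrow(pts)),
                 tolerance = 1e-6)
  }
})

test_that("segmentation is invariant to positive affine amplitude rescaling", {
  res <- sharp_analysis()
  maps <- res$maps
  roi <- matrix(TRUE, nrow(maps$amplitude), ncol(maps$amplitude))
  cfg <- res$cfg
  seg1 <- segment_lesion(normalize_saturate(maps$amplitude, roi,
                                            cfg$saturation_percentiles),
                         roi, cfg)
  seg2 <- segment_lesion(normalize_saturate(3.7 * maps$amplitude + 11, roi,
                                            cfg$saturation_percentiles),
                         roi, cfg)
  expect_identical(seg1$lesion_mask, seg2$lesion_mask)
})

test_that("detected boundary is within 0.3 mm Hausdorff of the true ellipse", {
  ph <- sharp_phantom()
  res <- sharp_analysis()
  seg <- res$segmentation
  cfg <- ph$truth$config
  pts <- do.call(rbind, seg$boundary)
  det <- cbind(res$maps$x_mm[pts[, 2]], res$maps$y_mm[pts[, 1]])
  th <- seq(0, 2 * pi, length.out = 2000)
  tru <- cbind(cfg$lesion_center_mm[1] + cfg$lesion_semiaxes_mm[1] * cos(th),
               cfg$lesion_center_mm[2] + cfg$lesion_semiaxes_mm[2] * sin(th))
  d2 <- outer(det[, 1], tru[, 1], "-")^2 + outer(det[, 2], tru[, 2], "-")^2
  h <- max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
  expect_lte(h, 0.3)
})

test_that("detected lesion area tracks truth across residual fractions", {
  for (rf in c(0, 0.1, 0.2)) {
    cfg <- small_phantom_config(residual_fraction = rf, noise_sd_frac = 0.05,
                                border_width_mm = 0.2, seed = 12)
    ph <- generate_phantom(cfg)
    res <- suppressMessages(analyze_scan(ph$volume))
    true_area <- sum(ph$truth$true_lesion_mask)
    det_area <- sum(res$segmentation$lesion_mask)
    expect_lt(abs(det_area - true_area) / true_area, 0.15)
  }
})

test_that("a contrast-free scan raises the lesion-free flag", {
  cfg <- small_phantom_config(residual_fraction = 1,
                              island_density_per_cm2 = 0, seed = 13)
  ph <- generate_phantom(cfg)
  res <- suppressMessages(analyze_scan(ph$volume))
  expect_true(res$segmentation$lesion_free)
  expect_true(is.na(res$metrics$mean_amplitude))
})

test_that("small speckle components are absorbed during cleanup", {
  set.seed(5)
  nm <- matrix(0.8 + runif(3600, -0.02, 0.02), 60, 60)
  nm[20:40, 20:40] <- 0.1            # a real lesion, 441 px
  nm[5:6, 5:6] <- 0.05               # 4-px below-threshold speckle
  roi <- matrix(TRUE, 60, 60)
  seg <- segment_lesion(nm, roi, pipeline_config(min_component_px = 50,
                                                 blur_sigma_px = 0.5))
  expect_false(seg$lesion_free)
  expect_false(seg$lesion_mask[5, 5])         # speckle absorbed into normal
  expect_true(seg$lesion_mask[30, 30])
  expect_equal(seg$n_components, 1L)
})
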