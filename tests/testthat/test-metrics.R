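test_that("mean amplitude is the plain lesion mean", {
  nm <- matrix(0, 10, 10)
  mask <- matrix(FALSE, 10, 10)
  mask[2:4, 2] <- TRUE
  nm[2:4, 2] <- c(0.1, 0.2, 0.3)
  expect_equal(mean_amplitude(nm, mask), 0.2)
  nm[mask] <- 0.25
  expect_equal(mean_amplitude(nm, mask), 0.25)
  expect_error(mean_amplitude(nm, matrix(FALSE, 10, 10)), "undefined")
})

test_that("local SD image equals the naive double-loop oracle", {
  set.seed(11)
  x <- matrix(runif(900), 30, 30)
  w <- 5L; r <- 2L
  got <- local_sd_image(x, w)
  for (i in (r + 1):(30 - r)) for (j in (r + 1):(30 - r)) {
    win <- x[(i - r):(i + r), (j - r):(j + r)]
    expect_lt(abs(got[i, j] - sd(as.vector(win))), 1e-9)
  }
  # a window of 24 zeros and one 1: sample SD = sqrt(0.96/24) = 0.2
  y <- matrix(0, 9, 9); y[5, 5] <- 1
  expect_equal(local_sd_image(y, 5L)[5, 5], 0.2)
})

test_that("local SD metric is zero on a constant lesion and excludes the rim", {
  nr <- 40; nc <- 40
  seg <- straight_edge_segmentation(nr, nc, split = 20)
  nm <- matrix(0.9, nr, nc)
  nm[seg$lesion_mask] <- 0.3
  expect_equal(local_sd_metric(nm, seg$lesion_mask, seg, 5L), 0)
  # a spike on the boundary column must not leak into the metric
  nm2 <- nm; nm2[10, 20] <- 1
  expect_equal(local_sd_metric(nm2, seg$lesion_mask, seg, 5L), 0)
  # the same spike in the interior does
  nm3 <- nm; nm3[10, 10] <- 1
  expect_gt(local_sd_metric(nm3, seg$lesion_mask, seg, 5L), 0)
  expect_error(local_sd_metric(nm, matrix(FALSE, nr, nc), seg, 5L),
               "undefined")
})

test_that("boundary slope recovers an ideal step edge exactly", {
  nr <- 30; nc <- 40
  seg <- straight_edge_segmentation(nr, nc, split = 20)
  nm <- matrix(0.8, nr, nc)
  nm[seg$lesion_mask] <- 0.1
  out <- boundary_slope_metric(nm, seg, offset_px = 5L, grid_step_mm = 0.1)
  # 0.7 amplitude difference over 10 px x 0.1 mm = 1.0 mm
  expect_equal(out$mean_slope, 0.7)
  expect_true(all(abs(out$slope_samples - 0.7) < 1e-12))
  # uniform map: all slopes zero
  expect_equal(boundary_slope_metric(matrix(0.5, nr, nc), seg)$mean_slope, 0)
})

test_that("boundary slope matches the gradient of a linear ramp", {
  nr <- 30; nc <- 60
  seg <- straight_edge_segmentation(nr, nc, split = 30)
  g_per_mm <- 0.45
  nm <- matrix(rep((seq_len(nc) - 30) * 0.1 * g_per_mm + 0.5, each = nr),
               nr, nc)
  out <- boundary_slope_metric(nm, seg, offset_px = 5L, grid_step_mm = 0.1)
  expect_equal(out$mean_slope, g_per_mm, tolerance = 0.05 * g_per_mm)
})

test_that("boundary slope is antisymmetric under swapping the two roles", {
  nr <- 30; nc <- 40
  seg <- straight_edge_segmentation(nr, nc, split = 20)
  nm <- matrix(0.8, nr, nc); nm[seg$lesion_mask] <- 0.1
  fwd <- boundary_slope_metric(nm, seg)
  # swap: lesion <-> normal, normals flipped, boundary on the other side
  swapped <- seg
  swapped$lesion_mask <- seg$normal_mask
  swapped$normal_mask <- seg$lesion_mask
  swapped$boundary <- list(cbind(seq_len(nr), rep(21, nr)))
  swapped$normals <- list(cbind(rep(0, nr), rep(-1, nr)))
  bwd <- boundary_slope_metric(nm, swapped)
  expect_equal(bwd$mean_slope, -fwd$mean_slope)
  expect_error(boundary_slope_metric(nm, structure(
    list(boundary = list(), normals = list(), lesion_mask = seg$lesion_mask,
         normal_mask = seg$normal_mask, roi_mask = seg$roi_mask),
    class = "lesion_segmentation")), "undefined")
})

test_that("peak-depth tails match the constructed example and a sort oracle", {
  depth <- matrix(0, 20, 20)
  lesion <- matrix(FALSE, 20, 20); normal <- matrix(FALSE, 20, 20)
  lesion[1:10, 1:10] <- TRUE                   # 100 lesion px
  normal[11:20, 1:10] <- TRUE                  # 100 normal px
  lv <- c(rep(0.2, 85), rep(0.9, 15))
  depth[lesion] <- lv
  depth[normal] <- 0.15
  out <- peak_depth_metric(depth, lesion, normal, 0.15)
  expect_equal(out$d_L_mm, 0.9)
  expect_equal(out$d_N_mm, 0.15)
  expect_equal(out$rel_depth_mm, 0.75)
  # identical constant depths: zero
  d2 <- matrix(0.4, 20, 20)
  expect_equal(peak_depth_metric(d2, lesion, normal, 0.15)$rel_depth_mm, 0)
  # random fixtures vs full-sort oracle
  set.seed(4)
  for (i in 1:5) {
    depth[lesion] <- runif(100); depth[normal] <- runif(100)
    out <- peak_depth_metric(depth, lesion, normal, 0.15)
    dl <- sort(depth[lesion]); dn <- sort(depth[normal])
    expect_lt(abs(out$d_L_mm - mean(rev(dl)[1:15])), 1e-9)
    expect_lt(abs(out$d_N_mm - mean(dn[1:15])), 1e-9)
    expect_equal(out$rel_depth_mm, out$d_L_mm - out$d_N_mm)
  }
  expect_error(peak_depth_metric(depth, matrix(FALSE, 20, 20), normal),
               "undefined")
})

test_that("metrics are deterministic given maps and segmentation", {
  res <- sharp_analysis()
  m1 <- compute_lesion_metrics(res$maps, res$norm_map, res$segmentation,
                               res$cfg)
  m2 <- compute_lesion_metrics(res$maps, res$norm_map, res$segmentation,
                               res$cfg)
  expect_identical(m1$mean_amplitude, m2$mean_amplitude)
  expect_identical(m1$mean_slope, m2$mean_slope)
  expect_identical(m1$rel_peak_depth_mm, m2$rel_peak_depth_mm)
  expect_equal(m1$rel_peak_depth_mm, m1$d_L_mm - m1$d_N_mm)
})

test_that("adding pigment islands raises mean amplitude and local SD", {
  base <- small_phantom_config(noise_sd_frac = 0, border_width_mm = 0.2,
                               residual_fraction = 0.1, seed = 14)
  isl <- small_phantom_config(noise_sd_frac = 0, border_width_mm = 0.2,
                              residual_fraction = 0.1, seed = 14,
                              island_density_per_cm2 = 60)
  m0 <- suppressMessages(analyze_scan(generate_phantom(base)$volume))$metrics
  m1 <- suppressMessages(analyze_scan(generate_phantom(isl)$volume))$metrics
  expect_gt(m1$mean_amplitude, m0$mean_amplitude)
  expect_gt(m1$local_sd, m0$local_sd)
})

test_that("widening the border transition lowers the boundary slope", {
  slopes <- vapply(c(0.2, 1.0, 2.5), function(bw) {
    cfg <- small_phantom_config(noise_sd_frac = 0, border_width_mm = bw,
                                residual_fraction = 0.05, seed = 15)
    suppressMessages(analyze_scan(generate_phantom(cfg)$volume))$metrics$mean_slope
  }, 0)
  expect_true(all(diff(slopes) < 0))
})

test_that("losing residual pigment deepens the relative peak depth", {
  depths <- vapply(c(0.3, 0.05), function(rf) {
    cfg <- small_phantom_config(noise_sd_frac = 0, border_width_mm = 0.2,
                                residual_fraction = rf,
                                vessel_amplitude_frac = 0.1, seed = 16)
    suppressMessages(analyze_scan(generate_phantom(cfg)$volume))$metrics$rel_peak_depth_mm
  }, 0)
  expect_gt(depths[2], depths[1])
})
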