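test_that("phantom generation is deterministic given the seed", {
  cfg <- small_phantom_config(seed = 9, island_density_per_cm2 = 10)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$pa, b$volume$pa)
  expect_identical(a$volume$us, b$volume$us)
  c <- generate_phantom(small_phantom_config(seed = 10,
                                             island_density_per_cm2 = 10))
  expect_false(identical(a$volume$pa, c$volume$pa))
})

test_that("lesion-free limit gives a uniform epidermal band before noise", {
  cfg <- small_phantom_config(residual_fraction = 1,
                              island_density_per_cm2 = 0,
                              noise_sd_frac = 0, surface_curvature_mm = 0)
  ph <- generate_phantom(cfg)
  # band peak per column should be the melanin amplitude everywhere
  peaks <- apply(ph$volume$pa, c(1, 3), max)
  expect_equal(max(peaks) - min(peaks), 0, tolerance = 1e-12)
})

test_that("flat noise-free phantom peaks exactly at surface + half band", {
  cfg <- small_phantom_config(residual_fraction = 1, noise_sd_frac = 0,
                              surface_curvature_mm = 0,
                              surface_depth_mm = 1.0,
                              epidermis_thickness_mm = 0.2)
  ph <- generate_phantom(cfg)
  expected_row <- round((1.0 + 0.1) / cfg$geometry$axial_spacing_mm) + 1
  arg <- apply(ph$volume$pa, c(1, 3), which.max)
  expect_true(all(arg == expected_row))
})

test_that("raising residual fraction never decreases lesion band amplitude", {
  base <- list(noise_sd_frac = 0, island_density_per_cm2 = 0, seed = 4)
  prev <- NULL
  for (rf in c(0, 0.3, 0.7, 1)) {
    cfg <- do.call(small_phantom_config,
                   c(base, list(residual_fraction = rf)))
    pa <- generate_phantom(cfg)$volume$pa
    if (!is.null(prev)) expect_true(all(pa - prev >= -1e-12))
    prev <- pa
  }
})

test_that("pigment islands only alter the interior of the true lesion", {
  cfg0 <- small_phantom_config(noise_sd_frac = 0, island_density_per_cm2 = 0,
                               seed = 6)
  cfg1 <- small_phantom_config(noise_sd_frac = 0,
                               island_density_per_cm2 = 60, seed = 6)
  a <- generate_phantom(cfg0)$volume$pa
  b <- generate_phantom(cfg1)$volume$pa
  g <- cfg0$geometry
  x <- (seq_len(g$n_lateral) - 1) * g$lateral_pitch_mm
  y <- g$elevation_positions_mm
  rho <- sqrt(outer(rep(1, length(y)),
                    ((x - cfg0$lesion_center_mm[1]) /
                       cfg0$lesion_semiaxes_mm[1])^2) +
              outer(((y - cfg0$lesion_center_mm[2]) /
                       cfg0$lesion_semiaxes_mm[2])^2,
                    rep(1, length(x))))
  outside <- which(rho > 1, arr.ind = TRUE)
  for (i in seq_len(nrow(outside)))
    expect_identical(a[outside[i, 1], , outside[i, 2]],
                     b[outside[i, 1], , outside[i, 2]])
  expect_false(identical(a, b))  # islands did change the interior
})

test_that("PA is zero above the surface and negligible below the vessel", {
  cfg <- small_phantom_config(noise_sd_frac = 0, seed = 7)
  ph <- generate_phantom(cfg)
  g <- cfg$geometry
  z <- (seq_len(g$n_axial) - 1) * g$axial_spacing_mm
  for (k in c(1L, 11L)) for (i in c(1L, 20L)) {
    zs <- ph$truth$true_surface_mm[k, i]
    col <- ph$volume$pa[k, , i]
    expect_true(all(col[z < zs] == 0))
    deep <- z > zs + cfg$vessel_depth_mm + 0.3
    expect_true(all(col[deep] < 1e-3))
  }
})

test_that("cohort generation labels scans and derives seeds reproducibly", {
  vit <- small_phantom_config()
  igh <- small_phantom_config(island_density_per_cm2 = 40,
                              border_width_mm = 0.3)
  coh <- generate_cohort(vit, igh, n_vit = 3, n_igh = 2, seed = 21)
  expect_length(coh, 5)
  labs <- vapply(coh, function(s) s$volume$group_label, "")
  expect_equal(labs, c("VIT", "VIT", "VIT", "IGH", "IGH"))
  ids <- vapply(coh, function(s) s$volume$scan_id, "")
  expect_equal(ids, c("VIT01", "VIT02", "VIT03", "IGH01", "IGH02"))
  coh2 <- generate_cohort(vit, igh, n_vit = 3, n_igh = 2, seed = 21)
  expect_identical(attr(coh, "seeds"), attr(coh2, "seeds"))
  expect_identical(coh[[4]]$volume$pa, coh2[[4]]$volume$pa)
  # single-scan cohort
  one <- generate_cohort(vit, igh, n_vit = 1, n_igh = 0, seed = 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$volume$group_label, "VIT")
})

test_that("cohorts can be written to disk with a manifest and re-run", {
  d <- file.path(tempdir(), "cohdir")
  coh <- generate_cohort(small_phantom_config(),
                         small_phantom_config(border_width_mm = 0.3),
                         n_vit = 1, n_igh = 1, seed = 2, out_dir = d)
  man <- read_cohort_manifest(file.path(d, "cohort.csv"))
  expect_equal(nrow(man), 2)
  v <- load_scan(man$path[1])
  expect_equal(v$group_label, "VIT")
  expect_equal(v$pa, coh[[1]]$volume$pa, tolerance = 1e-6)
})
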