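#' Phantom configuration
#'
#' Parametric description of a synthetic co-registered PA/US scan of skin
#' carrying one hypopigmented lesion. The scene is a curved skin surface
#' with a bright epidermal melanin band, an elliptical lesion in which the
#' band amplitude drops to `residual_fraction` through a logistic edge of
#' 10-90% width `border_width_mm`, optional focal pigment islands ("skip
#' areas") inside the lesion, a dermal vessel sheet (superficial vascular
#' plexus) below the surface, and additive noise. The US channel carries
#' Rayleigh speckle below a bright surface echo so that the surface is
#' detectable by thresholding.
#'
#' @param geometry a [scan_geometry()].
#' @param surface_depth_mm mean depth of the skin surface below the first
#'   axial sample, mm.
#' @param surface_curvature_mm peak-to-peak smooth surface undulation, mm.
#' @param surface_tilt_mm peak-to-peak linear surface tilt across the
#'   lateral axis, mm (0 = level).
#' @param epidermis_thickness_mm FWHM of the epidermal melanin band, mm.
#' @param melanin_amplitude PA amplitude of the normal epidermal band
#'   (arbitrary units).
#' @param lesion_center_mm length-2 ellipse center `(x, y)`, mm.
#' @param lesion_semiaxes_mm length-2 ellipse semi-axes `(a, b)`, mm.
#' @param residual_fraction lesion pigment as a fraction of normal skin,
#'   in `[0, 1]`.
#' @param border_width_mm 10-90% width of the logistic pigment ramp at the
#'   lesion edge, mm; 0 gives a hard step.
#' @param island_density_per_cm2 expected number of focal pigment islands
#'   per cm^2 of lesion area.
#' @param island_radius_mm mean island radius, mm (radius ~ 2 sigma of the
#'   Gaussian island profile).
#' @param island_amplitude_frac island pigment as a fraction of normal.
#' @param vessel_amplitude_frac vessel-sheet PA amplitude as a fraction of
#'   `melanin_amplitude`.
#' @param vessel_depth_mm vessel-sheet depth below the local surface, mm.
#' @param noise_sd_frac additive Gaussian noise SD as a fraction of
#'   `melanin_amplitude` (clipped at zero to keep amplitudes non-negative).
#' @param seed integer RNG seed; the whole phantom is deterministic
#'   given the configuration and seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(geometry = scan_geometry(),
                           surface_depth_mm = 1.0,
                           surface_curvature_mm = 0.3,
                           surface_tilt_mm = 0,
                           epidermis_thickness_mm = 0.2,
                           melanin_amplitude = 1.0,
                           lesion_center_mm = c(19.05, 12.5),
                           lesion_semiaxes_mm = c(6, 5),
                           residual_fraction = 0.1,
                           border_width_mm = 1.0,
                           island_density_per_cm2 = 0,
                           island_radius_mm = 0.25,
                           island_amplitude_frac = 0.8,
                           vessel_amplitude_frac = 0.1,
                           vessel_depth_mm = 0.8,
                           noise_sd_frac = 0.02,
                           seed = 1L) {
  cfg <- structure(list(
    geometry = geometry,
    surface_depth_mm = surface_depth_mm,
    surface_curvature_mm = surface_curvature_mm,
    surface_tilt_mm = surface_tilt_mm,
    epidermis_thickness_mm = epidermis_thickness_mm,
    melanin_amplitude = melanin_amplitude,
    lesion_center_mm = lesion_center_mm,
    lesion_semiaxes_mm = lesion_semiaxes_mm,
    residual_fraction = residual_fraction,
    border_width_mm = border_width_mm,
    island_density_per_cm2 = island_density_per_cm2,
    island_radius_mm = island_radius_mm,
    island_amplitude_frac = island_amplitude_frac,
    vessel_amplitude_frac = vessel_amplitude_frac,
    vessel_depth_mm = vessel_depth_mm,
    noise_sd_frac = noise_sd_frac,
    seed = as.integer(seed)
  ), class = "phantom_config")
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  validate_scan_geometry(cfg$geometry)
  if (cfg$residual_fraction < 0 || cfg$residual_fraction > 1)
    stop("residual_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$border_width_mm < 0) stop("border_width_mm must be >= 0",
                                    call. = FALSE)
  if (cfg$noise_sd_frac < 0) stop("noise_sd_frac must be >= 0", call. = FALSE)
  if (length(cfg$lesion_center_mm) != 2L || length(cfg$lesion_semiaxes_mm) != 2L)
    stop("lesion center and semi-axes must each have length 2", call. = FALSE)
  if (any(cfg$lesion_semiaxes_mm <= 0))
    stop("lesion semi-axes must be positive", call. = FALSE)
  cfg
}

#' Vitiligo-like and IGH-like phantom presets
#'
#' Study conditions for the two simulated disease groups. The
#' vitiligo-like preset has near-total pigment loss (residual 0.05), a
#' wide 2.0 mm border ramp and no pigment islands; the IGH-like preset
#' retains more pigment (residual 0.2), has a sharply demarcated 0.3 mm
#' border, and carries focal pigment islands (40 per cm^2, mean radius
#' 0.25 mm at 80% of normal amplitude).
#'
#' @param ... overrides passed on to [phantom_config()].
#' @return A [phantom_config()].
#' @export
vit_phantom_config <- function(...) {
  args <- list(residual_fraction = 0.05, border_width_mm = 2.0,
               island_density_per_cm2 = 0)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

#' @rdname vit_phantom_config
#' @export
igh_phantom_config <- function(...) {
  args <- list(residual_fraction = 0.2, border_width_mm = 0.3,
               island_density_per_cm2 = 40, island_radius_mm = 0.25,
               island_amplitude_frac = 0.8)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

# continuous surface depth (mm) at positions x (lateral, mm), y (elev, mm)
phantom_surface_mm <- function(cfg, x, y) {
  g <- cfg$geometry
  Lx <- (g$n_lateral - 1) * g$lateral_pitch_mm
  Ly <- g$elevation_span_mm
  zs <- outer(y, x, function(yy, xx) {
    cfg$surface_depth_mm +
      (cfg$surface_curvature_mm / 2) *
        cos(2 * pi * (xx - Lx / 2) / Lx) * cos(2 * pi * (yy - Ly / 2) / Ly) +
      cfg$surface_tilt_mm * (xx / Lx - 0.5)
  })
  zs  # matrix [y, x]
}

# pigment field (fraction of normal) at positions x, y; islands drawn from
# the supplied RNG state. Returns matrix [y, x].
phantom_pigment_field <- function(cfg, x, y, islands) {
  a <- cfg$lesion_semiaxes_mm[1]; b <- cfg$lesion_semiaxes_mm[2]
  cx <- cfg$lesion_center_mm[1]; cy <- cfg$lesion_center_mm[2]
  dx <- outer(rep(1, length(y)), x - cx)
  dy <- outer(y - cy, rep(1, length(x)))
  rho <- sqrt((dx / a)^2 + (dy / b)^2)
  th <- atan2(dy, dx)
  r_local <- 1 / sqrt((cos(th) / a)^2 + (sin(th) / b)^2)
  d <- (rho - 1) * r_local                   # approx signed distance, + outside
  if (cfg$border_width_mm > 0) {
    s <- cfg$border_width_mm / (2 * log(9))  # 10-90% width -> logistic scale
    outside_frac <- 1 / (1 + exp(-d / s))
  } else {
    outside_frac <- (d > 0) + 0.5 * (d == 0)
  }
  pig <- cfg$residual_fraction + (1 - cfg$residual_fraction) * outside_frac
  if (!is.null(islands) && nrow(islands) > 0) {
    add <- matrix(0, nrow(pig), ncol(pig))
    for (i in seq_len(nrow(islands))) {
      sig <- islands$radius_mm[i] / 2
      add <- add + cfg$island_amplitude_frac *
        exp(-((dx - (islands$x[i] - cx))^2 + (dy - (islands$y[i] - cy))^2) /
              (2 * sig^2))
    }
    pig <- pig + add * (rho < 1)             # islands confined to the lesion
    pig[pig > 1] <- 1
  }
  pig
}

# draw island centers/radii inside the lesion ellipse (uses current RNG)
draw_islands <- function(cfg) {
  a <- cfg$lesion_semiaxes_mm[1]; b <- cfg$lesion_semiaxes_mm[2]
  area_cm2 <- pi * a * b / 100
  n <- stats::rpois(1, cfg$island_density_per_cm2 * area_cm2)
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0),
                                radius_mm = numeric(0)))
  # uniform in the ellipse via radius sqrt transform
  u <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
  data.frame(x = cfg$lesion_center_mm[1] + a * u * cos(th),
             y = cfg$lesion_center_mm[2] + b * u * sin(th),
             radius_mm = stats::rgamma(n, shape = 4,
                                       scale = cfg$island_radius_mm / 4))
}

#' Generate a synthetic PA/US phantom scan
#'
#' Renders the scene described by a [phantom_config()] onto the scan grid:
#' frames at the Scotch-yoke elevational positions, a Gaussian epidermal
#' PA band of FWHM `epidermis_thickness_mm` centred half a band below the
#' surface and scaled by the lesion pigment field, a vessel sheet at
#' `vessel_depth_mm` below the surface, additive clipped Gaussian noise,
#' and a US channel with a sharp surface echo (6x speckle mean) over
#' Rayleigh speckle. Deterministic given the seed.
#'
#' @param cfg a [phantom_config()].
#' @return A list with elements `volume` (a [pa_us_volume()]) and `truth`
#'   (class `phantom_truth`: `true_surface_mm` and `true_surface_idx`
#'   matrices `[frame, lateral]`, `true_lesion_mask` on the uniform
#'   projection grid `[Y, X]`, `true_border_width_mm`, and `config`).
#' @export
generate_phantom <- function(cfg) {
  cfg <- validate_phantom_config(cfg)
  g <- cfg$geometry
  x <- (seq_len(g$n_lateral) - 1) * g$lateral_pitch_mm
  y <- g$elevation_positions_mm
  z <- (seq_len(g$n_axial) - 1) * g$axial_spacing_mm
  Lx <- (g$n_lateral - 1) * g$lateral_pitch_mm
  if (cfg$lesion_center_mm[1] + cfg$lesion_semiaxes_mm[1] > Lx ||
      cfg$lesion_center_mm[1] - cfg$lesion_semiaxes_mm[1] < 0 ||
      cfg$lesion_center_mm[2] + cfg$lesion_semiaxes_mm[2] >
        g$elevation_span_mm ||
      cfg$lesion_center_mm[2] - cfg$lesion_semiaxes_mm[2] < 0)
    warning("lesion extends outside the scan area; it will be clipped")

  with_seed(cfg$seed, {
    islands <- if (cfg$island_density_per_cm2 > 0) draw_islands(cfg) else NULL
    zs <- phantom_surface_mm(cfg, x, y)          # [frame, lateral]
    pig <- phantom_pigment_field(cfg, x, y, islands)

    pa <- array(0, dim = c(g$n_frames, g$n_axial, g$n_lateral))
    us <- array(0, dim = c(g$n_frames, g$n_axial, g$n_lateral))
    sig_e <- cfg$epidermis_thickness_mm / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    sig_v <- 0.075
    sig_us <- g$axial_spacing_mm / 2             # sharp surface echo
    ray_scale <- sqrt(2 / pi)                    # Rayleigh with mean 1
    for (k in seq_len(g$n_frames)) {
      zc <- zs[k, ] + cfg$epidermis_thickness_mm / 2   # band centre per column
      dzc <- outer(z, zc, "-")                   # [axial, lateral]
      dzsurf <- outer(z, zs[k, ], "-")
      band <- exp(-dzc^2 / (2 * sig_e^2)) * (dzsurf >= 0) *
        matrix(cfg$melanin_amplitude * pig[k, ], g$n_axial, g$n_lateral,
               byrow = TRUE)
      dzv <- outer(z, zs[k, ] + cfg$vessel_depth_mm, "-")
      vessel <- cfg$vessel_amplitude_frac * cfg$melanin_amplitude *
        exp(-dzv^2 / (2 * sig_v^2)) * (dzsurf >= 0)
      frame <- band + vessel
      if (cfg$noise_sd_frac > 0)
        frame <- frame + stats::rnorm(length(frame), 0,
                                      cfg$noise_sd_frac * cfg$melanin_amplitude)
      pa[k, , ] <- pmax(0, frame)

      ridge <- 6 * exp(-dzsurf^2 / (2 * sig_us^2))
      below <- dzsurf > 0
      speckle <- matrix(ray_scale * sqrt(-2 * log(stats::runif(length(below)))),
                        g$n_axial, g$n_lateral)
      amb <- matrix(0.05 * sqrt(-2 * log(stats::runif(length(below)))),
                    g$n_axial, g$n_lateral)
      us[k, , ] <- pmax(ridge, ifelse(below, speckle, amb))
    }

    xu <- seq(0, Lx, by = g$uniform_step_mm)
    yu <- seq(0, g$elevation_span_mm, by = g$uniform_step_mm)
    a <- cfg$lesion_semiaxes_mm[1]; b <- cfg$lesion_semiaxes_mm[2]
    rho_u <- sqrt(outer(rep(1, length(yu)),
                        ((xu - cfg$lesion_center_mm[1]) / a)^2) +
                  outer(((yu - cfg$lesion_center_mm[2]) / b)^2,
                        rep(1, length(xu))))
    truth <- structure(list(
      true_surface_mm = zs,
      true_surface_idx = round(zs / g$axial_spacing_mm) + 1,
      true_lesion_mask = rho_u <= 1,
      true_border_width_mm = cfg$border_width_mm,
      islands = islands,
      config = cfg
    ), class = "phantom_truth")

    vol <- pa_us_volume(pa, us, g, scan_id = sprintf("phantom-%d", cfg$seed))
    list(volume = vol, truth = truth)
  })
}

#' Generate a labeled two-group phantom cohort
#'
#' Draws `n_vit` vitiligo-like and `n_igh` IGH-like scans. Per-scan seeds
#' are derived reproducibly from the master seed, and lesion center and
#' semi-axes receive mild per-scan jitter so the cohort is not 53 copies
#' of one lesion.
#'
#' @param vit_cfg,igh_cfg group base configurations
#'   ([vit_phantom_config()], [igh_phantom_config()]).
#' @param n_vit,n_igh group sizes (>= 0; at least one scan overall).
#' @param seed master integer seed.
#' @param jitter_frac relative jitter applied to lesion center (as a
#'   fraction of the semi-axes) and semi-axes.
#' @param out_dir optional directory; when given, every scan is written
#'   with [save_scan()] and a cohort manifest CSV is placed alongside.
#' @return A list of per-scan lists `(volume, truth)`, with attribute
#'   `"seeds"` (the derived per-scan seeds). Volumes carry `group_label`
#'   `"VIT"` or `"IGH"` and scan ids `VIT01`, ..., `IGH01`, ....
#' @export
generate_cohort <- function(vit_cfg = vit_phantom_config(),
                            igh_cfg = igh_phantom_config(),
                            n_vit = 36L, n_igh = 17L, seed = 1L,
                            jitter_frac = 0.1, out_dir = NULL) {
  stopifnot(n_vit >= 0, n_igh >= 0, n_vit + n_igh >= 1)
  n <- n_vit + n_igh
  plan <- with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n)
    jit <- matrix(stats::runif(4 * n, -jitter_frac, jitter_frac), ncol = 4)
    list(seeds = seeds, jit = jit)
  })
  labels <- c(rep("VIT", n_vit), rep("IGH", n_igh))
  ids <- c(sprintf("VIT%02d", seq_len(n_vit)),
           sprintf("IGH%02d", seq_len(n_igh)))
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    base <- if (labels[i] == "VIT") vit_cfg else igh_cfg
    cfg <- base
    cfg$seed <- plan$seeds[i]
    cfg$lesion_center_mm <- base$lesion_center_mm +
      plan$jit[i, 1:2] * base$lesion_semiaxes_mm
    cfg$lesion_semiaxes_mm <- base$lesion_semiaxes_mm * (1 + plan$jit[i, 3:4])
    ph <- generate_phantom(cfg)
    ph$volume$scan_id <- ids[i]
    ph$volume$group_label <- labels[i]
    scans[[i]] <- ph
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, paste0(ids, ".tif"))
    for (i in seq_len(n)) save_scan(scans[[i]]$volume, paths[i])
    write_cohort_manifest(
      data.frame(scan_id = ids, path = paste0(ids, ".tif"),
                 group_label = labels),
      file.path(out_dir, "cohort.csv"))
  }
  attr(scans, "seeds") <- plan$seeds
  scans
}
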