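#' Tissue preset: ground truth for the synthetic-data generator
#'
#' @param name preset name.
#' @param m_shape power-law shape factor m.
#' @param mus_prime_390 reduced scattering anchor at 390 nm (cm^-1).
#' @param g scattering anisotropy.
#' @param n refractive index.
#' @param fb_curve named numeric vector: intrinsic F_SHG/B_SHG per
#'   excitation wavelength (names in nm).
#' @param efficiency_curve named numeric vector: relative SHG conversion
#'   efficiency per excitation wavelength.
#' @param thickness_um section thickness for SHG imaging (um).
#' @param scatter_thickness_um section thickness for the transmission
#'   measurements (um).
#' @return An object of class `tissue_preset`.
#' @export
tissue_preset <- function(name, m_shape, mus_prime_390, g, n, fb_curve,
                          efficiency_curve, thickness_um = 100,
                          scatter_thickness_um = 50) {
  stopifnot(m_shape > 0, mus_prime_390 > 0, g > 0, g < 1, n > 1,
            all(fb_curve > 0), all(efficiency_curve >= 0),
            thickness_um > 0, scatter_thickness_um > 0)
  structure(list(name = name, m_shape = m_shape,
                 mus_prime_390 = mus_prime_390, g = g, n = n,
                 fb_curve = fb_curve, efficiency_curve = efficiency_curve,
                 thickness_um = thickness_um,
                 scatter_thickness_um = scatter_thickness_um),
            class = "tissue_preset")
}

#' Built-in tissue presets
#'
#' Five synthetic tissue types (normal stroma, benign, low-grade serous,
#' endometrioid, high-grade serous) whose ground-truth parameters honor
#' the qualitative orderings established for ovarian ECM: HGS has the
#' largest reduced scattering, the highest conversion efficiency and the
#' smallest intrinsic F/B; benign has the largest intrinsic F/B and the
#' smallest shape factor; endometrioid has the weakest scattering; LGS and
#' endometrioid have the largest m. Shape factors use literature values
#' for ovarian ECM (benign 1.01, HGS 1.17, normal 1.32, endometrioid
#' 1.40, LGS 1.41); all other anchors are synthetic package constants.
#' Intrinsic F/B rises with excitation wavelength in every tissue (HGS
#' most weakly); the HGS efficiency curve peaks at 890 nm and declines
#' toward longer wavelengths while the other tissues rise slowly, LGS
#' fastest.
#'
#' @return Named list of five [tissue_preset()] objects.
#' @export
builtin_presets <- function() {
  wl <- c(780, 890, 988, 1070, 1160)
  fb_at <- function(fb988, slope)
    stats::setNames(fb988 * (wl / 988)^slope, wl)
  eff_at <- function(v) stats::setNames(v, wl)
  list(
    normal = tissue_preset("normal", m_shape = 1.32, mus_prime_390 = 32,
      g = 0.88, n = 1.40, fb_curve = fb_at(4, 1.5),
      efficiency_curve = eff_at(c(0.30, 0.34, 0.38, 0.42, 0.46))),
    benign = tissue_preset("benign", m_shape = 1.01, mus_prime_390 = 30,
      g = 0.89, n = 1.40, fb_curve = fb_at(8, 2.0),
      efficiency_curve = eff_at(c(0.32, 0.36, 0.40, 0.44, 0.48))),
    LGS = tissue_preset("LGS", m_shape = 1.41, mus_prime_390 = 28,
      g = 0.90, n = 1.40, fb_curve = fb_at(6, 2.5),
      efficiency_curve = eff_at(c(0.28, 0.36, 0.44, 0.52, 0.60))),
    endometrioid = tissue_preset("endometrioid", m_shape = 1.40,
      mus_prime_390 = 20, g = 0.87, n = 1.39, fb_curve = fb_at(2.5, 0.8),
      efficiency_curve = eff_at(c(0.26, 0.29, 0.32, 0.35, 0.38))),
    HGS = tissue_preset("HGS", m_shape = 1.17, mus_prime_390 = 40,
      g = 0.91, n = 1.41, fb_curve = fb_at(2, 0.4),
      efficiency_curve = eff_at(c(0.90, 1.00, 0.85, 0.70, 0.60))))
}

#' Ground-truth reduced scattering of a preset at given wavelengths
#'
#' `mu_s'(lambda) = mus_prime_390 * (lambda / 390)^(2m - 4)`.
#'
#' @param preset a [tissue_preset()].
#' @param wavelengths_nm wavelengths (nm).
#' @return mu_s' values (cm^-1).
#' @export
preset_mus_prime <- function(preset, wavelengths_nm) {
  preset$mus_prime_390 * (wavelengths_nm / 390)^(2 * preset$m_shape - 4)
}

#' Optical properties of a preset at one wavelength
#'
#' @param preset a [tissue_preset()].
#' @param wavelength_nm wavelength (nm).
#' @return An [optical_properties()] object (mu_a = 0).
#' @export
preset_optical_properties <- function(preset, wavelength_nm) {
  musp <- preset_mus_prime(preset, wavelength_nm)
  optical_properties(wavelength_nm, n = preset$n,
                     mu_s = musp / (1 - preset$g), g = preset$g)
}

#' Tissue slab of a preset for one excitation wavelength
#'
#' Carries properties at the excitation and SHG (half) wavelengths.
#'
#' @param preset a [tissue_preset()].
#' @param excitation_wavelength_nm excitation wavelength (nm).
#' @return A [tissue_slab()].
#' @export
preset_slab <- function(preset, excitation_wavelength_nm) {
  tissue_slab(preset$thickness_um * 1e-4,
              list(preset_optical_properties(preset, excitation_wavelength_nm),
                   preset_optical_properties(preset,
                                             excitation_wavelength_nm / 2)))
}

preset_curve_at <- function(curve, wavelength_nm) {
  wl <- as.numeric(names(curve))
  key <- which(abs(wl - wavelength_nm) < 1e-6)
  if (length(key)) return(unname(curve[key[1]]))
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    stop("wavelength outside the preset's curve grid", call. = FALSE)
  exp(approx(log(wl), log(pmax(curve, 1e-12)), xout = log(wavelength_nm))$y)
}

#' Ground-truth emission parameters of a preset
#'
#' @param preset a [tissue_preset()].
#' @param excitation_wavelength_nm excitation wavelength (nm); values off
#'   the preset's grid are interpolated log-log.
#' @return An [emission_params()].
#' @export
preset_emission <- function(preset, excitation_wavelength_nm) {
  emission_params(excitation_wavelength_nm,
                  preset_curve_at(preset$fb_curve, excitation_wavelength_nm),
                  preset_curve_at(preset$efficiency_curve,
                                  excitation_wavelength_nm))
}

#' Generate synthetic collimated-transmission measurements
#'
#' Emits the rows a transmission spectrometer run would produce for one
#' preset sample: the ground-truth power law gives mu_s'(lambda), mu_s =
#' mu_s' / (1 - g), and the transmitted fraction exp(-mu_s t) is
#' perturbed by multiplicative log-normal noise with coefficient of
#' variation `noise_cv`. TIR critical-angle columns (against a 1.5-index
#' reference) encode the preset's refractive index, and the measured
#' anisotropy arrives as the `g` column (it is obtained independently on
#' the bench and is an input here).
#'
#' @param preset a [tissue_preset()].
#' @param wavelengths_nm measurement wavelengths (default the eight
#'   measured points 390-1070 nm).
#' @param noise_cv multiplicative noise coefficient of variation
#'   (default 0.05).
#' @param seed RNG seed.
#' @param sample_id identifier written into the rows.
#' @return data.frame of measurement rows (see [read_scattering_csv()]),
#'   plus `g`.
#' @export
generate_scattering_measurements <- function(preset,
    wavelengths_nm = c(390, 445, 494, 535, 780, 890, 988, 1070),
    noise_cv = 0.05, seed = NA, sample_id = preset$name) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (any(wavelengths_nm < 200 | wavelengths_nm > 1300))
    warning("wavelengths outside 200-1300 nm", call. = FALSE)
  with_seed(seed, {
    t_cm <- preset$scatter_thickness_um * 1e-4
    mus <- preset_mus_prime(preset, wavelengths_nm) / (1 - preset$g)
    tf <- exp(-mus * t_cm)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      tf <- tf * exp(rnorm(length(tf), -sdlog^2 / 2, sdlog))
    }
    tf <- pmin(tf, 1)
    data.frame(sample_id = sample_id, wavelength_nm = wavelengths_nm,
               transmitted_fraction = tf,
               thickness_um = preset$scatter_thickness_um,
               critical_angle_deg = asin(preset$n / 1.5) * 180 / pi,
               n_reference = 1.5, g = preset$g)
  })
}

# oriented band-pass filtered noise: a lightweight fiber-texture surrogate
fiber_texture <- function(ny, nx, sigma_long = 4, sigma_short = 1,
                          angle = 0) {
  noise <- matrix(rnorm(ny * nx), ny, nx)
  sm <- blur_aniso(noise, sigma_short, sigma_long)
  bg <- gaussian_blur(sm, 4 * sigma_long)
  tex <- pmax(sm - bg, 0) + 0.05
  tex / sum(tex)
}

blur_aniso <- function(m, sigma_row, sigma_col) {
  gaussian_blur_1d(gaussian_blur_1d(m, sigma_row, margin = 1),
                   sigma_col, margin = 2)
}

gaussian_blur_1d <- function(m, sigma, margin) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), -r:r, `+`)
    idx[idx < 1] <- 1 - idx[idx < 1] + 1
    idx[idx > n] <- 2 * n - idx[idx > n]
    idx[idx < 1] <- 1; idx[idx > n] <- n
    as.numeric(matrix(v[idx], n, 2 * r + 1) %*% k)
  }
  if (margin == 1) apply(m, 2, conv1) else t(apply(m, 1, conv1))
}

#' Generate a synthetic two-channel depth-resolved SHG stack pair
#'
#' Expected per-slice channel totals come from the photon-transport
#' forward model evaluated on the preset's ground truth (ballistic
#' excitation attenuation squared in intensity, Monte Carlo detection
#' fractions at the SHG wavelength, intrinsic F/B and relative
#' efficiency); per-pixel intensities are drawn Poisson around an oriented
#' filtered-noise fiber texture scaled to those totals. The detector
#' calibration factor multiplies the forward channel, as in the
#' instrument. The ground truth is attached as attribute `ground_truth`.
#'
#' @param preset a [tissue_preset()].
#' @param excitation_wavelength_nm excitation wavelength (nm).
#' @param image_shape c(ny, nx) pixels per slice (default 32 x 32).
#' @param z_step_um axial step (um, default 10).
#' @param photon_scale expected total detected photons per launched unit
#'   (sets shot-noise level; default 2e6).
#' @param seed RNG seed.
#' @param geometry a [detection_geometry()] (default instrument NAs).
#' @param config a [sim_config()]; its `depth_grid_cm` is overridden by
#'   the slice grid.
#' @param detector_calibration forward/backward gain ratio applied to the
#'   forward channel (default 1.6).
#' @return An [image_stack_pair()] with attribute `ground_truth`.
#' @export
generate_depth_stacks <- function(preset, excitation_wavelength_nm,
                                  image_shape = c(32, 32), z_step_um = 10,
                                  photon_scale = 2e6, seed = NA,
                                  geometry = detection_geometry(),
                                  config = sim_config(n_photons = 2e4),
                                  detector_calibration = 1.6) {
  if (photon_scale <= 0) stop("photon_scale must be positive", call. = FALSE)
  if (z_step_um <= 0) stop("z_step must be positive", call. = FALSE)
  with_seed(seed, {
    thick_cm <- preset$thickness_um * 1e-4
    depths <- seq(0, thick_cm, by = z_step_um * 1e-4)
    slab <- preset_slab(preset, excitation_wavelength_nm)
    em <- preset_emission(preset, excitation_wavelength_nm)
    cfg <- config
    cfg$depth_grid_cm <- depths
    cfg$rng_seed <- NA # already inside the seeded stream
    frac <- mc_detection_fractions(slab, depths,
                                   excitation_wavelength_nm / 2,
                                   geometry, cfg)
    det <- compose_fractions(frac, em$intrinsic_fb)
    ball <- ballistic_focal_weight(slab, depths, excitation_wavelength_nm)
    e_fwd <- photon_scale * em$relative_efficiency * ball * det$forward
    e_bwd <- photon_scale * em$relative_efficiency * ball * det$backward
    ny <- image_shape[1]; nx <- image_shape[2]
    nz <- length(depths)
    fstack <- array(0, c(nz, ny, nx))
    bstack <- array(0, c(nz, ny, nx))
    for (i in seq_len(nz)) {
      tex <- fiber_texture(ny, nx)
      fstack[i, , ] <- rpois(ny * nx,
                             tex * e_fwd[i] * detector_calibration)
      bstack[i, , ] <- rpois(ny * nx, tex * e_bwd[i])
    }
    pair <- image_stack_pair(fstack, bstack, z_step_um,
                             excitation_wavelength_nm, detector_calibration)
    attr(pair, "ground_truth") <- list(
      preset = preset$name, intrinsic_fb = em$intrinsic_fb,
      relative_efficiency = em$relative_efficiency,
      photon_scale = photon_scale,
      expected_forward = e_fwd * detector_calibration,
      expected_backward = e_bwd, depths_cm = depths)
    pair
  })
}

#' Generate a labeled synthetic feature cohort
#'
#' Per-class mean feature vectors are taken from preset ground truth
#' (F/B and efficiency at 988 nm and their least-squares slopes across
#' the excitation sweep, mu_s' at the four short wavelengths, and the
#' shape factor m); samples are drawn with multiplicative Gaussian noise
#' of coefficient of variation `within_class_cv`. `between_class_scale`
#' scales each class mean's deviation from the grand mean, controlling
#' separability (1 = the presets as such; 0 = identical classes).
#'
#' @param presets list of [tissue_preset()] objects (default
#'   [builtin_presets()]).
#' @param n_per_class samples per class (>= 2).
#' @param between_class_scale separation multiplier (default 1).
#' @param within_class_cv within-class coefficient of variation
#'   (default 0.1).
#' @param seed RNG seed.
#' @return A [feature_table()] with attribute `ground_truth` (the class
#'   mean table).
#' @export
generate_feature_cohort <- function(presets = builtin_presets(),
                                    n_per_class = 4,
                                    between_class_scale = 1,
                                    within_class_cv = 0.1, seed = NA) {
  if (n_per_class < 2) stop("n_per_class must be >= 2", call. = FALSE)
  means <- do.call(rbind, lapply(presets, preset_feature_means))
  grand <- colMeans(means)
  means <- sweep(sweep(means, 2, grand), 1, between_class_scale, `*`)
  means <- sweep(means, 2, grand, `+`)
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(presets), function(i) {
      mu <- means[i, ]
      noise <- matrix(rnorm(n_per_class * length(mu), 0, within_class_cv),
                      n_per_class)
      sweep(1 + noise, 2, mu, `*`)
    }))
    colnames(rows) <- colnames(means)
    labels <- rep(vapply(presets, `[[`, character(1), "name"),
                  each = n_per_class)
    ft <- feature_table(
      sample_id = paste0(labels, "_", sequence(rep(n_per_class,
                                                   length(presets)))),
      tissue_label = labels, features = as.data.frame(rows))
    attr(ft, "ground_truth") <- means
    ft
  })
}

preset_feature_means <- function(preset) {
  wl <- as.numeric(names(preset$fb_curve))
  fb_slope <- unname(coef(lm(preset$fb_curve ~ wl))[2])
  wle <- as.numeric(names(preset$efficiency_curve))
  eff_slope <- unname(coef(lm(preset$efficiency_curve ~ wle))[2])
  musp <- preset_mus_prime(preset, c(390, 445, 494, 535))
  c(fb_988 = preset_curve_at(preset$fb_curve, 988),
    fb_slope = fb_slope,
    eff_988 = preset_curve_at(preset$efficiency_curve, 988),
    eff_slope = eff_slope,
    mus_prime_390 = musp[1], mus_prime_445 = musp[2],
    mus_prime_494 = musp[3], mus_prime_535 = musp[4],
    m_shape = preset$m_shape)
}

#' Generate a complete synthetic sample directory
#'
#' Emits everything the pipeline ingests for one sample: TIFF stack pairs
#' (one or more fields of view per excitation wavelength), the
#' transmission CSV, a YAML manifest, and a ground-truth JSON serialized
#' alongside the data.
#'
#' @param preset a [tissue_preset()].
#' @param dir output directory.
#' @param excitation_wavelengths_nm excitation wavelengths for stacks.
#' @param n_fields fields of view per wavelength (default 3).
#' @param seed RNG seed (sub-seeds are derived deterministically).
#' @param ... passed to [generate_depth_stacks()].
#' @return `dir`, invisibly.
#' @export
generate_synthetic_sample <- function(preset, dir,
                                      excitation_wavelengths_nm = c(890, 988),
                                      n_fields = 3, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list(preset = preset$name, m_shape = preset$m_shape,
                mus_prime_390 = preset$mus_prime_390, g = preset$g,
                n = preset$n, fb_curve = as.list(preset$fb_curve),
                efficiency_curve = as.list(preset$efficiency_curve),
                seed = seed)
  sc <- generate_scattering_measurements(preset, seed = seed * 1000L + 1L)
  write.csv(sc, file.path(dir, "transmission.csv"), row.names = FALSE)
  fields <- list()
  k <- 0L
  for (wl in excitation_wavelengths_nm) for (f in seq_len(n_fields)) {
    k <- k + 1L
    pair <- generate_depth_stacks(preset, wl,
                                  seed = seed * 1000L + 1L + k, ...)
    sub <- file.path(dir, sprintf("stack_%dnm_field%d", wl, f))
    write_stack_pair(pair, sub)
    fields[[length(fields) + 1L]] <- list(wavelength_nm = wl, field = f,
                                          path = basename(sub))
  }
  yaml::write_yaml(list(sample = preset$name, fields = fields),
                   file.path(dir, "sample.yaml"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
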