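#' Tissue slab for photon transport
#'
#' A homogeneous slab of given thickness with per-wavelength optical
#' properties and the refractive indices of the surrounding media (water
#' immersion above the objective-side face, aqueous mount below). The axial
#' coordinate runs from z = 0 at the top (objective-side) surface toward
#' the condenser; "forward" means exit through the bottom face.
#'
#' @param thickness_cm slab thickness in cm (> 0).
#' @param properties list of [optical_properties()] objects; indexed by
#'   wavelength.
#' @param n_top refractive index of the immersion medium above (default
#'   1.33, water).
#' @param n_bottom refractive index of the mounting medium below (default
#'   1.33).
#' @return An object of class `tissue_slab`.
#' @export
tissue_slab <- function(thickness_cm, properties, n_top = 1.33,
                        n_bottom = 1.33) {
  if (thickness_cm <= 0) stop("thickness must be positive", call. = FALSE)
  if (inherits(properties, "optical_properties")) properties <- list(properties)
  stopifnot(all(vapply(properties, inherits, logical(1), "optical_properties")))
  wl <- vapply(properties, function(p) p$wavelength_nm, numeric(1))
  names(properties) <- format_wavelength(wl)
  structure(list(thickness_cm = thickness_cm, properties = properties,
                 n_top = n_top, n_bottom = n_bottom),
            class = "tissue_slab")
}

format_wavelength <- function(wl) sprintf("%.6g", wl)

#' Fetch a slab's optical properties at a wavelength
#'
#' @param slab a [tissue_slab()].
#' @param wavelength_nm wavelength (nm); must be present in the slab's map.
#' @return The matching `optical_properties` object.
#' @export
slab_properties <- function(slab, wavelength_nm) {
  key <- format_wavelength(wavelength_nm)
  p <- slab$properties[[key]]
  if (is.null(p))
    stop("no optical properties at ", wavelength_nm, " nm in slab",
         call. = FALSE)
  p
}

#' Forward/backward detection geometry
#'
#' Acceptance half-angles are computed in the immersion medium as
#' `asin(NA / n_immersion)`.
#'
#' @param na_backward numerical aperture of the epi (objective) detector
#'   (default 0.8, water-immersion objective).
#' @param na_forward numerical aperture of the trans (condenser) detector
#'   (default 0.9).
#' @param n_immersion refractive index defining the acceptance angles
#'   (default 1.33).
#' @return An object of class `detection_geometry`.
#' @export
detection_geometry <- function(na_backward = 0.8, na_forward = 0.9,
                               n_immersion = 1.33) {
  if (na_backward <= 0 || na_backward >= n_immersion ||
      na_forward <= 0 || na_forward >= n_immersion)
    stop("numerical apertures must lie in (0, n_immersion)", call. = FALSE)
  structure(list(na_backward = na_backward, na_forward = na_forward,
                 n_immersion = n_immersion,
                 cos_accept_forward = cos(asin(na_forward / n_immersion)),
                 cos_accept_backward = cos(asin(na_backward / n_immersion))),
            class = "detection_geometry")
}

#' Intrinsic SHG emission parameters at one excitation wavelength
#'
#' `intrinsic_fb` is the forward/backward SHG creation ratio at the source
#' (set by fibril size and packing relative to the SHG wavelength) —
#' distinct from the measured F/B ratio, which is additionally shaped by
#' scattering of the emitted photons. `relative_efficiency` scales the SHG
#' signal created per unit excitation; only ratios between samples are
#' meaningful. The SHG wavelength is excitation / 2 by construction.
#'
#' @param excitation_wavelength_nm laser excitation wavelength (nm).
#' @param intrinsic_fb intrinsic F_SHG/B_SHG (> 0).
#' @param relative_efficiency relative SHG conversion efficiency (>= 0).
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(excitation_wavelength_nm, intrinsic_fb,
                            relative_efficiency = 1) {
  if (intrinsic_fb <= 0) stop("intrinsic_fb must be positive", call. = FALSE)
  if (relative_efficiency < 0)
    stop("relative_efficiency must be >= 0", call. = FALSE)
  structure(list(excitation_wavelength_nm = excitation_wavelength_nm,
                 shg_wavelength_nm = excitation_wavelength_nm / 2,
                 intrinsic_fb = intrinsic_fb,
                 relative_efficiency = relative_efficiency),
            class = "emission_params")
}

#' Monte Carlo simulation configuration
#'
#' @param n_photons photons launched per depth point (default 1e5).
#' @param depth_grid_cm focal depths (cm) at which responses are simulated.
#' @param rng_seed integer seed; `NA` leaves the RNG stream untouched.
#' @param roulette_threshold weight below which Russian roulette triggers
#'   (default 1e-4).
#' @param roulette_survival survival probability in roulette (default 0.1).
#' @param emission_cone_half_angle_rad half-angle of the cone (about the
#'   axial direction) within which SHG photons are launched uniformly in
#'   solid angle; default is the focusing half-angle of an NA 0.8
#'   water-immersion objective, `asin(0.8 / 1.33)`. Use 0 for collimated
#'   launches.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_photons = 1e5, depth_grid_cm = NULL, rng_seed = NA,
                       roulette_threshold = 1e-4, roulette_survival = 0.1,
                       emission_cone_half_angle_rad = asin(0.8 / 1.33)) {
  if (n_photons < 1) stop("n_photons must be >= 1", call. = FALSE)
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette_survival must lie in (0, 1)", call. = FALSE)
  if (emission_cone_half_angle_rad < 0 ||
      emission_cone_half_angle_rad > pi / 2)
    stop("emission cone half-angle must lie in [0, pi/2]", call. = FALSE)
  structure(list(n_photons = as.integer(n_photons),
                 depth_grid_cm = depth_grid_cm, rng_seed = rng_seed,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 emission_cone_half_angle_rad = emission_cone_half_angle_rad),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Sample a photon free path
#'
#' Exponential step sampling: `s = -ln(u) / mu_t`.
#'
#' @param mu_t total interaction coefficient (cm^-1, > 0).
#' @param uniform_draw draw(s) in (0, 1).
#' @return Path length(s) in cm.
#' @examples
#' sample_free_path(100, exp(-1)) # 0.01 cm
#' @export
sample_free_path <- function(mu_t, uniform_draw) {
  if (any(mu_t <= 0)) stop("mu_t must be positive", call. = FALSE)
  if (any(uniform_draw <= 0 | uniform_draw >= 1))
    stop("uniform draw must lie in (0, 1)", call. = FALSE)
  -log(uniform_draw) / mu_t
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Standard inverse-CDF sampler; `g = 0` falls back to the isotropic
#' branch `2u - 1`. The mean of the sampled cosine equals g.
#'
#' @param g scattering anisotropy, in (-1, 1).
#' @param uniform_draw draw(s) in (0, 1); when `NULL`, `n` draws are taken
#'   from R's RNG (matching the transport kernel's sampler exactly).
#' @param n number of RNG draws when `uniform_draw` is `NULL`.
#' @return Deflection cosine(s).
#' @export
sample_hg_deflection <- function(g, uniform_draw = NULL, n = 1) {
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)", call. = FALSE)
  if (is.null(uniform_draw)) return(mc_sample_hg(as.integer(n), g))
  if (any(uniform_draw <= 0 | uniform_draw >= 1))
    stop("uniform draw must lie in (0, 1)", call. = FALSE)
  if (abs(g) < 1e-8) return(2 * uniform_draw - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * uniform_draw)
  (1 + g^2 - tmp^2) / (2 * g)
}

#' Ballistic excitation weight at the focal depth
#'
#' SHG generation is quadratic in the excitation intensity; with
#' ballistic-only delivery of the focused excitation, the SHG source
#' strength at depth z is attenuated as `exp(-2 * mu_s(lambda_ex) * z)`.
#'
#' @param slab a [tissue_slab()] carrying properties at the excitation
#'   wavelength.
#' @param depth_cm focal depth(s) from the top surface (cm), within the
#'   slab.
#' @param excitation_wavelength_nm excitation wavelength (nm).
#' @return Dimensionless source weight(s) in (0, 1].
#' @export
ballistic_focal_weight <- function(slab, depth_cm, excitation_wavelength_nm) {
  if (any(depth_cm < 0 | depth_cm > slab$thickness_cm))
    stop("depth outside slab", call. = FALSE)
  p <- slab_properties(slab, excitation_wavelength_nm)
  exp(-2 * p$mu_s * depth_cm)
}

# Run the kernel for one launch direction; returns the raw tally list.
mc_run <- function(slab, depth_cm, shg_wavelength_nm, geometry, config,
                   launch_dir, n_photons = config$n_photons) {
  p <- slab_properties(slab, shg_wavelength_nm)
  mc_propagate_kernel(
    n_photons = as.integer(n_photons), depth = depth_cm,
    thickness = slab$thickness_cm,
    mu_s = p$mu_s, mu_a = p$mu_a, g = p$g, n_tissue = p$n,
    n_top = slab$n_top, n_bottom = slab$n_bottom,
    cos_emission_min = cos(config$emission_cone_half_angle_rad),
    launch_dir = as.integer(launch_dir),
    cos_accept_forward = geometry$cos_accept_forward,
    cos_accept_backward = geometry$cos_accept_backward,
    roulette_threshold = config$roulette_threshold,
    roulette_survival = config$roulette_survival)
}

#' Propagate SHG photons created at a focal depth
#'
#' Launches `config$n_photons` photons at the given depth. Each photon
#' starts forward (toward the condenser) with probability
#' `fb / (1 + fb)` where `fb = emission$intrinsic_fb`, else backward, with
#' its direction drawn uniformly in solid angle within the emission cone.
#' Photons random-walk with Henyey-Greenstein scattering, weight-decay
#' absorption, and Russian roulette; at the slab faces, Fresnel
#' reflection/refraction decides escape, and escaping photons are detected
#' when their refracted angle falls inside the matching detector's
#' acceptance cone.
#'
#' @param slab a [tissue_slab()] carrying SHG-wavelength properties.
#' @param depth_cm focal depth (cm), within the slab.
#' @param emission an [emission_params()].
#' @param geometry a [detection_geometry()].
#' @param config a [sim_config()]; its `rng_seed` (when not `NA`) makes the
#'   tally reproducible.
#' @return A `photon_tally`: list with summed weights `detected_forward`,
#'   `detected_backward`, `escaped_undetected`, `absorbed` (includes the
#'   Russian-roulette net so the four sinks add to `launched` exactly),
#'   `launched`, plus launch bookkeeping `launched_forward` /
#'   `launched_backward`.
#' @export
propagate_shg_photons <- function(slab, depth_cm, emission, geometry, config) {
  stopifnot(inherits(emission, "emission_params"))
  if (depth_cm < 0 || depth_cm > slab$thickness_cm)
    stop("depth outside slab", call. = FALSE)
  with_seed(config$rng_seed, {
    fb <- emission$intrinsic_fb
    n_fwd <- rbinom(1, config$n_photons, fb / (1 + fb))
    n_bwd <- config$n_photons - n_fwd
    zero <- list(detected_forward = 0, detected_backward = 0,
                 escaped_undetected = 0, absorbed = 0, launched = 0,
                 detected_forward_unscattered = 0)
    tf <- if (n_fwd > 0) mc_run(slab, depth_cm, emission$shg_wavelength_nm,
                                geometry, config, +1, n_fwd) else zero
    tb <- if (n_bwd > 0) mc_run(slab, depth_cm, emission$shg_wavelength_nm,
                                geometry, config, -1, n_bwd) else zero
    structure(list(
      detected_forward = tf$detected_forward + tb$detected_forward,
      detected_backward = tf$detected_backward + tb$detected_backward,
      escaped_undetected = tf$escaped_undetected + tb$escaped_undetected,
      absorbed = tf$absorbed + tb$absorbed,
      launched = tf$launched + tb$launched,
      launched_forward = n_fwd, launched_backward = n_bwd,
      detected_forward_from_forward = tf$detected_forward,
      detected_backward_from_backward = tb$detected_backward),
      class = "photon_tally")
  })
}

# Per-depth detection fractions for unit-weight launches in each axial
# direction. Photon transport is linear, so any intrinsic F/B candidate's
# response is a convex combination of these two tallies.
mc_detection_fractions <- function(slab, depth_grid_cm, shg_wavelength_nm,
                                   geometry, config) {
  out <- lapply(depth_grid_cm, function(z) {
    tf <- mc_run(slab, z, shg_wavelength_nm, geometry, config, +1)
    tb <- mc_run(slab, z, shg_wavelength_nm, geometry, config, -1)
    c(pFF = tf$detected_forward / tf$launched,
      pFB = tf$detected_backward / tf$launched,
      pBF = tb$detected_forward / tb$launched,
      pBB = tb$detected_backward / tb$launched)
  })
  m <- do.call(rbind, out)
  data.frame(depth_cm = depth_grid_cm, m)
}

compose_fractions <- function(frac, intrinsic_fb) {
  wf <- intrinsic_fb / (1 + intrinsic_fb)
  list(forward = wf * frac$pFF + (1 - wf) * frac$pBF,
       backward = wf * frac$pFB + (1 - wf) * frac$pBB)
}

#' Simulate a depth-resolved two-channel SHG response
#'
#' For every depth in `config$depth_grid_cm`, the detected forward and
#' backward signals are
#' `relative_efficiency * exp(-2 mu_s,ex z) * (per-photon detection
#' fraction)`, with the detection fractions estimated by the Monte Carlo
#' kernel at the SHG wavelength. The measured F/B curve and the normalized
#' forward attenuation curve (forward divided by the mean of its top
#' `norm_k` values) are populated. Identical `rng_seed` and config give
#' bitwise-identical output.
#'
#' @inheritParams propagate_shg_photons
#' @param norm_k number of top slices averaged for the normalization
#'   denominator (default 3).
#' @return A `depth_response_sim` data.frame with columns `depth_cm`,
#'   `forward_detected`, `backward_detected`, `measured_fb`,
#'   `normalized_forward`, plus the per-direction detection fractions.
#' @export
simulate_depth_response <- function(slab, emission, geometry, config,
                                    norm_k = 3) {
  stopifnot(inherits(emission, "emission_params"))
  depths <- config$depth_grid_cm
  if (is.null(depths) || !length(depths))
    stop("config$depth_grid_cm must be a non-empty depth grid", call. = FALSE)
  if (any(depths < 0 | depths > slab$thickness_cm))
    stop("depth grid outside slab", call. = FALSE)
  with_seed(config$rng_seed, {
    frac <- mc_detection_fractions(slab, depths, emission$shg_wavelength_nm,
                                   geometry, config)
    det <- compose_fractions(frac, emission$intrinsic_fb)
    ball <- ballistic_focal_weight(slab, depths,
                                   emission$excitation_wavelength_nm)
    fwd <- emission$relative_efficiency * ball * det$forward
    bwd <- emission$relative_efficiency * ball * det$backward
    res <- data.frame(depth_cm = depths, forward_detected = fwd,
                      backward_detected = bwd,
                      measured_fb = ifelse(bwd > 0, fwd / bwd, NA_real_),
                      normalized_forward = normalize_to_top_k(fwd, norm_k))
    res <- cbind(res, frac[, c("pFF", "pFB", "pBF", "pBB")])
    class(res) <- c("depth_response_sim", class(res))
    res
  })
}

normalize_to_top_k <- function(x, k = 3) {
  if (!length(x) || max(x) <= 0)
    stop("cannot normalize an all-zero curve", call. = FALSE)
  x / mean(sort(x, decreasing = TRUE)[seq_len(min(k, length(x)))])
}

#' Collimated-transmission Monte Carlo (Beer-Lambert oracle)
#'
#' Launches photons at the top surface, collimated along the axis, through
#' an index-matched slab, and reports the unscattered (zero-collision)
#' detected fraction, which must follow `exp(-mu_s * t)`.
#'
#' @param mu_s scattering coefficient (cm^-1).
#' @param thickness_cm slab thickness (cm).
#' @param n_photons photon count (default 1e5).
#' @param g anisotropy used for the (irrelevant to the unscattered tally)
#'   scattered photons; default 0.9.
#' @param seed optional RNG seed.
#' @return List with `unscattered_fraction` and the full kernel tally.
#' @export
simulate_collimated_transmission <- function(mu_s, thickness_cm,
                                             n_photons = 1e5, g = 0.9,
                                             seed = NA) {
  with_seed(seed, {
    tally <- mc_propagate_kernel(
      n_photons = as.integer(n_photons), depth = 0,
      thickness = thickness_cm, mu_s = mu_s, mu_a = 0, g = g,
      n_tissue = 1.33, n_top = 1.33, n_bottom = 1.33,
      cos_emission_min = 1, launch_dir = 1L,
      cos_accept_forward = 0, cos_accept_backward = 0,
      roulette_threshold = 1e-4, roulette_survival = 0.1)
    list(unscattered_fraction =
           tally$detected_forward_unscattered / tally$launched,
         tally = tally)
  })
}

#' Audit weight conservation of a photon tally
#'
#' @param tally a `photon_tally` (or raw kernel tally list).
#' @return Relative discrepancy `|sinks - launched| / launched`.
#' @export
tally_conservation_error <- function(tally) {
  sinks <- tally$detected_forward + tally$detected_backward +
    tally$escaped_undetected + tally$absorbed
  abs(sinks - tally$launched) / tally$launched
}
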