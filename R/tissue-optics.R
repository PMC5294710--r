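#' Per-wavelength optical properties of a tissue
#'
#' Bundles the bulk optical parameters governing photon transport at one
#' wavelength: refractive index `n`, absorption coefficient `mu_a` (cm^-1),
#' scattering coefficient `mu_s` (cm^-1), and scattering anisotropy `g`
#' (mean cosine of the single-scattering deflection). The reduced
#' scattering coefficient `mu_s_prime = mu_s * (1 - g)` is derived and
#' always kept consistent. Absorption defaults to zero, reflecting the
#' `mu_a << mu_s` regime of fibrillar tissue; set `allow_absorption = TRUE`
#' to carry a nonzero `mu_a` without the negligible-absorption validation.
#'
#' @param wavelength_nm wavelength in nm.
#' @param n refractive index (> 1).
#' @param mu_s scattering coefficient, cm^-1 (>= 0).
#' @param g scattering anisotropy, in (-1, 1).
#' @param mu_a absorption coefficient, cm^-1 (>= 0); default 0.
#' @param allow_absorption if `FALSE` (default) and `mu_a > 0.01 * mu_s`,
#'   the negligible-absorption contract is flagged with a warning.
#' @return An object of class `optical_properties` (a named list with
#'   fields `wavelength_nm`, `n`, `mu_a`, `mu_s`, `g`, `mu_s_prime`).
#' @export
optical_properties <- function(wavelength_nm, n, mu_s, g, mu_a = 0,
                               allow_absorption = FALSE) {
  stopifnot(is.numeric(wavelength_nm), wavelength_nm > 0)
  if (!is.numeric(n) || n <= 1)
    stop("refractive index n must exceed 1", call. = FALSE)
  if (mu_s < 0) stop("mu_s must be non-negative", call. = FALSE)
  if (mu_a < 0) stop("mu_a must be non-negative", call. = FALSE)
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)", call. = FALSE)
  if (!allow_absorption && mu_a > 0.01 * mu_s)
    warning("mu_a exceeds 1% of mu_s: outside the negligible-absorption regime",
            call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, n = n, mu_a = mu_a,
                 mu_s = mu_s, g = g,
                 mu_s_prime = reduced_scattering(mu_s, g)),
            class = "optical_properties")
}

#' Reduced scattering coefficient
#'
#' The merged density/organization scattering parameter
#' `mu_s' = mu_s * (1 - g)`.
#'
#' @param mu_s scattering coefficient, cm^-1 (>= 0).
#' @param g scattering anisotropy, in (-1, 1).
#' @return Reduced scattering coefficient in cm^-1.
#' @examples
#' reduced_scattering(100, 0.9) # 10
#' @export
reduced_scattering <- function(mu_s, g) {
  if (any(mu_s < 0)) stop("mu_s must be non-negative", call. = FALSE)
  if (any(g <= -1 | g >= 1)) stop("g must lie in (-1, 1)", call. = FALSE)
  mu_s * (1 - g)
}

#' Scattering coefficient from collimated transmission
#'
#' Beer-Lambert inversion of an on-axis attenuation measurement,
#' `mu_s = -ln(T) / t`. Valid when absorption is negligible relative to
#' scattering, so the measured attenuation is attributed to scattering.
#'
#' @param transmitted_fraction on-axis transmitted intensity fraction, in
#'   (0, 1].
#' @param thickness_cm slab thickness in cm (> 0).
#' @return Scattering coefficient in cm^-1.
#' @examples
#' mu_s_from_transmission(exp(-1), 0.01) # 100 cm^-1
#' @export
mu_s_from_transmission <- function(transmitted_fraction, thickness_cm) {
  if (any(transmitted_fraction <= 0 | transmitted_fraction > 1))
    stop("transmitted_fraction must lie in (0, 1]", call. = FALSE)
  if (any(thickness_cm <= 0)) stop("thickness must be positive", call. = FALSE)
  -log(transmitted_fraction) / thickness_cm
}

#' Refractive index from a total-internal-reflection measurement
#'
#' Snell's law at the critical angle against a higher-index reference
#' medium: `n_sample = n_reference * sin(critical_angle)`.
#'
#' @param critical_angle_rad measured critical angle in radians, in
#'   (0, pi/2].
#' @param n_reference refractive index of the reference medium (> 1).
#' @return Sample refractive index.
#' @examples
#' refractive_index_from_tir(asin(1.4 / 1.5), 1.5) # 1.4
#' @export
refractive_index_from_tir <- function(critical_angle_rad, n_reference) {
  if (any(critical_angle_rad <= 0 | critical_angle_rad > pi / 2))
    stop("critical angle must lie in (0, pi/2]", call. = FALSE)
  if (any(n_reference <= 1))
    stop("reference index must exceed 1", call. = FALSE)
  n <- n_reference * sin(critical_angle_rad)
  if (any(n > n_reference + 1e-12))
    stop("impossible geometry: sample index exceeds reference", call. = FALSE)
  n
}

#' Wavelength-resolved reduced scattering spectrum
#'
#' @param wavelengths_nm strictly increasing wavelengths (nm).
#' @param mu_s_prime reduced scattering coefficients (cm^-1, >= 0), one per
#'   wavelength.
#' @param standard_errors optional per-wavelength standard errors (cm^-1).
#' @return An object of class `scattering_spectrum`.
#' @export
scattering_spectrum <- function(wavelengths_nm, mu_s_prime,
                                standard_errors = NULL) {
  if (length(wavelengths_nm) != length(mu_s_prime))
    stop("wavelengths and values must have equal length", call. = FALSE)
  if (is.unsorted(wavelengths_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(mu_s_prime < 0)) stop("mu_s_prime must be >= 0", call. = FALSE)
  if (!is.null(standard_errors) &&
      length(standard_errors) != length(wavelengths_nm))
    stop("standard_errors length mismatch", call. = FALSE)
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 mu_s_prime = as.numeric(mu_s_prime),
                 standard_errors = standard_errors),
            class = "scattering_spectrum")
}

#' Power-law fit of the reduced scattering spectrum (shape factor m)
#'
#' Fits `mu_s'(lambda) ~ lambda^(2m - 4)` by least squares on
#' `ln mu_s'` versus `ln lambda`; the slope `s` maps to the shape factor
#' `m = (s + 4) / 2`. Larger m corresponds to larger, more ordered
#' sub-micron structures (m is half the fractal dimension in the
#' Whittle-Matern picture of the refractive-index correlation). When the
#' spectrum carries standard errors, a weighted fit
#' (weights 1 / se_log^2, with se_log = se / value by the delta method)
#' can be requested.
#'
#' @param spectrum a [scattering_spectrum()] with at least 3 positive
#'   values.
#' @param reference_wavelength_nm wavelength at which the fitted amplitude
#'   is reported (default 390 nm, the shortest measured wavelength).
#' @param weighted use the spectrum's standard errors as inverse-variance
#'   weights in log space (ignored when no errors are present).
#' @return An object of class `power_law_fit`: list with `m`, `amplitude`
#'   (cm^-1 at the reference wavelength), `reference_wavelength_nm`, and
#'   `residual_norm` (root-sum-square of log-space residuals).
#' @examples
#' sp <- scattering_spectrum(c(390, 445, 494, 535), 1e7 / c(390, 445, 494, 535)^2)
#' fit_power_law(sp)$m # 1
#' @export
fit_power_law <- function(spectrum, reference_wavelength_nm = 390,
                          weighted = FALSE) {
  stopifnot(inherits(spectrum, "scattering_spectrum"))
  if (length(spectrum$wavelengths_nm) < 3)
    stop("power-law fit needs at least 3 wavelengths", call. = FALSE)
  if (any(spectrum$mu_s_prime <= 0))
    stop("power-law fit requires positive mu_s_prime values", call. = FALSE)
  x <- log(spectrum$wavelengths_nm)
  y <- log(spectrum$mu_s_prime)
  w <- NULL
  if (weighted && !is.null(spectrum$standard_errors)) {
    se_log <- spectrum$standard_errors / spectrum$mu_s_prime
    if (all(se_log > 0)) w <- 1 / se_log^2
  }
  fit <- if (is.null(w)) lm(y ~ x) else lm(y ~ x, weights = w)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  structure(list(
    m = (slope + 4) / 2,
    amplitude = exp(intercept + slope * log(reference_wavelength_nm)),
    reference_wavelength_nm = reference_wavelength_nm,
    residual_norm = sqrt(sum(fit$residuals^2))),
    class = "power_law_fit")
}

#' Evaluate a fitted scattering power law
#'
#' @param fit a [fit_power_law()] result (or a list with `m`, `amplitude`,
#'   `reference_wavelength_nm`).
#' @param wavelengths_nm wavelengths at which to evaluate (nm).
#' @return Predicted mu_s' values (cm^-1).
#' @export
predict_power_law <- function(fit, wavelengths_nm) {
  fit$amplitude * (wavelengths_nm / fit$reference_wavelength_nm)^(2 * fit$m - 4)
}

#' Read scattering measurements from CSV
#'
#' Expected columns: `sample_id`, `wavelength_nm`, `transmitted_fraction`,
#' `thickness_um`, optionally `critical_angle_deg` and `n_reference`.
#' Thickness arrives in micrometres (instrument convention) and is
#' converted to cm at this boundary.
#'
#' @param path CSV file path.
#' @return data.frame with an added `mu_s` column (cm^-1) and, when TIR
#'   columns are present, an `n_sample` column.
#' @export
read_scattering_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "wavelength_nm", "transmitted_fraction", "thickness_um")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("scattering CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d$mu_s <- mu_s_from_transmission(d$transmitted_fraction,
                                   d$thickness_um * 1e-4)
  if (all(c("critical_angle_deg", "n_reference") %in% names(d)))
    d$n_sample <- refractive_index_from_tir(d$critical_angle_deg * pi / 180,
                                            d$n_reference)
  d
}

#' Serialize optical properties or a power-law fit to JSON
#'
#' Keys carry explicit unit suffixes so serialized records are
#' self-describing.
#'
#' @param x an `optical_properties` or `power_law_fit` object.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_optics_json <- function(x, path = NULL) {
  rec <- if (inherits(x, "optical_properties")) {
    list(wavelength_nm = x$wavelength_nm, n = x$n,
         mu_a_per_cm = x$mu_a, mu_s_per_cm = x$mu_s, g = x$g,
         mu_s_prime_per_cm = x$mu_s_prime)
  } else if (inherits(x, "power_law_fit")) {
    list(m_shape = x$m, amplitude_per_cm = x$amplitude,
         reference_wavelength_nm = x$reference_wavelength_nm,
         residual_norm = x$residual_norm)
  } else stop("unsupported type for optics JSON", call. = FALSE)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Interpolate optical properties to an unmeasured wavelength
#'
#' Interpolates between measured wavelengths: `ln mu_s` linear in
#' `ln lambda` (consistent with power-law scattering), `g` and `n` linear
#' in `lambda`. Extrapolation beyond the measured range uses the nearest
#' segment's trend for mu_s and clamps g and n to the end values.
#'
#' @param props list of `optical_properties` at measured wavelengths.
#' @param wavelength_nm target wavelength (nm).
#' @return An `optical_properties` object at the target wavelength.
#' @export
interpolate_optical_properties <- function(props, wavelength_nm) {
  stopifnot(length(props) >= 2)
  wl <- vapply(props, function(p) p$wavelength_nm, numeric(1))
  o <- order(wl)
  wl <- wl[o]; props <- props[o]
  mus <- vapply(props, function(p) p$mu_s, numeric(1))
  gs <- vapply(props, function(p) p$g, numeric(1))
  ns <- vapply(props, function(p) p$n, numeric(1))
  mua <- vapply(props, function(p) p$mu_a, numeric(1))
  lx <- log(wl); lt <- log(wavelength_nm)
  interp_lin <- function(x, y, xt) {
    if (xt <= x[1]) i <- 1 else if (xt >= x[length(x)]) i <- length(x) - 1
    else i <- findInterval(xt, x)
    y[i] + (y[i + 1] - y[i]) * (xt - x[i]) / (x[i + 1] - x[i])
  }
  mu_s_t <- if (all(mus > 0)) exp(interp_lin(lx, log(mus), lt))
            else max(0, interp_lin(lx, mus, lt))
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  g_t <- interp_lin(wl, gs, clamp(wavelength_nm, wl[1], wl[length(wl)]))
  n_t <- interp_lin(wl, ns, clamp(wavelength_nm, wl[1], wl[length(wl)]))
  mua_t <- max(0, interp_lin(wl, mua, clamp(wavelength_nm, wl[1], wl[length(wl)])))
  optical_properties(wavelength_nm, n = n_t, mu_s = mu_s_t, g = g_t,
                     mu_a = mua_t, allow_absorption = TRUE)
}
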