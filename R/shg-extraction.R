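#' Default intrinsic F/B candidate grid
#'
#' 33 logarithmically spaced candidates from 0.25 to 16, covering the
#' physically plausible range of SHG creation ratios.
#'
#' @param from,to grid limits (> 0).
#' @param length_out number of candidates.
#' @return Increasing numeric vector of candidates.
#' @export
default_fb_grid <- function(from = 0.25, to = 16, length_out = 33) {
  exp(seq(log(from), log(to), length.out = length_out))
}

lookup_fingerprint <- function(slab, shg_wavelength_nm,
                               excitation_wavelength_nm, geometry, config,
                               depths_cm) {
  p <- slab_properties(slab, shg_wavelength_nm)
  pe <- slab_properties(slab, excitation_wavelength_nm)
  paste0(
    "shg[", paste(sprintf("%.8g", c(p$mu_s, p$mu_a, p$g, p$n)), collapse = ","),
    "]ex[", paste(sprintf("%.8g", c(pe$mu_s, pe$mu_a, pe$g, pe$n)), collapse = ","),
    "]slab[", sprintf("%.8g", slab$thickness_cm), ",",
    sprintf("%.8g", slab$n_top), ",", sprintf("%.8g", slab$n_bottom),
    "]geom[", sprintf("%.8g", geometry$na_forward), ",",
    sprintf("%.8g", geometry$na_backward), ",",
    sprintf("%.8g", geometry$n_immersion),
    "]cfg[", config$n_photons, ",", sprintf("%.8g", config$rng_seed), ",",
    sprintf("%.8g", config$roulette_threshold), ",",
    sprintf("%.8g", config$roulette_survival), ",",
    sprintf("%.8g", config$emission_cone_half_angle_rad),
    "]z[", paste(sprintf("%.8g", depths_cm), collapse = ","), "]")
}

#' Build a lookup table of simulated F/B-versus-depth curves
#'
#' Runs the Monte Carlo forward model on `config$depth_grid_cm` and stores
#' one simulated depth response per intrinsic-F/B candidate. All candidate
#' curves derive from a single seeded pair of kernel runs per depth (all
#' photons launched forward, all launched backward): photon transport is
#' linear in the launch mixture, so each candidate's response is the exact
#' convex combination of the two tallies — identical config/seed policy
#' across candidates by construction.
#'
#' @param slab a [tissue_slab()] with properties at the SHG (and
#'   excitation) wavelength.
#' @param geometry a [detection_geometry()].
#' @param config a [sim_config()] with a non-empty `depth_grid_cm`.
#' @param excitation_wavelength_nm excitation wavelength (nm); the SHG
#'   wavelength is half of it.
#' @param fb_grid increasing positive intrinsic-F/B candidates (default
#'   [default_fb_grid()]).
#' @return An `fb_lookup` object: the candidate grid, the per-depth
#'   detection-fraction table, the per-candidate measured-F/B curve matrix
#'   (depths x candidates), the per-unit-efficiency forward curve, and a
#'   fingerprint keying the cache.
#' @export
build_fb_lookup <- function(slab, geometry, config, excitation_wavelength_nm,
                            fb_grid = default_fb_grid()) {
  if (!length(fb_grid) || any(fb_grid <= 0) ||
      is.unsorted(fb_grid, strictly = TRUE))
    stop("fb_grid must be non-empty, positive, strictly increasing",
         call. = FALSE)
  depths <- config$depth_grid_cm
  if (is.null(depths) || !length(depths))
    stop("config$depth_grid_cm must be set", call. = FALSE)
  shg_wl <- excitation_wavelength_nm / 2
  frac <- with_seed(config$rng_seed,
                    mc_detection_fractions(slab, depths, shg_wl, geometry,
                                           config))
  fb_curves <- vapply(fb_grid, function(fb) {
    det <- compose_fractions(frac, fb)
    ifelse(det$backward > 0, det$forward / det$backward, NA_real_)
  }, numeric(length(depths)))
  fb_curves <- matrix(fb_curves, nrow = length(depths),
                      dimnames = list(NULL, sprintf("fb_%g", fb_grid)))
  ball <- ballistic_focal_weight(slab, depths, excitation_wavelength_nm)
  structure(list(
    fb_grid = fb_grid, depths_cm = depths, fractions = frac,
    fb_curves = fb_curves, ballistic = ball, n_photons = config$n_photons,
    excitation_wavelength_nm = excitation_wavelength_nm,
    fingerprint = lookup_fingerprint(slab, shg_wl, excitation_wavelength_nm,
                                     geometry, config, depths)),
    class = "fb_lookup")
}

# measured F/B curve for an arbitrary candidate, interpolated onto depths,
# with the curve's own Monte Carlo standard error (binomial, from the
# effective detected photon counts behind the composed fractions)
lookup_fb_curve <- function(table, fb, depths_cm, with_sigma = FALSE) {
  det <- compose_fractions(table$fractions, fb)
  sim <- ifelse(det$backward > 0, det$forward / det$backward, NA_real_)
  out <- approx(table$depths_cm, sim, xout = depths_cm, rule = 2)$y
  if (!with_sigma) return(out)
  n <- if (!is.null(table$n_photons)) table$n_photons else Inf
  nf <- pmax(n * det$forward, 1)
  nb <- pmax(n * det$backward, 1)
  sig <- sim * sqrt(1 / nf + 1 / nb)
  list(fb = out,
       sigma = approx(table$depths_cm, sig, xout = depths_cm, rule = 2)$y)
}

chi_square_fb <- function(meas_fb, sim_fb, sigma) {
  ok <- is.finite(meas_fb) & is.finite(sim_fb) & is.finite(sigma) & sigma > 0
  if (!any(ok)) stop("no usable depth points for the fit", call. = FALSE)
  sum(((meas_fb[ok] - sim_fb[ok]) / sigma[ok])^2)
}

fb_sigma <- function(measured) {
  if (!is.null(measured$fb_se) && all(is.finite(measured$fb_se)) &&
      all(measured$fb_se > 0)) return(measured$fb_se)
  # Poisson propagation of the two channel intensities
  n_fields <- if (!is.null(measured$n_fields)) measured$n_fields[1] else 1
  f_tot <- pmax(measured$forward * n_fields, 1e-9)
  b_tot <- pmax(measured$backward * n_fields, 1e-9)
  measured$fb_ratio * sqrt(1 / f_tot + 1 / b_tot)
}

#' Extract the intrinsic F/B from a measured depth response
#'
#' Scores every candidate in the lookup table against the measured
#' F/B-versus-depth curve with the Pearson chi-square statistic
#' `sum_i (meas_i - sim_i)^2 / sigma_i^2`, taking per-depth variances from
#' measurement replicates when present and from Poisson propagation of the
#' two channel intensities otherwise. The best candidate is refined by
#' repeatedly halving the candidate step around the minimum (the
#' composition identity makes refined curves exact re-evaluations of the
#' same seeded simulation). `accepted` is the chi-square goodness-of-fit
#' criterion at p >= 0.05 (df = usable depths - 1); `fb_uncertainty` is
#' the half-width of the contiguous grid neighborhood within the 68%
#' confidence increment (chi-square <= min + 1). Grid ties report the
#' lower candidate and widen the uncertainty to cover both.
#'
#' @param measured a `depth_response` (see [compute_depth_response()]) or
#'   any data.frame with `depth_um` (or `depth_cm`), `forward`, `backward`,
#'   `fb_ratio`, optional `fb_se`, `n_fields`.
#' @param table an [build_fb_lookup()] result spanning the measured depths.
#' @param refine number of step-halving refinement passes around the grid
#'   minimum (default 6; 0 disables refinement).
#' @return An `extraction_result`: list with `intrinsic_fb`,
#'   `fb_uncertainty`, `chi_square`, `p_value`, `accepted`, `grid_index`,
#'   `chi_square_grid`.
#' @export
extract_fb <- function(measured, table, refine = 6) {
  if (!inherits(table, "fb_lookup") || !length(table$fb_grid))
    stop("empty or invalid lookup table", call. = FALSE)
  depths_cm <- measured_depths_cm(measured)
  span <- range(table$depths_cm)
  if (min(depths_cm) < span[1] - 1e-9 || max(depths_cm) > span[2] + 1e-9)
    stop("measured depth grid outside the table's depth span", call. = FALSE)
  sigma <- fb_sigma(measured)
  # total variance: measurement plus the table's own Monte Carlo error
  chi_for <- function(fb) {
    sim <- lookup_fb_curve(table, fb, depths_cm, with_sigma = TRUE)
    chi_square_fb(measured$fb_ratio, sim$fb,
                  sqrt(sigma^2 + sim$sigma^2))
  }
  chi <- vapply(table$fb_grid, chi_for, numeric(1))
  i_min <- which(chi <= min(chi) + 1e-12)[1] # tie-break: lower candidate
  tied <- which(abs(chi - chi[i_min]) <= 1e-12)
  best_fb <- table$fb_grid[i_min]
  best_chi <- chi[i_min]
  # contiguous 68% neighborhood on the grid
  within <- chi <= best_chi + 1
  lo <- i_min; while (lo > 1 && within[lo - 1]) lo <- lo - 1
  hi <- i_min; while (hi < length(chi) && within[hi + 1]) hi <- hi + 1
  hi <- max(hi, max(tied))
  fb_unc <- (table$fb_grid[hi] - table$fb_grid[lo]) / 2
  # refinement: halve the candidate step around the minimum
  if (refine > 0 && length(table$fb_grid) > 1) {
    step <- if (i_min == 1) log(table$fb_grid[2] / table$fb_grid[1])
            else log(table$fb_grid[i_min] / table$fb_grid[i_min - 1])
    centre <- log(best_fb)
    for (r in seq_len(refine)) {
      step <- step / 2
      cand <- exp(centre + step * (-1:1))
      cand <- cand[cand >= table$fb_grid[1] & cand <= max(table$fb_grid)]
      cc <- vapply(cand, chi_for, numeric(1))
      j <- which.min(cc)
      centre <- log(cand[j])
      if (cc[j] < best_chi) { best_chi <- cc[j]; best_fb <- cand[j] }
    }
  }
  n_ok <- sum(is.finite(measured$fb_ratio) & is.finite(sigma) & sigma > 0)
  df <- max(1, n_ok - 1)
  p_value <- pchisq(best_chi, df = df, lower.tail = FALSE)
  structure(list(intrinsic_fb = best_fb, fb_uncertainty = fb_unc,
                 chi_square = best_chi, p_value = p_value,
                 accepted = p_value >= 0.05, grid_index = i_min,
                 chi_square_grid = chi, df = df),
            class = "extraction_result")
}

measured_depths_cm <- function(measured) {
  if (!is.null(measured$depth_cm)) return(measured$depth_cm)
  if (!is.null(measured$depth_um)) return(measured$depth_um * 1e-4)
  stop("measured response needs depth_cm or depth_um", call. = FALSE)
}

#' Extract the relative SHG conversion efficiency
#'
#' Simulates the detected forward signal per unit conversion efficiency
#' (ballistic excitation attenuation times the Monte Carlo forward
#' detection fraction at the fitted intrinsic F/B) and returns the
#' least-squares scale factor between the measured absolute forward curve
#' and that per-unit curve. Only ratios of the returned efficiencies
#' between samples are meaningful; the instrument/collection constant is
#' folded into the scale. Shape agreement is reported as the RMS residual
#' between the two self-normalized curves.
#'
#' @param measured a `depth_response` carrying the absolute (calibrated)
#'   `forward` curve.
#' @param slab,geometry,config as in [build_fb_lookup()].
#' @param fitted_fb intrinsic F/B for this wavelength (from
#'   [extract_fb()]).
#' @param excitation_wavelength_nm excitation wavelength (nm).
#' @param scale known launched-intensity scale (e.g. the generator's
#'   photon scale); the returned efficiency is the fitted scale factor
#'   divided by this.
#' @param table optional pre-built [build_fb_lookup()] for this slab and
#'   wavelength (avoids re-simulation).
#' @return List with `relative_efficiency`, `shape_rms_residual`,
#'   `per_unit_curve`.
#' @export
extract_conversion_efficiency <- function(measured, slab, geometry, config,
                                          fitted_fb,
                                          excitation_wavelength_nm,
                                          scale = 1, table = NULL) {
  depths_cm <- measured_depths_cm(measured)
  if (is.null(table)) {
    cfg <- config
    cfg$depth_grid_cm <- depths_cm
    table <- build_fb_lookup(slab, geometry, cfg, excitation_wavelength_nm,
                             fb_grid = fitted_fb)
  }
  det <- compose_fractions(table$fractions, fitted_fb)
  fwd_unit <- approx(table$depths_cm, table$ballistic * det$forward,
                     xout = depths_cm, rule = 2)$y
  m <- measured$forward
  if (all(m == 0)) return(list(relative_efficiency = 0,
                               shape_rms_residual = NA_real_,
                               per_unit_curve = fwd_unit))
  eff <- sum(m * fwd_unit) / sum(fwd_unit^2) / scale
  shape_res <- tryCatch({
    mn <- normalize_to_top_k(m, 3)
    sn <- normalize_to_top_k(fwd_unit, 3)
    sqrt(mean((mn - sn)^2))
  }, error = function(e) NA_real_)
  list(relative_efficiency = eff, shape_rms_residual = shape_res,
       per_unit_curve = fwd_unit)
}

#' Normalize an efficiency table to its global maximum
#'
#' Divides every relative-efficiency entry by the table's global maximum,
#' so the largest entry becomes exactly 1 (the convention used when
#' plotting per-tissue efficiency spectra on a common scale).
#'
#' @param x numeric vector, matrix, or data.frame of non-negative
#'   efficiencies.
#' @return Object of the same shape, scaled; idempotent.
#' @export
normalize_efficiency_table <- function(x) {
  vals <- if (is.data.frame(x)) as.matrix(x[vapply(x, is.numeric, logical(1))])
          else x
  if (!length(vals)) stop("empty efficiency table", call. = FALSE)
  if (any(vals < 0, na.rm = TRUE))
    stop("efficiencies must be non-negative", call. = FALSE)
  mx <- max(vals, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("degenerate normalization: all efficiencies are zero", call. = FALSE)
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], function(v) v / mx)
    x
  } else x / mx
}

#' Sweep F/B and efficiency extraction across excitation wavelengths
#'
#' For each excitation wavelength with a measured response, interpolates
#' the slab's optical properties to the excitation and SHG wavelengths
#' (log-log in wavelength for mu_s, linear for g and n), builds a lookup
#' table, and extracts the intrinsic F/B and relative conversion
#' efficiency. Wavelengths whose properties cannot be interpolated are
#' skipped with a warning.
#'
#' @param measured_by_wavelength named list: names are excitation
#'   wavelengths (nm), values are `depth_response` objects.
#' @param base_properties list of measured [optical_properties()] spanning
#'   the needed wavelength range.
#' @param thickness_cm slab thickness (cm).
#' @param geometry,config as in [build_fb_lookup()].
#' @param fb_grid candidate grid (default [default_fb_grid()]).
#' @param n_top,n_bottom surround indices for the slab.
#' @return data.frame with one row per wavelength: `wavelength_nm`, `fb`,
#'   `fb_err`, `efficiency`, `chi2`, `accepted`.
#' @export
wavelength_sweep <- function(measured_by_wavelength, base_properties,
                             thickness_cm, geometry, config,
                             fb_grid = default_fb_grid(),
                             n_top = 1.33, n_bottom = 1.33) {
  if (!length(measured_by_wavelength)) {
    warning("empty wavelength list: nothing to extract", call. = FALSE)
    return(data.frame(wavelength_nm = numeric(0), fb = numeric(0),
                      fb_err = numeric(0), efficiency = numeric(0),
                      chi2 = numeric(0), accepted = logical(0)))
  }
  wls <- as.numeric(names(measured_by_wavelength))
  rows <- lapply(seq_along(wls), function(i) {
    wl <- wls[i]
    measured <- measured_by_wavelength[[i]]
    res <- tryCatch({
      p_ex <- interpolate_optical_properties(base_properties, wl)
      p_shg <- interpolate_optical_properties(base_properties, wl / 2)
      slab <- tissue_slab(thickness_cm, list(p_ex, p_shg),
                          n_top = n_top, n_bottom = n_bottom)
      cfg <- config
      cfg$depth_grid_cm <- measured_depths_cm(measured)
      tbl <- build_fb_lookup(slab, geometry, cfg, wl, fb_grid)
      ex <- extract_fb(measured, tbl)
      eff <- extract_conversion_efficiency(measured, slab, geometry, cfg,
                                           ex$intrinsic_fb, wl, table = tbl)
      data.frame(wavelength_nm = wl, fb = ex$intrinsic_fb,
                 fb_err = ex$fb_uncertainty,
                 efficiency = eff$relative_efficiency,
                 chi2 = ex$chi_square, accepted = ex$accepted)
    }, error = function(e) {
      warning("skipping ", wl, " nm: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    res
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(wavelength_nm = numeric(0), fb = numeric(0),
                      fb_err = numeric(0), efficiency = numeric(0),
                      chi2 = numeric(0), accepted = logical(0))
  out[order(out$wavelength_nm), , drop = FALSE]
}

#' Persist a lookup table to a directory
#'
#' Writes the per-candidate measured-F/B curves as one CSV and a JSON
#' manifest (fingerprint, grid, depths, detection fractions), allowing
#' reuse without re-simulation.
#'
#' @param table an `fb_lookup`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fb_lookup <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curves <- data.frame(depth_cm = table$depths_cm, table$fb_curves,
                       check.names = FALSE)
  write.csv(curves, file.path(dir, "fb_curves.csv"), row.names = FALSE)
  manifest <- list(fingerprint = table$fingerprint, fb_grid = table$fb_grid,
                   depths_cm = table$depths_cm, n_photons = table$n_photons,
                   excitation_wavelength_nm = table$excitation_wavelength_nm,
                   fractions = table$fractions, ballistic = table$ballistic)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Load a lookup table written by [write_fb_lookup()]
#'
#' @param dir directory containing `fb_curves.csv` and `manifest.json`.
#' @return An `fb_lookup`.
#' @export
read_fb_lookup <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  curves <- read.csv(file.path(dir, "fb_curves.csv"), check.names = FALSE)
  structure(list(
    fb_grid = manifest$fb_grid, depths_cm = manifest$depths_cm,
    fractions = as.data.frame(manifest$fractions),
    fb_curves = as.matrix(curves[, -1, drop = FALSE]),
    ballistic = manifest$ballistic, n_photons = manifest$n_photons,
    excitation_wavelength_nm = manifest$excitation_wavelength_nm,
    fingerprint = manifest$fingerprint),
    class = "fb_lookup")
}
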