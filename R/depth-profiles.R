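#' Two-channel depth-resolved image stack pair
#'
#' @param forward_stack 3-D array (z, y, x) of forward-detector
#'   intensities (>= 0).
#' @param backward_stack matching array for the backward (epi) detector.
#' @param z_step_um axial step between slices (um, > 0).
#' @param excitation_wavelength_nm excitation wavelength (nm).
#' @param detector_calibration forward/backward channel gain ratio (> 0)
#'   from the bead calibration of the two detection pathways; dividing the
#'   forward channel by it puts both channels on one intensity scale.
#' @return An object of class `image_stack_pair`.
#' @export
image_stack_pair <- function(forward_stack, backward_stack, z_step_um,
                             excitation_wavelength_nm,
                             detector_calibration = 1) {
  if (!identical(dim(forward_stack), dim(backward_stack)))
    stop("forward and backward stacks must have identical shapes",
         call. = FALSE)
  if (length(dim(forward_stack)) != 3)
    stop("stacks must be 3-D arrays (z, y, x)", call. = FALSE)
  if (z_step_um <= 0) stop("z_step must be positive", call. = FALSE)
  if (detector_calibration <= 0)
    stop("detector_calibration must be positive", call. = FALSE)
  if (min(forward_stack) < 0 || min(backward_stack) < 0)
    stop("intensities must be non-negative", call. = FALSE)
  structure(list(forward_stack = forward_stack,
                 backward_stack = backward_stack, z_step_um = z_step_um,
                 excitation_wavelength_nm = excitation_wavelength_nm,
                 detector_calibration = detector_calibration),
            class = "image_stack_pair")
}

#' Integrate a stack pair across each field of view
#'
#' Sums intensities over (y, x) per slice and divides the forward totals
#' by the detector calibration so both channels share one intensity scale.
#'
#' @param stack_pair an [image_stack_pair()].
#' @return data.frame with `slice`, `forward`, `backward` (calibrated
#'   per-slice totals).
#' @export
integrate_stack <- function(stack_pair) {
  stopifnot(inherits(stack_pair, "image_stack_pair"))
  nz <- dim(stack_pair$forward_stack)[1]
  fwd <- apply(stack_pair$forward_stack, 1, sum) /
    stack_pair$detector_calibration
  bwd <- apply(stack_pair$backward_stack, 1, sum)
  data.frame(slice = seq_len(nz), forward = fwd, backward = bwd)
}

locate_surface_slice <- function(forward_totals, threshold_frac = 0.1) {
  mx <- max(forward_totals)
  if (mx <= 0) return(1L)
  idx <- which(forward_totals > threshold_frac * mx)
  if (!length(idx)) 1L else idx[1]
}

#' Measured depth response from one or more fields of view
#'
#' Averages the calibrated per-slice channel totals across fields of view
#' sampled at different locations of the same section, forms the F/B curve
#' from the mean channels, and retains per-depth standard errors of the
#' per-field F/B ratios for the extraction chi-square. Depths are indexed
#' from the objective-side surface, located as the first slice whose
#' forward total exceeds `surface_threshold` of the stack maximum
#' (sections sit in mounting medium, so leading slices can be empty).
#'
#' @param stack_pairs a single [image_stack_pair()] or a list of them; all
#'   must share `z_step_um` and excitation wavelength.
#' @param surface_threshold fraction of the maximum forward total defining
#'   the surface slice (default 0.1); set to 0 to keep every slice.
#' @return A `depth_response` data.frame: `depth_um`, `forward`,
#'   `backward`, `fb_ratio`, `fb_se` (NA when only one field),
#'   `n_fields`.
#' @export
compute_depth_response <- function(stack_pairs, surface_threshold = 0.1) {
  if (inherits(stack_pairs, "image_stack_pair"))
    stack_pairs <- list(stack_pairs)
  stopifnot(length(stack_pairs) >= 1)
  z_steps <- vapply(stack_pairs, function(s) s$z_step_um, numeric(1))
  wls <- vapply(stack_pairs, function(s) s$excitation_wavelength_nm,
                numeric(1))
  if (length(unique(z_steps)) != 1)
    stop("fields of view have inconsistent z-steps", call. = FALSE)
  if (length(unique(wls)) != 1)
    stop("fields of view have inconsistent excitation wavelengths",
         call. = FALSE)
  totals <- lapply(stack_pairs, integrate_stack)
  nz <- unique(vapply(totals, nrow, integer(1)))
  if (length(nz) != 1)
    stop("fields of view have inconsistent slice counts", call. = FALSE)
  fwd_m <- do.call(cbind, lapply(totals, `[[`, "forward"))
  bwd_m <- do.call(cbind, lapply(totals, `[[`, "backward"))
  n_fields <- ncol(fwd_m)
  fwd <- rowMeans(fwd_m)
  bwd <- rowMeans(bwd_m)
  fb <- ifelse(bwd > 0, fwd / bwd, NA_real_)
  fb_fields <- fwd_m / ifelse(bwd_m > 0, bwd_m, NA_real_)
  fb_se <- if (n_fields > 1)
    apply(fb_fields, 1, function(v) sd(v, na.rm = TRUE)) / sqrt(n_fields)
  else rep(NA_real_, nz)
  surface <- locate_surface_slice(fwd, surface_threshold)
  keep <- surface:nz
  out <- data.frame(
    depth_um = (seq_along(keep) - 1) * z_steps[1],
    forward = fwd[keep], backward = bwd[keep], fb_ratio = fb[keep],
    fb_se = fb_se[keep], n_fields = n_fields)
  class(out) <- c("depth_response", class(out))
  out
}

#' Populate the normalized forward attenuation curve
#'
#' Self-normalizes the forward channel with the average maximum intensity,
#' read as the mean of the top `k` per-slice forward totals (robust to
#' single-slice noise); the maximum of the normalized curve is ~1.
#'
#' @param response a `depth_response`.
#' @param k number of top slices averaged (default 3).
#' @return The response with a `normalized_forward` column added.
#' @export
normalize_attenuation <- function(response, k = 3) {
  response$normalized_forward <- normalize_to_top_k(response$forward, k)
  response
}

#' Estimate mean fiber diameter from a 2-D SHG image
#'
#' Approximates fiber diameters by thresholding the image and measuring
#' the above-threshold run length of line profiles drawn perpendicular to
#' the locally dominant fiber orientation. Orientation is estimated from
#' the gradient structure tensor in a Gaussian window (the principal
#' eigenvector of the tensor points across the fiber, along the dominant
#' gradient), making the manual profile placement of the bench procedure
#' reproducible. Profile start points are taken at evenly spaced
#' foreground pixels, so the estimate is deterministic.
#'
#' @param image 2-D numeric matrix (y, x).
#' @param intensity_threshold binarization threshold (same units as
#'   `image`).
#' @param n_profiles number of line profiles (default 50).
#' @param pixel_size_um physical pixel size (um/px, default 1).
#' @param tensor_sigma_px Gaussian window for the structure tensor
#'   (default 3 px).
#' @return List with `mean_diameter_um`, `se_um`, `diameters_um`.
#' @export
estimate_fiber_diameter <- function(image, intensity_threshold,
                                    n_profiles = 50, pixel_size_um = 1,
                                    tensor_sigma_px = 3) {
  stopifnot(is.matrix(image))
  fg <- which(image > intensity_threshold, arr.ind = TRUE)
  if (!nrow(fg)) stop("no pixels above threshold", call. = FALSE)
  sm <- gaussian_blur(image, 1)
  gx <- matrix(0, nrow(image), ncol(image))
  gy <- matrix(0, nrow(image), ncol(image))
  gx[, 2:(ncol(image) - 1)] <-
    (sm[, 3:ncol(image)] - sm[, 1:(ncol(image) - 2)]) / 2
  gy[2:(nrow(image) - 1), ] <-
    (sm[3:nrow(image), ] - sm[1:(nrow(image) - 2), ]) / 2
  jxx <- gaussian_blur(gx * gx, tensor_sigma_px)
  jxy <- gaussian_blur(gx * gy, tensor_sigma_px)
  jyy <- gaussian_blur(gy * gy, tensor_sigma_px)
  pick <- fg[unique(round(seq(1, nrow(fg),
                              length.out = min(n_profiles, nrow(fg))))), ,
             drop = FALSE]
  step <- 0.25
  diameters <- apply(pick, 1, function(rc) {
    y <- rc[1]; x <- rc[2]
    a <- jxx[y, x]; b <- jxy[y, x]; c <- jyy[y, x]
    # principal eigenvector of [[a, b], [b, c]] = across-fiber direction
    theta <- 0.5 * atan2(2 * b, a - c)
    dx <- cos(theta); dy <- sin(theta)
    if (abs(a - c) < 1e-12 && abs(b) < 1e-12) { dx <- 1; dy <- 0 }
    # walk both ways to the first sub-threshold sample; the threshold
    # crossing is taken at the midpoint of the last passing interval
    half <- vapply(c(1, -1), function(sgn) {
      s <- step
      repeat {
        v <- bilinear_at(image, y + sgn * s * dy, x + sgn * s * dx)
        if (is.na(v) || v <= intensity_threshold) break
        s <- s + step
      }
      s - step / 2
    }, numeric(1))
    sum(half) * pixel_size_um
  })
  list(mean_diameter_um = mean(diameters),
       se_um = if (length(diameters) > 1)
         sd(diameters) / sqrt(length(diameters)) else 0,
       diameters_um = diameters)
}

# separable Gaussian blur with reflected edges
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), -r:r, `+`)
    idx[idx < 1] <- 1 - idx[idx < 1] + 1
    idx[idx > n] <- 2 * n - idx[idx > n]
    idx[idx < 1] <- 1; idx[idx > n] <- n
    matrix(v[idx], n, 2 * r + 1) %*% k
  }
  m2 <- apply(m, 2, conv1)
  t(apply(t(m2), 2, conv1))
}

bilinear_at <- function(m, y, x) {
  if (y < 1 || x < 1 || y > nrow(m) || x > ncol(m)) return(NA_real_)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- min(y0 + 1, nrow(m)); x1 <- min(x0 + 1, ncol(m))
  fy <- y - y0; fx <- x - x0
  m[y0, x0] * (1 - fy) * (1 - fx) + m[y1, x0] * fy * (1 - fx) +
    m[y0, x1] * (1 - fy) * fx + m[y1, x1] * fy * fx
}

#' Write a stack pair as multi-page TIFF files plus a YAML manifest
#'
#' Emits `forward.tif` and `backward.tif` (32-bit float, one page per
#' slice) and `manifest.yaml` carrying the z-step, wavelength and detector
#' calibration needed to re-pair the channels.
#'
#' @param stack_pair an [image_stack_pair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack_pair <- function(stack_pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # TIFF pages live in [0, 1]; per-channel intensity scales go in the
  # manifest so counts survive the round trip
  f_scale <- max(stack_pair$forward_stack, 1)
  b_scale <- max(stack_pair$backward_stack, 1)
  as_pages <- function(a, s)
    lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / s)
  tiff::writeTIFF(as_pages(stack_pair$forward_stack, f_scale),
                  file.path(dir, "forward.tif"), bits.per.sample = 32)
  tiff::writeTIFF(as_pages(stack_pair$backward_stack, b_scale),
                  file.path(dir, "backward.tif"), bits.per.sample = 32)
  yaml::write_yaml(list(
    z_step_um = stack_pair$z_step_um,
    excitation_wavelength_nm = stack_pair$excitation_wavelength_nm,
    detector_calibration = stack_pair$detector_calibration,
    forward_scale = f_scale, backward_scale = b_scale),
    file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a stack pair written by [write_stack_pair()]
#'
#' @param dir directory with `forward.tif`, `backward.tif`,
#'   `manifest.yaml`.
#' @return An [image_stack_pair()].
#' @export
read_stack_pair <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  read_stack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr
  }
  fs <- if (!is.null(man$forward_scale)) man$forward_scale else 1
  bs <- if (!is.null(man$backward_scale)) man$backward_scale else 1
  image_stack_pair(read_stack(file.path(dir, "forward.tif")) * fs,
                   read_stack(file.path(dir, "backward.tif")) * bs,
                   z_step_um = man$z_step_um,
                   excitation_wavelength_nm = man$excitation_wavelength_nm,
                   detector_calibration = man$detector_calibration)
}

#' Write a depth response to CSV
#'
#' @param response a `depth_response` (optionally with
#'   `normalized_forward`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_depth_response_csv <- function(response, path) {
  write.csv(as.data.frame(response), path, row.names = FALSE)
  invisible(path)
}
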