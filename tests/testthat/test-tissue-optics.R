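test_that("reduced scattering follows mu_s * (1 - g) and rejects bad domains", {
  expect_equal(reduced_scattering(100, 0.9), 10)
  expect_equal(reduced_scattering(50, 0), 50)
  expect_equal(reduced_scattering(0, 0.5), 0)
  expect_error(reduced_scattering(100, 1), "g must lie")
  expect_error(reduced_scattering(-1, 0.5), "non-negative")
  # monotone decreasing in g for fixed mu_s
  gs <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(reduced_scattering(80, gs)) < 0))
})

test_that("Beer-Lambert inversion is exact over a wide optical-depth range", {
  expect_equal(mu_s_from_transmission(exp(-1), 0.01), 100)
  expect_equal(mu_s_from_transmission(1, 0.42), 0)
  expect_equal(mu_s_from_transmission(exp(-2), 0.005), 400)
  for (od in c(1e-3, 0.1, 1, 5, 10)) {
    t_cm <- 0.005
    expect_equal(mu_s_from_transmission(exp(-od), t_cm), od / t_cm,
                 tolerance = 1e-12)
  }
  expect_error(mu_s_from_transmission(0, 0.01), "\\(0, 1\\]")
  expect_error(mu_s_from_transmission(1.1, 0.01), "\\(0, 1\\]")
  expect_error(mu_s_from_transmission(0.5, -1), "positive")
})

test_that("TIR refractive index inverts Snell's law at the critical angle", {
  expect_equal(refractive_index_from_tir(asin(1.4 / 1.5), 1.5), 1.4)
  expect_equal(refractive_index_from_tir(pi / 2, 1.5), 1.5)
  expect_equal(refractive_index_from_tir(0.1, 1.5), 1.5 * sin(0.1))
  expect_error(refractive_index_from_tir(2, 1.5), "critical angle")
  expect_error(refractive_index_from_tir(0.5, 0.9), "reference index")
})

test_that("optical_properties keeps mu_s_prime consistent and flags absorption", {
  p <- optical_properties(494, 1.4, 200, 0.9)
  expect_equal(p$mu_s_prime, p$mu_s * (1 - p$g))
  expect_warning(optical_properties(494, 1.4, 100, 0.9, mu_a = 5),
                 "negligible-absorption")
  expect_silent(optical_properties(494, 1.4, 100, 0.9, mu_a = 5,
                                   allow_absorption = TRUE))
})

test_that("power-law fit recovers the shape factor exactly on clean spectra", {
  wl <- c(390, 445, 494, 535)
  # slope -2 => m = 1
  sp <- scattering_spectrum(wl, 1e7 / wl^2)
  f <- fit_power_law(sp)
  expect_equal(f$m, 1, tolerance = 1e-10)
  expect_lt(f$residual_norm, 1e-10)
  # flat => m = 2
  expect_equal(fit_power_law(scattering_spectrum(wl, rep(12, 4)))$m, 2,
               tolerance = 1e-10)
  # round trip over random (m, amplitude), amplitude reported at 390 nm
  set.seed(1)
  for (i in 1:20) {
    m <- runif(1, 0.5, 2.5); amp <- runif(1, 5, 80)
    vals <- amp * (wl / 390)^(2 * m - 4)
    f <- fit_power_law(scattering_spectrum(wl, vals))
    expect_equal(f$m, m, tolerance = 1e-6)
    expect_equal(f$amplitude, amp, tolerance = 1e-6)
    # amplitude rescaling leaves m unchanged
    f2 <- fit_power_law(scattering_spectrum(wl, vals * 7.3))
    expect_equal(f2$m, m, tolerance = 1e-6)
  }
  expect_error(fit_power_law(scattering_spectrum(wl[1:2], c(1, 2))),
               "at least 3")
  expect_error(fit_power_law(scattering_spectrum(wl, c(1, 2, 0, 3))),
               "positive")
})

test_that("weighted power-law fit uses the provided standard errors", {
  wl <- c(390, 445, 494, 535)
  vals <- 30 * (wl / 390)^(-1.5)
  vals[4] <- vals[4] * 2 # corrupt the point that gets down-weighted
  se <- c(0.1, 0.1, 0.1, 50)
  fw <- fit_power_law(scattering_spectrum(wl, vals, se), weighted = TRUE)
  fu <- fit_power_law(scattering_spectrum(wl, vals))
  expect_lt(abs(fw$m - 1.25), abs(fu$m - 1.25))
})

test_that("mean recovered m stays within 0.1 of truth at 5% noise", {
  wl <- c(390, 445, 494, 535)
  m_true <- 1.25
  set.seed(1)
  sdlog <- sqrt(log(1 + 0.05^2))
  ms <- replicate(100, {
    vals <- 30 * (wl / 390)^(2 * m_true - 4) *
      exp(rnorm(4, -sdlog^2 / 2, sdlog))
    fit_power_law(scattering_spectrum(wl, vals))$m
  })
  expect_lt(abs(mean(ms) - m_true), 0.1)
})

test_that("optical-property interpolation is power-law consistent", {
  wl <- c(390, 535, 780, 1070)
  m <- 1.3
  props <- lapply(wl, function(w)
    optical_properties(w, 1.4, 300 * (w / 390)^(2 * m - 4), 0.9))
  p <- interpolate_optical_properties(props, 445)
  expect_equal(p$mu_s, 300 * (445 / 390)^(2 * m - 4), tolerance = 1e-6)
  expect_equal(p$g, 0.9)
  # g and n interpolate linearly
  props2 <- list(optical_properties(400, 1.38, 100, 0.85),
                 optical_properties(800, 1.42, 50, 0.95))
  p2 <- interpolate_optical_properties(props2, 600)
  expect_equal(p2$g, 0.90, tolerance = 1e-9)
  expect_equal(p2$n, 1.40, tolerance = 1e-9)
})

test_that("scattering CSV ingestion converts units and applies both inversions", {
  d <- data.frame(sample_id = "s1", wavelength_nm = c(390, 445),
                  transmitted_fraction = exp(-c(1, 0.5)),
                  thickness_um = 50,
                  critical_angle_deg = asin(1.4 / 1.5) * 180 / pi,
                  n_reference = 1.5)
  path <- tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  r <- read_scattering_csv(path)
  expect_equal(r$mu_s, c(1, 0.5) / 0.005, tolerance = 1e-9)
  expect_equal(r$n_sample, rep(1.4, 2), tolerance = 1e-9)
  d$transmitted_fraction <- NULL
  write.csv(d, path, row.names = FALSE)
  expect_error(read_scattering_csv(path), "missing columns")
})

test_that("optics JSON records carry explicit unit suffixes", {
  js <- write_optics_json(optical_properties(494, 1.4, 200, 0.9))
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$mu_s_prime_per_cm, 20)
  expect_true(all(c("wavelength_nm", "mu_s_per_cm") %in% names(rec)))
  fit <- fit_power_law(scattering_spectrum(c(390, 445, 494),
                                           30 * (c(390, 445, 494) / 390)^-2))
  rec2 <- jsonlite::fromJSON(write_optics_json(fit))
  expect_equal(rec2$m_shape, 1, tolerance = 1e-9)
})
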