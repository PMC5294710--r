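test_that("lookup tables honor the ballistic limit and cache keying", {
  geom <- wide_geometry()
  slab0 <- matched_slab(mu_s_shg = 0, mu_s_ex = 0)
  cfg <- sim_config(n_photons = 2e3, rng_seed = 1,
                    depth_grid_cm = c(0, 0.005, 0.01))
  # degenerate grid
  t1 <- build_fb_lookup(slab0, geom, cfg, 988, fb_grid = 1)
  expect_equal(ncol(t1$fb_curves), 1)
  # transparent slab: flat curves exactly at the candidates
  t3 <- build_fb_lookup(slab0, geom, cfg, 988, fb_grid = c(2, 5, 10))
  for (i in 1:3)
    expect_equal(unname(t3$fb_curves[, i]), rep(c(2, 5, 10)[i], 3))
  # fingerprint differs when g differs
  slab_g <- matched_slab(mu_s_shg = 0, mu_s_ex = 0, g = 0.5)
  tg <- build_fb_lookup(slab_g, geom, cfg, 988, fb_grid = c(2, 5, 10))
  expect_false(identical(t3$fingerprint, tg$fingerprint))
  expect_error(build_fb_lookup(slab0, geom, cfg, 988, fb_grid = c(3, 2)),
               "increasing")
})

test_that("extraction recovers a table candidate from its own curve", {
  geom <- detection_geometry()
  slab <- matched_slab(mu_s_shg = 150, g = 0.85, mu_s_ex = 70, n = 1.40)
  cfg <- sim_config(n_photons = 1e4, rng_seed = 2,
                    depth_grid_cm = seq(0, 0.01, by = 0.002))
  tbl <- build_fb_lookup(slab, geom, cfg, 988, fb_grid = c(2, 5, 10))
  det <- shgscatter:::compose_fractions(tbl$fractions, 5)
  measured <- data.frame(depth_cm = tbl$depths_cm,
                         forward = det$forward * 1e6,
                         backward = det$backward * 1e6,
                         fb_ratio = det$forward / det$backward,
                         n_fields = 1)
  r <- extract_fb(measured, tbl, refine = 0)
  expect_equal(r$intrinsic_fb, 5)
  expect_equal(r$chi_square, 0)
  expect_true(r$accepted)
  # scale invariance: any common gain leaves the fit unchanged
  m2 <- measured
  m2$forward <- m2$forward * 37; m2$backward <- m2$backward * 37
  expect_equal(extract_fb(m2, tbl, refine = 0)$intrinsic_fb, 5)
  # gross mismatch is flagged, not thrown
  m3 <- measured
  m3$fb_ratio <- m3$fb_ratio * 1e3
  r3 <- extract_fb(m3, tbl, refine = 0)
  expect_false(r3$accepted)
  expect_error(extract_fb(measured, structure(list(fb_grid = numeric(0)),
                                              class = "fb_lookup")),
               "empty")
})

test_that("chi-square is zero only for an exact table-entry match", {
  geom <- detection_geometry()
  slab <- matched_slab(mu_s_shg = 100, g = 0.8, mu_s_ex = 50, n = 1.40)
  cfg <- sim_config(n_photons = 5e3, rng_seed = 3,
                    depth_grid_cm = seq(0, 0.01, by = 0.0025))
  tbl <- build_fb_lookup(slab, geom, cfg, 988, fb_grid = c(2, 4, 8))
  det <- shgscatter:::compose_fractions(tbl$fractions, 4)
  measured <- data.frame(depth_cm = tbl$depths_cm,
                         forward = det$forward * 1e6,
                         backward = det$backward * 1e6,
                         fb_ratio = det$forward / det$backward,
                         n_fields = 1)
  expect_equal(extract_fb(measured, tbl, refine = 0)$chi_square, 0)
  measured$fb_ratio <- measured$fb_ratio * 1.01
  expect_gt(extract_fb(measured, tbl, refine = 0)$chi_square, 0)
})

test_that("generated stacks round-trip to the generating intrinsic F/B", {
  step <- default_grid_log_step()
  geom <- detection_geometry()
  hits <- 0L; n_rep <- 5L
  for (fb_true in c(2, 10)) {
    preset <- flat_fb_preset(fb_true)
    slab <- preset_slab(preset, 988)
    tbl <- NULL
    for (rep in seq_len(n_rep)) {
      pairs <- lapply(1:2, function(f)
        generate_depth_stacks(preset, 988, seed = 5000 + rep * 10 + f,
                              image_shape = c(16, 16)))
      resp <- compute_depth_response(pairs)
      if (is.null(tbl)) {
        cfg <- sim_config(n_photons = 2e4,
                          depth_grid_cm = resp$depth_um * 1e-4,
                          rng_seed = 77)
        tbl <- build_fb_lookup(slab, geom, cfg, 988)
      }
      r <- extract_fb(resp, tbl)
      if (abs(log(r$intrinsic_fb / fb_true)) <= step + 1e-9)
        hits <- hits + 1L
    }
  }
  expect_equal(hits, 2L * n_rep)
})

test_that("conversion-efficiency recovery and the zero contract hold", {
  geom <- detection_geometry()
  preset <- flat_fb_preset(4, efficiency = 2.0)
  slab <- preset_slab(preset, 988)
  effs <- vapply(1:3, function(s) {
    pair <- generate_depth_stacks(preset, 988, seed = 900 + s,
                                  image_shape = c(16, 16))
    resp <- compute_depth_response(pair)
    cfg <- sim_config(n_photons = 2e4,
                      depth_grid_cm = resp$depth_um * 1e-4, rng_seed = 13)
    extract_conversion_efficiency(resp, slab, geom, cfg, 4, 988,
                                  scale = 2e6)$relative_efficiency
  }, numeric(1))
  expect_lt(abs(mean(effs) - 2.0) / 2.0, 0.1)
  # identically zero measured curve
  z <- data.frame(depth_cm = c(0, 0.005, 0.01), forward = 0, backward = 0,
                  fb_ratio = NA_real_, n_fields = 1)
  cfgz <- sim_config(n_photons = 2e3, depth_grid_cm = z$depth_cm,
                     rng_seed = 1)
  ez <- extract_conversion_efficiency(z, slab, geom, cfgz, 4, 988)
  expect_equal(ez$relative_efficiency, 0)
})

test_that("efficiency normalization is max-1, idempotent, and guarded", {
  expect_equal(normalize_efficiency_table(c(4, 2, 1)), c(1, 0.5, 0.25))
  expect_equal(normalize_efficiency_table(7), 1)
  x <- matrix(c(3, 1, 0.5, 6), 2)
  once <- normalize_efficiency_table(x)
  expect_equal(max(once), 1)
  expect_equal(normalize_efficiency_table(once), once)
  expect_error(normalize_efficiency_table(c(0, 0)), "degenerate")
  expect_error(normalize_efficiency_table(c(-1, 2)), "non-negative")
})

test_that("wavelength sweep recovers flat and sloped F/B spectra", {
  geom <- detection_geometry()
  step <- default_grid_log_step()
  base_props <- lapply(c(390, 494, 780, 1070),
                       function(w) preset_optical_properties(
                         flat_fb_preset(4), w))
  run_sweep <- function(preset, wls) {
    measured <- lapply(wls, function(wl) {
      pair <- generate_depth_stacks(preset, wl, seed = 31 + wl,
                                    image_shape = c(16, 16))
      compute_depth_response(pair)
    })
    names(measured) <- wls
    wavelength_sweep(measured, base_props, 0.01, geom,
                     sim_config(n_photons = 1e4, rng_seed = 3))
  }
  flat <- run_sweep(flat_fb_preset(4), c(890, 988))
  expect_equal(nrow(flat), 2)
  expect_true(all(abs(log(flat$fb / 4)) <= step + 1e-9))
  # monotone ground truth stays monotone after extraction
  sloped <- tissue_preset("sloped", 1.2, 30, 0.9, 1.40,
    fb_curve = c(`780` = 2, `890` = 4, `988` = 7, `1070` = 10, `1160` = 12),
    efficiency_curve = c(`780` = 0.5, `890` = 0.5, `988` = 0.5,
                         `1070` = 0.5, `1160` = 0.5))
  sw <- run_sweep(sloped, c(890, 988, 1070))
  expect_true(all(diff(sw$fb) > 0))
  expect_warning(empty <- wavelength_sweep(list(), base_props, 0.01, geom,
                                           sim_config(n_photons = 100)),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("lookup tables persist to CSV + manifest and load back", {
  geom <- detection_geometry()
  slab <- matched_slab(mu_s_shg = 100, g = 0.8, mu_s_ex = 50, n = 1.40)
  cfg <- sim_config(n_photons = 2e3, rng_seed = 4,
                    depth_grid_cm = c(0, 0.005, 0.01))
  tbl <- build_fb_lookup(slab, geom, cfg, 988, fb_grid = c(2, 5, 10))
  dir <- tempfile()
  write_fb_lookup(tbl, dir)
  back <- read_fb_lookup(dir)
  expect_equal(back$fb_grid, tbl$fb_grid)
  expect_equal(back$fb_curves, tbl$fb_curves, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$fingerprint, tbl$fingerprint)
  expect_equal(back$n_photons, tbl$n_photons)
})
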