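test_that("free-path sampling matches the exponential closed form", {
  expect_equal(sample_free_path(100, exp(-1)), 0.01)
  expect_equal(sample_free_path(10, 1 - 1e-12), 0, tolerance = 1e-10)
  set.seed(1)
  draws <- sample_free_path(50, runif(1e5))
  expect_lt(abs(mean(draws) - 1 / 50), 3 * (1 / 50) / sqrt(1e5))
  expect_error(sample_free_path(0, 0.5), "positive")
})

test_that("Henyey-Greenstein sampler matches a brute-force CDF inversion", {
  # closed-form HG CDF in the deflection cosine
  hg_cdf <- function(c, g) {
    (1 - g^2) / (2 * g) *
      (1 / sqrt(1 + g^2 - 2 * g * c) - 1 / (1 + g))
  }
  for (g in c(0.3, 0.9)) for (u in c(0.1, 0.5, 0.9)) {
    ours <- sample_hg_deflection(g, uniform_draw = u)
    oracle <- uniroot(function(c) hg_cdf(c, g) - u, c(-1, 1),
                      tol = 1e-12)$root
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
  # isotropic branch
  expect_equal(sample_hg_deflection(0, uniform_draw = 0.75), 0.5)
  expect_error(sample_hg_deflection(1, uniform_draw = 0.5), "g must lie")
})

test_that("HG mean deflection cosine equals g", {
  for (g in c(0, 0.5, 0.9)) {
    set.seed(1)
    expect_lt(abs(mean(sample_hg_deflection(g, n = 1e5)) - g), 0.004)
  }
})

test_that("ballistic focal weight is the squared Beer-Lambert attenuation", {
  slab <- matched_slab(mu_s_ex = 100)
  expect_equal(ballistic_focal_weight(slab, 0, 988), 1)
  expect_equal(ballistic_focal_weight(slab, 0.005, 988), exp(-1))
  slab0 <- matched_slab(mu_s_ex = 0)
  expect_equal(ballistic_focal_weight(slab0, c(0, 0.004, 0.01), 988),
               rep(1, 3))
  expect_error(ballistic_focal_weight(slab, 0.02, 988), "outside")
  expect_error(ballistic_focal_weight(slab, 0.005, 700), "no optical")
})

test_that("transparent index-matched slab preserves the launch split per photon", {
  slab <- matched_slab(mu_s_shg = 0)
  geom <- wide_geometry()
  cfg <- sim_config(n_photons = 2e4, rng_seed = 1)
  t <- propagate_shg_photons(slab, 0.005, emission_params(988, 4), geom, cfg)
  expect_identical(t$detected_forward, as.numeric(t$launched_forward))
  expect_identical(t$detected_backward, as.numeric(t$launched_backward))
  ratio <- t$detected_forward / t$detected_backward
  p <- 4 / 5
  se3 <- 3 * sqrt(p * (1 - p) / cfg$n_photons)
  expect_lt(abs(t$launched_forward / cfg$n_photons - p), se3)
  expect_equal(ratio, t$launched_forward / t$launched_backward)
})

test_that("mirror-symmetric turbid slab gives measured F/B of 1", {
  slab <- matched_slab(mu_s_shg = 150, g = 0.8)
  geom <- wide_geometry()
  cfg <- sim_config(n_photons = 4e4, rng_seed = 2,
                    depth_grid_cm = 0.005)
  r <- simulate_depth_response(slab, emission_params(988, 1), geom, cfg)
  # detection fractions are binomial with ~0.4 scale; 3 sigma on the ratio
  expect_lt(abs(r$measured_fb - 1), 3 * sqrt(2 / (0.3 * cfg$n_photons)))
})

test_that("every tally conserves launched weight to machine precision", {
  geom <- detection_geometry()
  for (mus in c(0, 50, 300)) for (g in c(0, 0.9)) for (mua in c(0, 1)) {
    slab <- tissue_slab(0.01,
      list(optical_properties(988, 1.4, 80, g, mu_a = mua,
                              allow_absorption = TRUE),
           optical_properties(494, 1.4, mus, g, mu_a = mua,
                              allow_absorption = TRUE)))
    cfg <- sim_config(n_photons = 5e3, rng_seed = 3)
    t <- propagate_shg_photons(slab, 0.004, emission_params(988, 3),
                               geom, cfg)
    expect_lt(tally_conservation_error(t), 1e-6)
  }
})

test_that("collimated unscattered fraction follows Beer-Lambert", {
  for (od in c(0.5, 2)) {
    r <- simulate_collimated_transmission(od / 0.01, 0.01,
                                          n_photons = 4e4, seed = 1)
    se3 <- 3 * sqrt(exp(-od) * (1 - exp(-od)) / 4e4)
    expect_lt(abs(r$unscattered_fraction - exp(-od)), se3)
  }
})

test_that("depth response honors the ballistic and scaling contracts", {
  slab <- matched_slab(mu_s_shg = 0, mu_s_ex = 0)
  geom <- wide_geometry()
  cfg <- sim_config(n_photons = 5e3, rng_seed = 4,
                    depth_grid_cm = c(0, 0.003, 0.006, 0.009))
  r <- simulate_depth_response(slab, emission_params(988, 4, 1), geom, cfg)
  # transparent slab: measured F/B identically intrinsic, flat forward
  expect_equal(r$measured_fb, rep(4, 4))
  expect_equal(r$normalized_forward, rep(1, 4))
  # doubling efficiency doubles channels, leaves F/B and shape unchanged
  r2 <- simulate_depth_response(slab, emission_params(988, 4, 2), geom, cfg)
  expect_equal(r2$forward_detected, 2 * r$forward_detected)
  expect_equal(r2$measured_fb, r$measured_fb)
  expect_equal(r2$normalized_forward, r$normalized_forward)
})

test_that("identical seeds reproduce the simulation bitwise", {
  slab <- matched_slab(mu_s_shg = 120, g = 0.85, mu_s_ex = 60)
  geom <- detection_geometry()
  cfg <- sim_config(n_photons = 3e3, rng_seed = 11,
                    depth_grid_cm = c(0, 0.005, 0.01))
  em <- emission_params(988, 5, 0.7)
  r1 <- simulate_depth_response(slab, em, geom, cfg)
  r2 <- simulate_depth_response(slab, em, geom, cfg)
  expect_identical(r1, r2)
  cfg2 <- cfg; cfg2$rng_seed <- 12
  r3 <- simulate_depth_response(slab, em, geom, cfg2)
  expect_false(identical(r1$forward_detected, r3$forward_detected))
})

test_that("shrinking the forward aperture shrinks forward detection", {
  slab <- matched_slab(mu_s_shg = 150, g = 0.8)
  cfg <- sim_config(n_photons = 2e4, rng_seed = 5, depth_grid_cm = 0.005)
  em <- emission_params(988, 2)
  fw <- vapply(c(0.9, 0.5, 0.2), function(na) {
    r <- simulate_depth_response(slab, em,
                                 detection_geometry(0.8, na, 1.33), cfg)
    r$forward_detected
  }, numeric(1))
  expect_true(all(diff(fw) < 0))
})
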