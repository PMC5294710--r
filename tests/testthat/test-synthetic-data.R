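test_that("built-in presets honor the established tissue orderings", {
  pr <- builtin_presets()
  expect_setequal(names(pr),
                  c("normal", "benign", "LGS", "endometrioid", "HGS"))
  musp <- vapply(pr, `[[`, numeric(1), "mus_prime_390")
  # HGS scatters most, endometrioid least
  expect_true(musp["HGS"] > max(musp[c("normal", "benign", "LGS")]))
  expect_true(musp["endometrioid"] < min(musp[c("normal", "benign", "LGS")]))
  # reported shape factors: LGS ~ endometrioid > normal > HGS > benign
  m <- vapply(pr, `[[`, numeric(1), "m_shape")
  expect_equal(unname(m[c("LGS", "endometrioid", "normal", "HGS", "benign")]),
               c(1.41, 1.40, 1.32, 1.17, 1.01))
  expect_true(min(m["LGS"], m["endometrioid"]) > m["normal"])
  expect_true(m["normal"] > m["HGS"] && m["HGS"] > m["benign"])
  # emission directionality at 988 nm: benign > LGS > normal > endo >= HGS
  fb <- vapply(pr, function(p) preset_curve_at(p$fb_curve, 988), numeric(1))
  expect_true(fb["benign"] > fb["LGS"] && fb["LGS"] > fb["normal"] &&
                fb["normal"] > fb["endometrioid"] &&
                fb["endometrioid"] >= fb["HGS"])
  # F/B rises with wavelength everywhere, most weakly for HGS
  slopes <- vapply(pr, function(p) {
    v <- p$fb_curve
    unname(coef(lm(log(v) ~ log(as.numeric(names(v)))))[2])
  }, numeric(1))
  expect_true(all(slopes > 0))
  expect_equal(names(which.min(slopes)), "HGS")
  # efficiency: HGS is the global maximum, peaking at 890 nm
  eff_max <- vapply(pr, function(p) max(p$efficiency_curve), numeric(1))
  expect_equal(names(which.max(eff_max)), "HGS")
  expect_equal(names(which.max(pr$HGS$efficiency_curve)), "890")
  eff988 <- vapply(pr, function(p)
    preset_curve_at(p$efficiency_curve, 988), numeric(1))
  expect_true(eff988["HGS"] > max(eff988[names(eff988) != "HGS"]))
})

test_that("noise-free transmission rows invert exactly to the preset", {
  pr <- builtin_presets()$LGS
  rows <- generate_scattering_measurements(pr, noise_cv = 0, seed = 1)
  mus <- mu_s_from_transmission(rows$transmitted_fraction,
                                rows$thickness_um * 1e-4)
  musp <- reduced_scattering(mus, rows$g)
  expect_equal(musp, preset_mus_prime(pr, rows$wavelength_nm),
               tolerance = 1e-9)
  short <- rows$wavelength_nm <= 535
  fit <- fit_power_law(scattering_spectrum(rows$wavelength_nm[short],
                                           musp[short]))
  expect_lt(abs(fit$m - pr$m_shape), 1e-6)
  # TIR columns encode the preset index
  expect_equal(refractive_index_from_tir(rows$critical_angle_deg[1] * pi / 180,
                                         rows$n_reference[1]),
               pr$n, tolerance = 1e-9)
})

test_that("mean recovered shape factor is unbiased at 5% noise", {
  pr <- builtin_presets()$normal
  ms <- vapply(1:60, function(s) {
    rows <- generate_scattering_measurements(pr, noise_cv = 0.05, seed = s)
    mus <- mu_s_from_transmission(rows$transmitted_fraction,
                                  rows$thickness_um * 1e-4)
    musp <- reduced_scattering(mus, rows$g)
    short <- rows$wavelength_nm <= 535
    fit_power_law(scattering_spectrum(rows$wavelength_nm[short],
                                      musp[short]))$m
  }, numeric(1))
  expect_lt(abs(mean(ms) - pr$m_shape), 0.1)
})

test_that("generated stacks match the forward model's expected totals", {
  pr <- builtin_presets()$normal
  pair <- generate_depth_stacks(pr, 988, seed = 21, image_shape = c(16, 16))
  gt <- attr(pair, "ground_truth")
  tot <- integrate_stack(pair)
  # integrate_stack undoes the calibration the generator applied
  e_fwd <- gt$expected_forward / pair$detector_calibration
  e_bwd <- gt$expected_backward
  expect_true(all(abs(tot$forward - e_fwd) <= 3 * sqrt(e_fwd) + 1e-9))
  expect_true(all(abs(tot$backward - e_bwd) <= 3 * sqrt(e_bwd) + 1e-9))
  # zero-efficiency preset emits a dark forward channel
  dark <- flat_fb_preset(3, efficiency = 0)
  pd <- generate_depth_stacks(dark, 988, seed = 22, image_shape = c(8, 8))
  expect_equal(sum(pd$forward_stack), 0)
  expect_equal(sum(pd$backward_stack), 0)
  expect_error(generate_depth_stacks(pr, 988, photon_scale = 0), "positive")
})

test_that("stack generation is deterministic under a fixed seed", {
  pr <- builtin_presets()$HGS
  p1 <- generate_depth_stacks(pr, 890, seed = 33, image_shape = c(8, 8))
  p2 <- generate_depth_stacks(pr, 890, seed = 33, image_shape = c(8, 8))
  expect_identical(p1$forward_stack, p2$forward_stack)
  p3 <- generate_depth_stacks(pr, 890, seed = 34, image_shape = c(8, 8))
  expect_false(identical(p1$forward_stack, p3$forward_stack))
})

test_that("feature cohorts reflect preset means and the seeding contract", {
  pr <- builtin_presets()
  ft0 <- generate_feature_cohort(pr, n_per_class = 3,
                                 within_class_cv = 1e-9, seed = 1)
  acc <- suppressWarnings(pairwise_classify(ft0))
  offdiag <- acc[upper.tri(acc)]
  expect_true(all(offdiag == 1))
  # class mean parameters are unchanged by cohort size
  ft4 <- generate_feature_cohort(pr, n_per_class = 4, seed = 1)
  expect_equal(attr(ft0, "ground_truth"), attr(ft4, "ground_truth"))
  expect_error(generate_feature_cohort(pr, n_per_class = 1), ">= 2")
})

test_that("identical presets classify at chance", {
  pr <- builtin_presets()
  twins <- list(a = pr$normal, b = pr$normal)
  twins$a$name <- "a"; twins$b$name <- "b"
  set.seed(2)
  accs <- vapply(1:15, function(s) {
    ft <- generate_feature_cohort(twins, n_per_class = 10,
                                  within_class_cv = 0.1, seed = 100 + s)
    suppressWarnings(pairwise_classify(ft))["a", "b"]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("a synthetic sample directory carries its ground truth", {
  pr <- builtin_presets()$endometrioid
  dir <- tempfile()
  generate_synthetic_sample(pr, dir, excitation_wavelengths_nm = 988,
                            n_fields = 1, seed = 5,
                            image_shape = c(8, 8))
  expect_true(file.exists(file.path(dir, "transmission.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "sample.yaml")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$preset, "endometrioid")
  expect_equal(gt$m_shape, pr$m_shape)
  man <- yaml::read_yaml(file.path(dir, "sample.yaml"))
  sub <- file.path(dir, man$fields[[1]]$path)
  pair <- read_stack_pair(sub)
  expect_equal(pair$excitation_wavelength_nm, 988)
})
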