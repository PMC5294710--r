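#!/usr/bin/env Rscript
# Inverts the cohort's measured depth responses into intrinsic F/B and
# relative SHG conversion efficiency: per sample and excitation
# wavelength, integrates the stacks, averages fields of view, builds (or
# reuses) the Monte Carlo lookup table for the sample's optical
# properties, and fits. Writes results/shg_metrics.csv.

library(shgscatter)

cohort <- yaml::read_yaml("results/cohort/cohort.yaml")
geometry <- detection_geometry()
photon_scale <- 2e6 # generator's detected-photon scale (known calibration)
cache <- new.env(parent = emptyenv())

rows <- do.call(rbind, lapply(cohort, function(entry) {
  sample_yaml <- yaml::read_yaml(file.path(entry$path, "sample.yaml"))
  fields <- sample_yaml$fields
  wls <- unique(vapply(fields, function(f) f$wavelength_nm, numeric(1)))
  scat <- read_scattering_csv(file.path(entry$path, "transmission.csv"))
  props <- lapply(seq_len(nrow(scat)), function(i)
    optical_properties(scat$wavelength_nm[i], scat$n_sample[i],
                       scat$mu_s[i], scat$g[i]))
  do.call(rbind, lapply(wls, function(wl) {
    pairs <- lapply(Filter(function(f) f$wavelength_nm == wl, fields),
                    function(f) read_stack_pair(file.path(entry$path, f$path)))
    resp <- normalize_attenuation(compute_depth_response(pairs))
    p_ex <- interpolate_optical_properties(props, wl)
    p_shg <- interpolate_optical_properties(props, wl / 2)
    slab <- tissue_slab(0.01, list(p_ex, p_shg))
    cfg <- sim_config(n_photons = 2e4, rng_seed = 7,
                      depth_grid_cm = resp$depth_um * 1e-4)
    key <- paste(entry$tissue, wl)
    tbl <- if (!is.null(cache[[key]])) cache[[key]] else
      cache[[key]] <- build_fb_lookup(slab, geometry, cfg, wl)
    fb <- extract_fb(resp, tbl)
    eff <- extract_conversion_efficiency(resp, slab, geometry, cfg,
                                         fb$intrinsic_fb, wl,
                                         scale = photon_scale, table = tbl)
    data.frame(sample = entry$sample, tissue = entry$tissue,
               wavelength_nm = wl, fb = fb$intrinsic_fb,
               fb_err = fb$fb_uncertainty, chi2 = fb$chi_square,
               accepted = fb$accepted,
               efficiency = eff$relative_efficiency)
  }))
}))
write.csv(rows, "results/shg_metrics.csv", row.names = FALSE)
agg <- aggregate(cbind(fb, efficiency) ~ tissue + wavelength_nm, rows, mean)
cat("Mean extracted intrinsic F/B and relative efficiency:\n")
print(agg, row.names = FALSE)
cat(sprintf("\nChi-square-accepted fits: %d of %d (rejections reflect the\n", sum(rows$accepted), nrow(rows)),
    "mismatch between measured-and-interpolated optics and the generating\n",
    "truth, the quality gate the goodness-of-fit flag exists for).\n")
cat("Expected: benign carries the largest F/B and HGS the smallest;",
    "HGS the highest conversion efficiency.\n")
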