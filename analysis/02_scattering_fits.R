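#!/usr/bin/env Rscript
# Fits the optical-scattering spectroscopy chain on the cohort's
# transmission files: Beer-Lambert mu_s, reduced scattering mu_s', and
# the power-law shape factor m over the 390-535 nm range. Writes
# results/scattering_fits.csv.

library(shgscatter)

cohort <- yaml::read_yaml("results/cohort/cohort.yaml")
rows <- do.call(rbind, lapply(cohort, function(entry) {
  d <- read_scattering_csv(file.path(entry$path, "transmission.csv"))
  d$mu_s_prime <- reduced_scattering(d$mu_s, d$g)
  short <- d[d$wavelength_nm <= 535, ]
  fit <- fit_power_law(scattering_spectrum(short$wavelength_nm,
                                           short$mu_s_prime))
  data.frame(sample = entry$sample, tissue = entry$tissue,
             n_sample_index = d$n_sample[1],
             mus_prime_390 = short$mu_s_prime[short$wavelength_nm == 390],
             m_shape = fit$m, amplitude_390 = fit$amplitude,
             residual_norm = fit$residual_norm)
}))
dir.create("results", showWarnings = FALSE)
write.csv(rows, "results/scattering_fits.csv", row.names = FALSE)
agg <- aggregate(cbind(mus_prime_390, m_shape) ~ tissue, rows, mean)
cat("Per-tissue mean reduced scattering at 390 nm and shape factor m:\n")
print(agg, row.names = FALSE)
cat("\nExpected pattern: HGS scatters most, endometrioid least;",
    "LGS/endometrioid carry the largest m, benign the smallest.\n")
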