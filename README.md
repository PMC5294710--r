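# shgscatter

Analysis chain for characterizing collagenous extracellular matrix (ECM)
from wavelength-dependent second harmonic generation (SHG) microscopy and
optical scattering spectroscopy, with ovarian tissue types as the driving
application.

SHG from collagen is created with an intrinsic forward/backward ratio,
F<sub>SHG</sub>/B<sub>SHG</sub>, set by fibril size and packing relative
to the SHG wavelength — but the microscope's two detectors see that ratio
only after the emitted photons have scattered through the turbid section.
The package decouples the two effects with a Monte Carlo photon-transport
forward model (homogeneous slab, Henyey–Greenstein phase function with
measured anisotropy *g*, Fresnel boundaries, NA-bounded forward/backward
detectors): measured F/B-versus-depth curves are inverted against lookup
tables of forward simulations to recover the intrinsic
F<sub>SHG</sub>/B<sub>SHG</sub> (best Pearson χ² fit over a candidate
grid), and the relative SHG conversion efficiency is the least-squares
scale between the measured forward attenuation curve and the
per-unit-efficiency prediction. In parallel, collimated transmission
measurements give the scattering coefficient by Beer–Lambert
(μ<sub>s</sub> = −ln T / t), the reduced scattering coefficient
μ<sub>s</sub>′ = μ<sub>s</sub>(1 − *g*), and the shape factor *m* from
the power law μ<sub>s</sub>′(λ) ∼ λ^(2m−4). The metric families combine
in a canonical linear discriminant with pairwise leave-one-out
accuracies, logistic-regression ROC curves, and ANOVA/Fisher-LSD group
comparisons.

Because the original patient measurements are not deposited, a
first-class synthetic-data module generates every input from known
ground truth — depth-resolved two-channel TIFF stacks, transmission
spectra, labeled feature cohorts — including five tissue presets (normal
stroma, benign, low-grade serous, endometrioid, high-grade serous) that
honor the established qualitative orderings of the four metrics.

## Worked example

Generate a synthetic high-grade-serous sample, turn its stacks into a
measured depth response, and invert:

```r
library(shgscatter)

preset <- builtin_presets()$HGS           # ground truth: F/B = 2 at 988 nm
pairs <- lapply(1:3, function(f)
  generate_depth_stacks(preset, 988, seed = 100 + f))
resp <- normalize_attenuation(compute_depth_response(pairs))

slab <- preset_slab(preset, 988)
cfg  <- sim_config(n_photons = 2e4, rng_seed = 7,
                   depth_grid_cm = resp$depth_um * 1e-4)
tbl  <- build_fb_lookup(slab, detection_geometry(), cfg, 988)
fb   <- extract_fb(resp, tbl)
eff  <- extract_conversion_efficiency(resp, slab, detection_geometry(),
                                      cfg, fb$intrinsic_fb, 988,
                                      scale = 2e6, table = tbl)
fb$intrinsic_fb;  fb$chi_square;  fb$accepted;  eff$relative_efficiency
#> [1] 2
#> [1] 2.774184
#> [1] TRUE
#> [1] 0.8520731
```

The measured F/B at the surface is ~1.3 — photon migration has mixed the
channels — yet the inversion recovers the generating intrinsic F/B of 2
exactly (a grid candidate) with an accepted χ², and the conversion
efficiency 0.852 against a ground truth of 0.85.

The numbered scripts under `analysis/` run the whole study on a
generated cohort and narrate what they find, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # synthetic samples on disk
Rscript analysis/02_scattering_fits.R     # mu_s' spectra and shape factor m
Rscript analysis/03_extract_shg_metrics.R # F/B + efficiency inversion
Rscript analysis/04_classification.R      # discriminant, LSD, ROC
Rscript analysis/05_report.R              # end-to-end run + figures
```

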