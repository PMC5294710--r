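---
title: "Methods: SHG emission directionality, optical scattering, and tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SHG emission directionality, optical scattering, and tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Second harmonic generation (SHG) microscopy of collagen produces photons
at half the excitation wavelength with an intrinsic forward/backward
creation ratio, F~SHG~/B~SHG~, set by fibril size and packing relative to
the SHG wavelength. What the two detectors of an SHG microscope record,
however, is not that ratio: emitted photons scatter on their way to the
slab faces, so the *measured* F/B versus depth curve mixes the creation
anisotropy with photon migration through the turbid section. The same
confound affects the SHG conversion efficiency, whose depth profile is
shaped by both the quadratic attenuation of the focused excitation and
the migration of the emitted photons.

This package implements the computational chain that undoes that
confound: a Monte Carlo photon-transport forward model predicts the
measured two-channel depth response for any candidate intrinsic F/B
given the section's measured optical properties; the candidate whose
prediction best matches the measurement (Pearson chi-square) is the
extracted F~SHG~/B~SHG~, and the least-squares scale between the measured
absolute forward curve and the per-unit-efficiency prediction is the
relative conversion efficiency. Independently, collimated transmission
spectroscopy yields the scattering coefficient via Beer-Lambert,
the reduced scattering coefficient mu~s~' = mu~s~(1 - g), and the
power-law shape factor m from mu~s~'(lambda) ~ lambda^(2m-4). The three
metric families feed a canonical linear discriminant for tissue
classification.

# The transport model and its assumptions

Photons are created at the focal depth inside a single homogeneous slab
(the sections are thin and uniform; the kernel follows the classic
multi-layer Monte Carlo conventions) and random-walk with exponential
step lengths, Henyey-Greenstein deflection with the measured anisotropy
g, weight-decay absorption, and Russian roulette (threshold 1e-4,
survival 0.1). At the faces, unpolarized Fresnel reflection/refraction
against the surrounding media decides escape; escaping photons count as
detected when the refracted angle lies inside the matching detector's
acceptance cone, `asin(NA / n_immersion)`, with NA 0.8 for the epi
(objective) side and 0.9 for the trans (condenser) side by default.

Choices where the underlying procedure is not fully constrained, and why:

* **Excitation delivery.** The focal SHG source strength is attenuated as
  `exp(-2 mu_s,ex z)` — ballistic-only delivery squared, because SHG is
  quadratic in excitation intensity and scattered excitation light does
  not contribute to the focal volume of a high-NA focus.
* **Emission lobe.** Photons launch uniformly in solid angle within a
  cone about the axial direction (forward with probability
  `fb / (1 + fb)`), with half-angle defaulting to the focusing
  half-angle of the NA 0.8 water-immersion objective. Only the F/B split
  is physically constrained; the lobe shape is a modeling choice and is
  configurable.
* **Roulette bookkeeping.** Terminated weight goes to the absorbed sink
  and the survivor boost is drawn from it, so every tally sums to the
  launched weight to machine precision while remaining unbiased in
  expectation; the `absorbed` field therefore reads "absorbed or
  terminated, net of roulette".
* **Absorption.** mu~a~ defaults to zero (fibrillar tissue has
  mu~a~ << mu~s~); nonzero values are carried when supplied explicitly.
* **Boundaries.** Water immersion above (n = 1.33) and an aqueous mount
  below; internally reflected photons keep propagating. A fresh
  exponential step is drawn after each boundary interaction, which is
  statistically identical to carrying the unused step by memorylessness.

# The inversion

Lookup tables hold one simulated F/B-versus-depth curve per intrinsic-F/B
candidate (default grid: 0.25 to 16 in 33 logarithmic steps). Because
photon transport is linear in the launch mixture, one seeded pair of
kernel runs per depth — all photons launched forward, then all backward —
composes *exactly* into any candidate's curve; this superposition
identity makes tables cheap, guarantees the identical config/seed policy
across candidates, and lets the refinement pass (step-halving around the
chi-square minimum) re-evaluate the same seeded simulation rather than
re-simulate.

The chi-square uses per-depth variances from replicate fields of view
when at least two are available, otherwise Poisson propagation of the
two channel intensities, plus — in quadrature — the lookup curve's own
Monte Carlo standard error from the effective detected photon counts.
Without the latter term the statistic rejects good fits whenever the
measurement is more precise than the simulation. A fit is `accepted`
when the chi-square p-value is at least 0.05 with depths - 1 degrees of
freedom; this mirrors the chi-square equivalence gate on the optimized
simulation, with the threshold and df convention being package choices.
Grid ties report the lower candidate and widen the uncertainty interval
to cover both.

Efficiency extraction fits the *absolute* calibrated forward curve
against the per-unit-efficiency prediction for scale (instrument
constants fold into the scale, so only between-sample ratios are
meaningful) and reports the RMS difference of the self-normalized curves
as a shape diagnostic. Optical properties at unmeasured wavelengths are
interpolated log-log in wavelength for mu~s~ (the form a power law makes
exact) and linearly for g and n.

# Scattering spectroscopy

`mu_s_from_transmission` inverts `T = exp(-mu_s t)`; the 50 um section
thickness used by the synthetic presets puts the measured optical depths
in the 0.5–1.5 range. The shape-factor fit is ordinary least squares on
`ln mu_s'` versus `ln lambda` over the 390–535 nm points (the short-
wavelength range carries the structural discrimination); the slope s
maps to m = (s + 4) / 2 and the amplitude is reported at 390 nm, the
shortest measured wavelength. A weighted variant using per-wavelength
standard errors exists; with only three replicate locations the
replicate-based weights are themselves noisy and were measurably worse
in calibration runs, so the unweighted fit is the default.

# The synthetic cohort: what it emulates and what it does not

The generator produces every input the chain consumes from known ground
truth: transmission rows (`exp(-mu_s t)` with multiplicative log-normal
noise, 5% coefficient of variation per reading, three independent
locations averaged per specimen), and two-channel image stacks whose
per-slice expected totals come from the same forward model, with
per-pixel Poisson draws around an oriented band-pass-filtered-noise
texture standing in for fibers. The detector calibration factor (default
1.6) multiplies the forward channel exactly as a real gain mismatch
would, and is undone by `integrate_stack`.

The five built-in presets emulate normal stroma, benign tumor, low-grade
serous, endometrioid, and high-grade serous ECM. Their shape factors are
literature values for ovarian ECM (benign 1.01, HGS 1.17, normal 1.32,
endometrioid 1.40, LGS 1.41); everything else — mu~s~'(390) anchors of
20–40 cm^-1, F/B curves rising with wavelength (most weakly for HGS),
an HGS efficiency curve peaking at 890 nm while the others rise slowly
— consists of synthetic package constants chosen once to honor the
established qualitative orderings (HGS scatters most and converts most
efficiently with the smallest F/B; benign carries the largest F/B and
the least sub-micron order; endometrioid scatters least). Cohort sizes
default to the study design: 4, 4, 4, 3, 3 specimens.

Two features of real data are deliberately absent, which bounds what
passing tests demonstrate. First, samples within a synthetic class share
one ground truth, so within-class spread comes from measurement noise
alone; pairwise classification accuracies on pipeline-derived features
therefore saturate near 1.0, unlike the 65–97% range real biological
variability produces (the classifier's calibration is instead tested on
cohorts with controlled within-class variance). Second, the spatial
texture is a noise surrogate, adequate for intensity integrals and
diameter phantoms but not a biophysical fiber-network model.

# Stochastic endpoints and problem sizes

The end-to-end ordering check is a stochastic endpoint: with 50 um
sections, 5% transmission noise, three locations, and 3–4 specimens per
class, the per-class shape-factor standard error (~0.07 for the weakly
scattering endometrioid) is comparable to the 0.08–0.09 gaps separating
normal from LGS/endometrioid; at this resolution LGS and endometrioid
are not distinguishable from each other by m at all. A
single cohort draw reproduces all orderings in roughly 85–90% of seeds.
The package therefore states the ordering property over replicate
cohorts: five independent runs, with every relation required to hold in
the majority of runs and in the pooled class means.

Default problem sizes, chosen as a deliberate precision/runtime balance
for a single-workstation analysis: 2x10^4 photons per depth point for
lookup tables (the table's Monte Carlo error then contributes less than
the measurement error to the chi-square), 10^4–10^5 for oracle checks,
10 um z-steps over 100 um sections, 16x16 to 24x24 pixel fields with a
detected-photon scale of ~10^6 per stack. The acceptance script and the
test suite recompute everything from scratch at these sizes.

# Numerical details worth knowing

* All randomness flows through R's RNG; every generator and simulation
  accepts a seed, sub-seeds derive deterministically from the global
  seed, and execution is sequential, so identical configurations
  reproduce outputs byte-for-byte.
* The Henyey-Greenstein sampler switches to the isotropic branch for
  |g| < 1e-8; the boundary Fresnel code special-cases near-normal
  incidence to avoid 0/0.
* Detector-acceptance comparisons carry a 1e-12 cosine epsilon so an
  emission cone exactly matching an acceptance cone does not drop edge
  photons to rounding.
* `normalize_attenuation` reads the "average maximum" as the mean of the
  top k = 3 per-slice forward totals, robust to single-slice noise; the
  surface slice is the first whose forward total exceeds 10% of the
  stack maximum (sections sit in mounting medium).
* The fiber-diameter estimator replaces manual profile placement with
  the gradient structure tensor in a Gaussian window (sigma 3 px): the
  principal eigenvector points across the fiber, and the above-threshold
  run length along it, with the crossing taken at the midpoint of the
  last passing 0.25 px step, is the diameter. On bar phantoms this is
  unbiased to within a pixel across orientations; the residual
  threshold-dependence of edge placement is inherent to thresholded
  profiles.
* Canonical discriminant analysis shrinks the pooled within-class
  scatter toward its diagonal (lambda 1e-3) because 3–4 samples per
  class with ~9 features make the scatter singular; the warning this
  logs in tiny-cohort runs is expected. Classification is nearest
  centroid in canonical space with equal priors; validation is
  leave-one-out by default with resubstitution behind a flag.
* `roc_from_logistic` sweeps the raw score when given a single
  predictor — a refitted logistic slope would silently flip a
  reversed score's direction — and the fitted probability for
  multivariate input; the trapezoid AUC then equals the tie-corrected
  normalized Mann-Whitney U exactly.

# Known limitations

The transport model is scalar (no polarization), steady-state, and
single-layer by default; the emission lobe within the cone is an
assumption, not a measurement; the chi-square acceptance threshold and
degrees-of-freedom convention are package choices; g arrives as a
measured input rather than being inverted from goniometry; and the
synthetic cohort's saturated classification accuracies mean Table-level
accuracy values from patient data are out of reach by design — only the
qualitative orderings and the calibration properties are claimed.
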