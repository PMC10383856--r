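# ramankin

Low-frequency Raman spectroscopy (LFRS, Raman shifts below ~150 cm⁻¹)
probes the lattice and collective vibrations that fingerprint crystalline
forms of molecular solids. Followed in situ during a solid-state
transformation — for example the dehydration of a pharmaceutical hydrate
into its anhydrate — it yields the transformation kinetics and the
mechanism behind them. `ramankin` is an R package for that workflow,
aimed at solid-state spectroscopists and formulation scientists:

* **Intensity transforms.** Raw Stokes intensity is dominated at low
  frequency by the thermal occupation of the modes. The package applies
  the Bose-factor reduction
  `Ir(ω) = I(ω,T) / [(n(ω,T)+1)·ω]`, with
  `n(ω,T)+1 = 1/(1 − exp(−c₂ω/T))` and c₂ = hc/k_B = 1.4387769 cm·K,
  and the Raman susceptibility `χ″(ω) = ω·Ir(ω)`, plus an optional
  `(ω₀−ω)⁴` spectrometer-response correction.
* **Spectral decomposition.** The low-frequency spectrum is fitted as a
  zero-centered Lorentzian quasi-elastic component (QES, from fast local
  relaxational motions), a lognormal vibrational density of states, and
  pseudo-Voigt phonon peaks; `qes_trace()` follows the integrated QES
  intensity along a temperature or time ramp.
* **Transformation kinetics.** A time series of spectra is converted to a
  transformation fraction ρ(t) ∈ [0,1] by non-negative two-endmember
  unmixing (ρ = b/(a+b) from `I_t ≈ a·S_hydrate + b·S_anhydrate`) or by
  tracking the area of the hydrate water-marker band near 80 cm⁻¹.
  ρ(t) is then fitted against a catalog of solid-state kinetic models —
  Avrami nucleation-and-growth `ρ = 1 − exp(−k·tⁿ)`, the Jander
  three-dimensional diffusion law `[1 − (1−ρ)^{1/3}]² = k·t`, and the
  classical D1/D2/D4/R2/R3/F1 forms — with AICc model ranking,
  half-transformation times and `t/t₁/₂` master curves.
* **Synthetic ground truth.** A fully seeded generator builds hydrate and
  anhydrate endmember spectra, evolves their mixture under a chosen
  kinetic law, and converts it to raw counts through the exact inverse of
  the Bose reduction, so every pipeline stage can be validated against
  known parameters without instrument data.

The package is tidyverse-native: spectra, series and transformation
curves are tibbles, fitted objects have `tidy()`/`glance()` methods, and
every result type has an `autoplot()`.

## Worked example

Simulate a theophylline-style dehydration (Avrami law, n = 2.95,
t₁/₂ = 100 min, 60 spectra, 0.5% noise), recover ρ(t) and fit kinetics:

```r
library(ramankin)

fx  <- fixture("tp_noRH")
sim <- simulate_dehydration(fx$hydrate, fx$anhydrate, fx$sim)

red   <- reduce_intensity(sim$series)          # Bose-factor reduction
curve <- transformation_rate_unmix(
  red, as_reduced(sim$ref_hydrate), as_reduced(sim$ref_anhydrate))

fit <- fit_kinetics(curve, "avrami")
fit
#> <kinetic_fit> avrami (nucleation and growth (Avrami), rho = 1 - exp(-k t^n))
#>   k = 8.05268e-07 +/- 4.5e-08 min^-n
#>   n = 2.9683 +/- 0.0119
#>   R^2 = 0.999928, AICc = -158.69, points = 14
half_time(curve)
#> [1] 99.79143
```

The fitted exponent 2.97 ± 0.01 recovers the generating n = 2.95 (an
exponent near 3 indicates nucleation with two-dimensional growth), and
t₁/₂ recovers the generating 100 min. Ranking the full model catalog
confirms the generating mechanism wins decisively on AICc:

```r
select_model(curve)[1:3, c("rank", "model", "k", "n", "r_squared", "aicc")]
#>   rank  model         k     n r_squared    aicc
#> 1    1 avrami 8.053e-07 2.968    0.9999 -158.69
#> 2    2     R2 2.922e-03    NA    0.7315  -46.93
#> 3    3     R3 2.036e-03    NA    0.7046  -45.60
```

`run_pipeline()` wraps the same steps (simulation or measured manifests,
reduction, ρ extraction, model ranking) behind a single YAML-configurable
call that writes `rho.csv`, `fit.json` and a text report.

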