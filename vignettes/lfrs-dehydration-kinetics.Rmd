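---
title: "Low-frequency Raman processing and dehydration kinetics with ramankin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-frequency Raman processing and dehydration kinetics with ramankin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramankin)
```

## The problem

Crystalline hydrates of drug molecules lose their structural water under
heat or low humidity, converting to an anhydrous form whose solubility
and stability can differ substantially. Low-frequency Raman spectroscopy
(LFRS; Raman shifts of roughly 5–150 cm⁻¹) resolves the lattice phonons
that fingerprint each crystalline form and can be acquired fast enough
to follow the conversion in situ. `ramankin` turns an ordered series of
such spectra into a transformation-rate curve $\rho(t)$ and a fitted
solid-state kinetic mechanism.

This vignette documents the models, the defaults and the numerical
choices, in the order the pipeline applies them.

## Intensity representations

Raw Stokes intensity at low frequency is dominated by the thermal
population of the modes. With the Bose occupation factor

$$n(\omega, T) + 1 = \frac{1}{1 - e^{-c_2 \omega / T}},
  \qquad c_2 = hc/k_B = 1.4387769\ \mathrm{cm\,K},$$

the package works in three representations:

* **raw** counts $I(\omega, T)$ as acquired;
* **reduced** intensity $I_r(\omega) = I(\omega,T) / [(n+1)\,\omega]$,
  which removes the trivial temperature dependence;
* **susceptibility** $\chi''(\omega) = \omega\, I_r(\omega)$, convenient
  for comparing ordered and disordered states. Composing the two
  transforms gives the identity $\chi'' = I/(n+1)$.

Assumptions: Stokes side only; the coupling coefficient relating
$\chi''$ to the vibrational density of states is never separated out —
only the product $\omega I_r$ is computed. The division by $\omega$ is
handled by a hard low-frequency **cutoff** (default 5 cm⁻¹, the
practical rejection limit of high-dispersion spectrometers), not by
regularization: points below the cutoff are dropped, matching what such
instruments actually measure. Temperatures are carried in kelvin
internally; manifests accept °C because that is how experiments are
logged ($K = °C + 273.15$).

An optional $(\omega_0-\omega)^4$ response correction is provided
(`omega4_correct()`), normalized to 1 at $\omega = 0$ so intensity
scales stay comparable. It is off by default in the pipeline: the
fourth-power dependence is a proportionality of the raw signal, and both
$\rho$ estimators below are insensitive to smooth multiplicative
envelopes of this kind.

## Spectral decomposition

`fit_decomposition()` models a reduced or susceptibility spectrum over a
window (default 5–150 cm⁻¹) as a sum of:

* **QES** — quasi-elastic scattering from fast local relaxational
  motions, the Stokes half of a Lorentzian centered at $\omega = 0$:
  $A\,\Gamma^2/(\omega^2+\Gamma^2)$ with half-width $\Gamma$ (cm⁻¹);
* **lognormal VDOS** — the broad vibrational envelope of disordered
  states, $A \exp[-\ln^2(\omega/\omega_c) / (2\sigma^2)]$,
  parameterized by its mode position $\omega_c$ (cm⁻¹) and
  dimensionless log-width $\sigma$ (the shape is named in the
  literature; this parameterization is the package's, chosen so each
  parameter has a direct reading);
* **phonon peaks** — pseudo-Voigt profiles with free Lorentzian
  fraction $\eta \in [0,1]$, equal Gaussian/Lorentzian widths and
  amplitude equal to peak height.

The fit is bounded Levenberg–Marquardt least squares (`minpack.lm`),
template-driven: the user supplies components with initial values and
box bounds, and no automatic peak detection is attempted — identifiable
low-frequency fits in practice come from a physically chosen template,
and identifiability is enforced through bounds rather than penalties.
Weights default to uniform. The iteration cap is 500; convergence
tolerances are set near machine precision so that noiseless synthetic
spectra are reproduced essentially exactly (the test suite requires
parameter recovery to 1 part in 10⁶ and residuals below $10^{-8}$ of
the maximum intensity).

The quasi-elastic intensity $I_{QES}$ is reported as the **integrated
Lorentzian area over the fit window**,
$A\Gamma[\arctan(\omega_{hi}/\Gamma) - \arctan(\omega_{lo}/\Gamma)]$,
not the peak amplitude: amplitude and width trade off strongly in this
fit, while their product's windowed integral is stable. Standard errors
are asymptotic, from the Jacobian cross-product at the solution;
$I_{QES}$ uncertainty follows by the delta method. `qes_trace()` fits a
whole series in axis order, warm-starting each fit from the previous
spectrum's estimates; an individual non-convergence flags that row
rather than aborting the trace.

## From spectra to a transformation fraction

The published record for this kind of experiment typically describes
the $\rho$ extraction only in appendix figures, so the package
implements two explicit, documented estimators and treats them as
cross-checks of one another:

* **Unmixing (primary).** Each spectrum is modelled as a non-negative
  combination $I_t \approx a\,S_{hydrate} + b\,S_{anhydrate}$ of two
  endmember references (non-negative least squares, `pracma`), and
  $\rho = b/(a+b)$. Closure $a+b=1$ is deliberately **not** imposed:
  overall scattering efficiency can drift during dehydration, and the
  abundance ratio is invariant under any uniform rescaling of the
  series. Unmixing operates on reduced intensity by default, so the
  Bose temperature dependence is already removed.
* **Band-area tracking (secondary).** The trapezoidal area $A(t)$ of
  the hydrate water-marker band (default window 60–100 cm⁻¹,
  bracketing the band near 80 cm⁻¹ that vanishes on dehydration) is
  anchored to the first and last spectra:
  $\rho(t) = (A_0 - A(t))/(A_0 - A_\infty)$. The complementary
  normalized area is reported as the `water_escape` trace. Anchoring
  assumes the series starts essentially unconverted and ends essentially
  converted; an incomplete run biases this estimator, which is one
  reason unmixing is the default.

$\rho$ is clipped to $[0,1]$ after estimation. The half-transformation
time $t_{1/2}$ is obtained by linear interpolation at the **first
upward crossing** of $\rho = 0.5$ (a sample exactly at 0.5 counts);
first-crossing keeps the value deterministic when noise makes the curve
graze 0.5 repeatedly. `master_curve()` rescales time by $t_{1/2}$;
curves sharing one mechanism collapse in this representation (for the
Avrami law $\rho = 1 - \exp(-\ln 2\,(t/t_{1/2})^n)$, free of $k$).

## Kinetic models and fitting

The catalog holds the eight classical isothermal solid-state forms
$g(\rho) = kt$: diffusion (D1, D2, D3 = Jander
$[1-(1-\rho)^{1/3}]^2$, D4 = Ginstling–Brounshtein), phase-boundary
(R2, R3), first-order (F1), and the Avrami nucleation-and-growth law
written as $\rho(t) = 1 - \exp(-k\,t^n)$ — note $k$ then carries units
min⁻ⁿ; `avrami_k_convert()` moves to the $(k_1 t)^n$ convention. New
models can be registered at run time.

Numerical choices:

* D2 and D4 have no closed-form $\rho(t)$; their monotone $g$ is
  inverted by a vectorized bisection (80 halvings, i.e. resolution
  ~$10^{-24}$), which keeps the integral and closed forms mutually
  consistent to well below the $10^{-10}$ the tests demand.
* `fit_kinetics()` performs nonlinear least squares on $\rho(t)$ with
  the rate constant parameterized as $\log k$ for conditioning (Avrami
  $k$ values for slow conversions are of order $10^{-7}$ min⁻ⁿ).
  The Avrami fit is initialized by the Sharp–Hancock linearization
  (slope of $\ln[-\ln(1-\rho)]$ vs $\ln t$); one-parameter models start
  from the median of $g(\rho)/t$. Both direct and linearized views are
  thus used: linearization to start, direct least squares to finish.
* The default fit window keeps $\rho \in [0.05, 0.95]$ (at least 6
  points required): baseline noise at the start and saturation at the
  end otherwise bias the mechanism parameters. The window is a
  documented, overridable default.
* Model ranking uses AICc (with the residual variance counted as a
  parameter); $R^2$ is reported alongside. For ranking, the residual
  sum of squares is floored at $10^{-20}$ per point: noiseless data
  fitted exactly by two nested models would otherwise be ranked on
  floating-point dust, whereas with the floor exact fits tie and the
  ranking falls to parsimony, then to lexical model id — fully
  deterministic. F1 is mathematically the $n=1$ Avrami law, so on
  F1-generated data the one-parameter form wins by parsimony, which is
  the intended behaviour.
* Parameter uncertainties are asymptotic (curvature-based), matching
  the "±" convention of published exponents.

## The synthetic generator

Because in situ dehydration series are rarely deposited, the package
ships a generator (`endmember()`, `simulate_dehydration()`,
`fixture()`) whose defaults encode the study conditions the package is
tested under:

* Endmembers are deterministic sums of the decomposition components on
  a 5–200 cm⁻¹ grid with 0.5 cm⁻¹ step (a typical acquisition range and
  a convention, since instrument export steps vary). The hydrate carries
  a broad water-marker band near 80 cm⁻¹; the anhydrate an extra
  lattice mode near 25 cm⁻¹ and a stronger QES (disorder left by water
  escape). The tables are styled on xanthine-family features without
  claiming spectroscopic accuracy; by construction the hydrate's
  60–100 cm⁻¹ band area exceeds the anhydrate's at least five-fold, so
  band tracking is well-posed.
* The mixture $(1-\rho^*)S_h + \rho^* S_a$ evolves under the chosen
  kinetic law; additive Gaussian noise (fraction `noise_sigma` of the
  maximum endmember susceptibility, homoscedastic in susceptibility
  units) is applied before conversion to raw counts via multiplication
  by $(n+1)$ — the exact inverse of the Bose reduction, so at zero
  noise the full pipeline recovers $\rho^*$ to machine precision.
* The three packaged fixtures encode: `tp_noRH` — Avrami with
  $n = 2.95$ (theophylline-style dehydration without humidity
  control); `tp_1RH_23C` — Jander diffusion at 23 °C / 1 % RH;
  `caf_20RH` — Avrami with $n = 1.410$ (caffeine-style, nucleation
  with quasi-absent growth). Reported half-times for such experiments
  are graphical only, so the fixtures' $t_{1/2}$ (100 / 600 / 200 min)
  are desk-scale choices, with $k$ derived as $\ln 2 / t_{1/2}^n$
  (Avrami) or $g(1/2)/t_{1/2}$ (Jander); only the exponents and
  mechanisms are anchored to reported fits. Each fixture uses 60 time
  points log-spaced from $t_{1/2}/100$ to $4\,t_{1/2}$ — log spacing
  resolves both the onset and the approach to saturation — with noise
  $\sigma = 0.005$ and a fixed documented seed (42, 44, 43
  respectively). All randomness flows through that one seed.

What the generator does **not** emulate: Poisson (shot) noise, baseline
drift and cosmic rays, intermediate metastable forms as distinct
endmembers, and instrument response curves. Passing tests therefore
demonstrate the estimators' correctness and noise robustness under
additive Gaussian conditions, not robustness to baseline artifacts or
multi-phase mixtures — on real data those require inspection of the
unmixing residuals.

## Problem sizes and determinism

The validation suite runs at desk scale by design: 60-spectrum series
on a 391-point grid for the end-to-end recoveries, 100-seed Monte Carlo
loops for the noise-robustness statements (unmixing RMSE below 0.02 at
1 % noise; the Jander fixture's mechanism identified first in at least
90 of 100 noisy replicates; decomposition parameters within 5 % in at
least 95 of 100 replicates), and 200 simulated curves for exponent
recovery (median error below 0.02). Fixed seeds make every such number
reproducible bit-for-bit; `run_pipeline()` outputs are byte-identical
across reruns of one configuration.

## Known limitations

* Two-endmember unmixing cannot represent intermediate crystalline
  forms; a three-phase series will show structured unmixing residuals
  and a $\rho(t)$ that is a projection, not a phase fraction.
* The band-area estimator depends on its endpoint anchoring and on the
  60–100 cm⁻¹ window being free of interfering modes in the anhydrate.
* Kinetic fits are isothermal; non-isothermal analysis
  (Kissinger/Friedman) and Arrhenius activation energies across
  temperatures are out of scope.
* Decomposition standard errors assume independent homoscedastic
  residuals; correlated baselines inflate them unpredictably.
* JCAMP-DX and binary vendor formats (SPC, WDF) are not read; spectra
  are exchanged as two-column ASCII with `#` metadata comments.
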