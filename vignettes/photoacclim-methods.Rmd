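---
title: "Models and methods behind photoacclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoacclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoacclim)
```

# Scope

`photoacclim` quantifies the photosynthetic phenotype that distinguishes
*Chlamydomonas reinhardtii* cells acclimated to extreme light (EL, PPFD
3000 µmol m⁻² s⁻¹, about 1.5× full sunlight) from cells grown at moderate
light. Each measurement type has a generator that emulates the instrument
signal and an analysis operator that extracts the physiological quantity,
so the complete pipeline — and every number it reports — can be exercised
without access to measured data. This vignette explains the models, the
parameter choices that were genuinely open, and what the synthetic data do
and do not demonstrate.

# Thermoluminescence: the Randall–Wilkins band

During a linear heating ramp $T = T_0 + \beta t$, charge pairs trapped in
photosystem II recombine as a first-order reaction with an Arrhenius rate
constant

$$k(T) = s\, e^{-E_a / (k_B T)},$$

and the glow intensity is the recombination rate itself,
$I(T) = k(T)\, n(T)$ with
$n(T) = n_0 \exp\!\big(-\tfrac{1}{\beta}\int_{T_0}^{T} k(T')\,dT'\big)$.
Defaults are the standard instrument ramp: $T_0 = 274$ K to
$T_{\mathrm{end}} = 340$ K at $\beta = 0.66$ K s⁻¹, activation energy
$E_a = 0.501$ eV (501 meV), $n_0 = 1$ (only relative intensities matter;
the initial trapped population is not observable on this scale).

Two design points are worth stating:

* **The depletion integral is simulated, not just $k(T) n_0$.** Because the
  intensity is the depletion rate, the time-integral of the band equals the
  charge released, $n_0 - n(T_{\mathrm{end}})$; the suite checks this
  conservation identity to $10^{-6}\,n_0$. The quadrature is trapezoidal on
  a uniform grid with step $dT = 0.01$ K — the integrand is smooth and the
  resulting peak error is orders of magnitude below the 0.1 °C at which
  band positions are reported.
* **Peak condition as independent route.** At the glow maximum
  $\beta E_a / (k_B T_m^2) = s\, e^{-E_a/(k_B T_m)}$. `solve_peak_condition()`
  brackets this root, and `s_from_peak()` is its closed-form inverse; the
  fixture generator uses the inverse to place a band at a prescribed
  temperature, and the tests require the simulator's argmax and the
  analytic root to agree within the grid spacing — a non-circular check of
  both routes. The peak reported by `band_features()` is refined by
  parabolic interpolation through the top three grid points, and the width
  by linear interpolation of the half-maximum crossings.

Lowering $s$ from $1.7\times10^7$ through $1.2\times10^7$ to
$9\times10^6$ s⁻¹ shifts the peak upward and widens the band, the
qualitative behaviour that makes a lowered pre-exponential factor a
plausible explanation of the wider, up-shifted B band of EL cells. Fitting
$(s, E_a)$ to measured glow curves is deliberately out of scope.

# First-order kinetics and the damage–repair model

Charge recombination (+DCMU flash decays) and the damaging reaction of
photoinhibition (+lincomycin oxygen time courses) are both fitted as
$v(t) = b + a e^{-kt}$ by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). The baseline is fixed at 0 by default: both decays
are complete in their respective models, and the published fits are simple
exponentials. The automatic initial rate is $\ln 2$ over the observed
half-decay time, with restarts at 10× and 0.1× on non-convergence;
constant series fail early with an explicit "no decay" condition rather
than returning a spurious rate. Parameter recovery is verified to
$10^{-6}$ relative error over $k \in [10^{-4}, 10^2]$ s⁻¹ on noiseless
grids, and to <5 % bias across 50 noise realisations at $\sigma = 0.01$.

Without lincomycin, damage (rate $k_{PI}$) and repair (rate $k_{rec}$) run
concurrently:

$$\frac{dA}{dt} = -k_{PI} A + k_{rec}(A_0 - A), \qquad
A(t) = A_{eq} + (A_0 - A_{eq})e^{-(k_{PI}+k_{rec})t}, \qquad
A_{eq} = A_0 \frac{k_{rec}}{k_{PI}+k_{rec}}.$$

The closed form is cross-checked against numerical ODE integration
(`deSolve::lsoda`) to $10^{-6}$. `fit_damage_repair()` solves the inverse
problem with $k_{PI}$ held at the value measured in the matching
+lincomycin experiment — the identification strategy a practitioner would
use, since $(k_{PI}, k_{rec})$ are poorly separable from a single plateau
curve.

# Fluorescence features

**OJIP induction.** $F_0$ is operationalised as the earliest recorded
sample (AquaPen-class instruments report their first reliable point tens
of µs after light-on; no explicit read-point is defined by the
measurement), $F_M$ as the global maximum, and
$F_V/F_M = (F_M - F_0)/F_M$. J and I step levels are read at the
conventional 2 ms and 30 ms by interpolation on a logarithmic time axis.
A trace still rising at its last sample gets a "truncated induction"
warning instead of a silent wrong $t_{F_M}$.

**77 K spectra.** The PSII/PSI emission ratio is the quotient of the band
maxima in 675–700 nm and 705–725 nm, windows that bracket the classic
685–695 nm (PSII) and 713–720 nm (PSI) emission peaks; the ratio
definition names no wavelengths, so fixed search bands around the textbook
maxima are the design choice, and the ratio is provably invariant to the
713 nm normalisation applied for display.

# Assays

* **Pigments.** The Wellburn (1994) methanol equations for 1–4 nm
  spectrophotometer resolution are pinned as constants
  (chl a = 16.72·A₆₆₅.₂ − 9.16·A₆₅₂.₄, chl b = 34.09·A₆₅₂.₄ − 15.28·A₆₆₅.₂,
  carotenoids = (1000·A₄₇₀ − 1.63·chl a − 104.96·chl b)/221, µg ml⁻¹).
  The synthetic inverse solves the corresponding 3×3 linear system, so the
  forward map is testable by exact roundtrip (10⁻⁹).
* **SOSG.** The per-period slope is an endpoint difference quotient, not a
  regression: the instrument records one point per 10-min period boundary.
  The statistic is the mean over three consecutive periods and is invariant
  to any constant offset.
* **Growth.** A culture counts as acclimated at a horizon if its OD₇₃₀
  reached 0.05 at any sampled time up to that horizon (cumulative
  interpretation of daily readings), which makes the percentages
  non-decreasing in the horizon by construction.

# The synthetic-data generators

The presets *are* the published phenotypes: every constant a generator
needs (rates, $F_0/F_M$, band peaks, equilibrium rates, acclimation
fractions) is taken directly from the printed control/EL values, and the
analysis operators must recover them through instrument-shaped data —
log-spaced flash samples from 0.3 ms to 120 s, 10-min oxygen sampling,
0.5 nm spectral grids, daily OD readings. Quantities the measurements do
not constrain were fixed once at realistic values and documented:

* 77 K band widths σ = 8 nm (PSII) and 12 nm (PSI); only the measured
  ratio matters, and the generator enforces it numerically by a scalar
  root find on the PSII amplitude.
* The −DCMU flash decay is biexponential with fast rate 300 s⁻¹ and fast
  fraction 0.55 (control) / 0.75 (EL), values chosen only to reproduce the
  observed ordering (the fast phase is larger in EL); the first-order
  analysis is applied to +DCMU data only.
* The OJIP shape is a sum of logistic components in log-time (O–J ≈
  0.5 ms, J–I ≈ 20 ms, I–P) pinned to $F_0$, $F_M$ and the 161 ms peak;
  the EL trace omits the J–I component (no resolvable J–I transition) and
  declines after the peak. No numeric induction traces exist to constrain
  steepness or step amplitudes, so these are shape conventions, not data.
* $A_0 = 50$ µmol O₂ (µg Chl)⁻¹ h⁻¹ for photoinhibition fixtures; only
  the equilibrium rates are published, and the relative normalisation
  removes $A_0$ from every fitted quantity. The no-lincomycin repair rate
  is derived from the equilibrium identity,
  $k_{rec} = k_{PI} A_{eq} / (A_0 - A_{eq})$.
* Growth fixtures add a 48 h acclimation fraction (13.3 % / 3.3 %)
  alongside the 96 h fraction so the full published growth table is
  reproduced; OD values between the fate-defining bounds are uniform
  jitter under a mandatory seed.
* Noise is additive i.i.d. Gaussian, applied last, with a mandatory seed;
  the generators never touch the caller's RNG stream.

Passing these fixtures shows that the analysis operators are correct and
stable on data of the right shape, sampling and magnitude. It does not
show robustness to what real instruments add — multiplicative drift,
correlated noise, baseline wander, partially resolved kinetic phases — and
the Monte-Carlo bias checks cover only the stated Gaussian noise level.

# Problem sizes and numerical settings

The shipped defaults are the sizes used throughout the tests and the
reproduction script: 200-point flash decays, 256-point OJIP traces,
6601-point glow curves (0.01 K grid), 7–13-point oxygen time courses,
261-point spectra, 30-culture growth experiments, 50-seed Monte-Carlo
loops. Root finds use bracketed bisection (1e-4 K for the peak condition,
1e-12 for the spectral amplitude); nonlinear fits run at `nlsLM` defaults
with bounded non-negative rates. Degenerate inputs (constant series,
truncated bands, out-of-ramp peaks, non-positive denominators) raise
conditions rather than producing numbers.

# Known limitations

* All kinetics are phenomenological first-order forms; there is no S-state
  cycling, excitonic modelling, multi-trap thermoluminescence or
  second-order recombination.
* The PSII/PSI ratio uses band maxima, not spectral deconvolution; if the
  published ratios were computed at fixed wavelengths instead, values on
  strongly overlapping spectra could differ slightly.
* `fit_damage_repair()` requires an externally supplied $k_{PI}$; the
  joint problem is ill-conditioned on plateau-shaped data.
* Statistical comparison between conditions (the error bars and asterisks
  of the source measurements) is out of scope.
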