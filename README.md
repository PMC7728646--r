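# photoacclim

Kinetic and spectral analysis of extreme-light acclimation in the green
alga *Chlamydomonas reinhardtii*.

Wild-type *C. reinhardtii* cultures can acclimate to photon flux densities
around 3000 µmol m⁻² s⁻¹ — about 1.5× full sunlight ("EL", extreme light).
The acclimated phenotype differs from moderate-light cells in a set of
quantitative signatures: slower S₂Q_A⁻ charge recombination, a lower
F_V/F_M with unchanged damaging rate of photoinhibition, a reduced 77 K
PSII/PSI emission ratio, shifted thermoluminescence bands, and an order of
magnitude less singlet-oxygen production. `photoacclim` implements every
analysis behind those numbers, for researchers in photosynthesis
biophysics who need the same feature extraction and kinetic modelling on
their own instrument data:

* **Thermoluminescence** — Randall–Wilkins first-order glow-curve
  simulation, I(T) = k(T)·n(T) with k(T) = s·exp(−E_a/(k_B·T)) on a linear
  ramp; analytic peak condition β·E_a/(k_B·T_m²) = s·exp(−E_a/(k_B·T_m))
  and its closed-form inverse; band peak/width/integral analysis.
* **Kinetics** — first-order fits v(t) = b + a·e^(−kt) for recombination
  and photoinhibition (k_PI), and the damage–repair model
  A_eq = A₀·k_rec/(k_PI + k_rec) with closed-form dynamics and a
  fixed-k_PI inverse fit.
* **Fluorescence** — flash-decay double normalisation, OJIP induction
  features (F₀, F_M, F_V/F_M, t_Fm, J/I steps), 77 K spectrum
  normalisation and PSII/PSI band-maximum ratio.
* **Assays** — Wellburn methanol pigment equations, SOSG singlet-oxygen
  slope statistic, oxygen-rate normalisations, growth threshold-crossing
  tables.
* **Synthetic data** — generators for every signal above, with `"control"`
  and `"EL"` presets encoding the published phenotype constants, so the
  whole pipeline runs and is tested with no external data.

## Worked example

```r
library(photoacclim)

# EL-preset flash-fluorescence decay (+DCMU), analysed like measured data:
ts  <- gen_flash_decay("EL", with_dcmu = TRUE)
fit <- fit_first_order(double_normalize_decay(ts, F0_pre = 0, Fmax = 1),
                       role = "recombination")
fit
#> <first_order_fit role=recombination k=0.08 s-1, amplitude=1, baseline=0, rss=0, n=200>

induction_features(gen_ojip("EL"))
#> <induction_features F0=0.7, Fm=1, t_Fm=0.161 s, Fv/Fm=0.300>

band_features(gen_glow_curve(21.6))   # EL B band
#> <band_features T_peak=21.60 degC, hwhm=17.13 K, integral=1>

psii_psi_ratio(gen_77k_spectrum("control"))
#> <spectrum_features PSII 687.0 nm (1.508), PSI 712.5 nm (1.005), ratio=1.500>
```

The fitted `k = 0.08 s⁻¹` is the S₂Q_A⁻ recombination rate constant of EL
cells (control: 0.24 s⁻¹); `Fv/Fm = 0.300` is their maximum PSII
photochemical yield; `T_peak = 21.60 °C` the EL thermoluminescence B-band
position; `ratio = 1.500` the control PSII/PSI 77 K emission ratio. A full
side-by-side table of all twenty phenotype constants and their recovered
values comes from `reproduce_phenotypes(seed = 1)`.

A thin command-line wrapper is installed at
`inst/scripts/photoacclim.R` (`simulate`, `analyze`, `reproduce-paper`
verbs) for shell use; the R functions above are the primary interface.

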