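#' @title Synthetic instrument-data generators
#' @description
#' Generators that emulate every instrument signal the analysis stages
#' consume — flash-fluorescence decays, OJIP transients, thermoluminescence
#' glow curves, photoinhibition oxygen time courses, 77 K emission spectra,
#' SOSG traces, pigment absorbance triplets and OD730 growth curves — from
#' the two [fixture_preset()]s, so the full pipeline runs and is tested
#' without any measured data. Each generator is deterministic given its
#' preset, arguments and (when noise is on) seed.
#' @name synthetic_data
NULL

#' Simulate a single-turnover flash fluorescence decay
#'
#' Emulates the fluorescence-yield decay recorded after a saturating
#' single-turnover flash, sampled logarithmically from 0.3 ms (the first
#' reliable instrument point) to `duration`. With DCMU the QA- to QB
#' electron transfer is blocked and the decay is a single exponential with
#' the preset's S2QA- recombination rate constant (amplitude 1, baseline
#' 0). Without DCMU the decay is biexponential: a fast QA- reoxidation
#' phase (rate 300 s-1; amplitude fraction larger in EL than control) on
#' top of the slow recombination phase.
#'
#' @param preset a [fixture_preset()] or its name.
#' @param with_dcmu logical; DCMU present?
#' @param duration record length, s, > 0 (instrument default 120 s).
#' @param n number of logarithmically spaced samples.
#' @param noise a [noise_spec()].
#' @return A [time_series()] of relative fluorescence (kind `"flash"`).
#' @examples
#' ts <- gen_flash_decay("control", with_dcmu = TRUE)
#' fit_first_order(ts)$k  # 0.24 s-1
#' @export
gen_flash_decay <- function(preset, with_dcmu = TRUE, duration = 120,
                            n = 200, noise = noise_spec()) {
  preset <- as_preset(preset)
  if (duration <= 0) stop("duration must be positive")
  tt <- 10^seq(log10(3e-4), log10(duration), length.out = n)
  v <- if (with_dcmu) {
    exp(-preset$k_recomb * tt)
  } else {
    f <- preset$fast_fraction
    f * exp(-300 * tt) + (1 - f) * exp(-preset$k_recomb * tt)
  }
  time_series(tt, apply_noise(v, noise), kind = "flash",
              value_unit = "relative", preset = preset$name,
              seed = if (noise$enabled) noise$seed else NA_integer_)
}

#' Simulate an OJIP fluorescence-induction transient
#'
#' Produces a phenomenological OJIP rise on a logarithmic time base from
#' 5e-5 s to 2 s: fluorescence climbs from F0 = F0_rel * FM through the
#' O-J (about 0.5 ms), J-I (about 20 ms) and I-P phases, peaks exactly at
#' the preset's t_Fm (161 ms), and declines afterwards (clearly for the EL
#' preset, marginally for control). The control trace shows all three
#' phases; the EL trace is dominated by the O-J rise with no resolvable
#' J-I transition; with DCMU the rise is a single sigmoid.
#'
#' @param preset a [fixture_preset()] or its name.
#' @param with_dcmu logical; DCMU present?
#' @param n number of samples.
#' @return A [time_series()] (kind `"ojip"`), FM = 1 a.u.
#' @examples
#' induction_features(gen_ojip("EL"))$FvFm  # 0.30
#' @export
gen_ojip <- function(preset, with_dcmu = FALSE, n = 256) {
  preset <- as_preset(preset)
  tt <- 10^seq(log10(5e-5), log10(2), length.out = n)
  # pin the grid point nearest t_Fm to exactly t_Fm
  i_fm <- which.min(abs(tt - preset$t_Fm))
  tt[i_fm] <- preset$t_Fm
  x <- log10(tt)
  x_fm <- log10(preset$t_Fm)

  sig <- function(x, c, w) stats::plogis((x - c) / w)
  w <- if (with_dcmu) {
    c(oj = 1, ji = 0, ip = 0)
  } else if (preset$name == "EL") {
    c(oj = 0.85, ji = 0, ip = 0.15)
  } else {
    c(oj = 0.5, ji = 0.25, ip = 0.25)
  }
  raw <- function(x) {
    w[["oj"]] * sig(x, -3.3, 0.25) + w[["ji"]] * sig(x, -1.7, 0.25) +
      w[["ip"]] * sig(x, -0.9, 0.18)
  }
  r <- (raw(x) - raw(x[1])) / (raw(x_fm) - raw(x[1]))
  # post-peak quenching: strictly decreasing beyond t_Fm
  d <- if (preset$name == "EL") 0.35 else 0.05
  after <- x > x_fm
  r[after] <- exp(-d * (x[after] - x_fm))
  F0 <- preset$F0_rel  # FM = 1
  time_series(tt, F0 + (1 - F0) * r, kind = "ojip",
              value_unit = "a.u.", preset = preset$name)
}

#' Generate a Randall-Wilkins glow-curve fixture peaking at a set temperature
#'
#' Inverts the first-order peak condition ([s_from_peak()]) to find the
#' pre-exponential factor that places the simulated band at `peak_T_C`,
#' runs [simulate_glow()] on the standard ramp, and optionally adds noise.
#'
#' @param peak_T_C desired band peak, degrees Celsius, inside the ramp.
#' @param Ea activation energy, eV (default 0.501).
#' @param beta heating rate, K/s (default 0.66).
#' @param T0,Tend ramp limits, K (defaults 274, 340).
#' @param dT simulation grid step, K.
#' @param noise a [noise_spec()].
#' @return A `glow_curve` (see [simulate_glow()]).
#' @examples
#' band_features(gen_glow_curve(13.6))$T_peak  # 13.6 degC
#' @export
gen_glow_curve <- function(peak_T_C, Ea = 0.501, beta = 0.66, T0 = 274,
                           Tend = 340, dT = 0.01, noise = noise_spec()) {
  T_m <- peak_T_C + 273.15
  if (!(T_m > T0 && T_m < Tend))
    stop("peak_T_C must lie inside the heating ramp")
  s <- s_from_peak(T_m, Ea = Ea, beta = beta, T0 = T0, Tend = Tend)
  gc <- simulate_glow(arrhenius_model(s = s, Ea = Ea, T0 = T0, beta = beta,
                                      Tend = Tend), dT = dT)
  gc$intensity <- apply_noise(gc$intensity, noise)
  gc
}

#' Simulate a photoinhibition oxygen-evolution time course
#'
#' With lincomycin (repair blocked) activity decays as a pure first order,
#' A(t) = A0 * exp(-k_PI * t). Without lincomycin, damage and repair run
#' concurrently and the closed-form damage-repair time course applies, with
#' the repair rate chosen so the equilibrium activity equals the preset's
#' published plateau (`o2_eq_rate`).
#'
#' @param preset a [fixture_preset()] or its name.
#' @param lincomycin logical; repair inhibitor present?
#' @param duration illumination length, s.
#' @param interval sampling interval, s (instrument default 600 s = 10 min).
#' @param A0 initial activity, umol O2 (ug Chl)-1 h-1, > 0.
#' @return A [time_series()] of activity (kind `"o2"`).
#' @examples
#' ts <- gen_photoinhibition_series("control", lincomycin = TRUE)
#' kpi_from_oxygen(photoinhibition_relative(ts))$k  # 1.47e-3 s-1
#' @export
gen_photoinhibition_series <- function(preset, lincomycin = TRUE,
                                       duration = 3600, interval = 600,
                                       A0 = 50) {
  preset <- as_preset(preset)
  if (A0 <= 0) stop("A0 must be positive")
  stopifnot(interval > 0, duration >= interval)
  tt <- seq(0, duration, by = interval)
  if (lincomycin) {
    out <- time_series(tt, A0 * exp(-preset$k_PI * tt), kind = "o2",
                       value_unit = "umol O2 (ug Chl)-1 h-1",
                       preset = preset$name)
    return(out)
  }
  A_eq <- preset$o2_eq_rate
  if (A_eq >= A0)
    stop("A0 must exceed the preset equilibrium rate for the no-lincomycin regime")
  k_rec <- preset$k_PI * A_eq / (A0 - A_eq)
  m <- damage_repair_model(k_PI = preset$k_PI, k_rec = k_rec, A0 = A0)
  ts <- simulate_damage_repair(m, tt)
  attr(ts, "preset") <- preset$name
  ts
}

# Two-Gaussian 77 K emission model on the standard grid.
two_band_spectrum <- function(a_psii, a_psi = 1, mu_psii = 686, mu_psi = 713,
                              sigma_psii = 8, sigma_psi = 12,
                              wavelength = seq(650, 780, by = 0.5)) {
  inten <- a_psii * exp(-(wavelength - mu_psii)^2 / (2 * sigma_psii^2)) +
    a_psi * exp(-(wavelength - mu_psi)^2 / (2 * sigma_psi^2))
  light_spectrum(wavelength, inten)
}

#' Simulate a 77 K chlorophyll fluorescence emission spectrum
#'
#' Sum of two Gaussian emission bands — PSII near 686 nm (sigma 8 nm) and
#' PSI near 713 nm (sigma 12 nm) — on a 650-780 nm grid with 0.5 nm step.
#' The PSII amplitude is solved numerically (scalar root find) so that the
#' band-maximum ratio measured by [psii_psi_ratio()] equals the preset's
#' published PSII/PSI value; the result is invariant to the subsequent
#' 713 nm normalization.
#'
#' @param preset a [fixture_preset()] or its name.
#' @return A [light_spectrum()].
#' @examples
#' psii_psi_ratio(gen_77k_spectrum("control"))$ratio  # 1.5
#' @export
gen_77k_spectrum <- function(preset) {
  preset <- as_preset(preset)
  target <- preset$psii_psi_ratio
  f <- function(a) psii_psi_ratio(two_band_spectrum(a))$ratio - target
  a <- stats::uniroot(f, c(1e-4, 100), tol = 1e-12)$root
  spec <- two_band_spectrum(a)
  attr(spec, "preset") <- preset$name
  spec
}

#' Simulate an SOSG fluorescence time series
#'
#' Piecewise-linear increase of SOSG fluorescence over consecutive red-light
#' illumination periods at the preset's singlet-oxygen production slope
#' (constant across periods); a dark control has slope 0.
#'
#' @param preset a [fixture_preset()] or its name.
#' @param n_periods number of illumination periods, >= 3.
#' @param period period length, minutes.
#' @param noise a [noise_spec()].
#' @param dark_control logical; dark incubation (no 1O2 production)?
#' @return A [time_series()] with time in minutes (kind `"sosg"`).
#' @export
gen_sosg_series <- function(preset, n_periods = 3, period = 10,
                            noise = noise_spec(), dark_control = FALSE) {
  preset <- as_preset(preset)
  if (n_periods < 3) stop("n_periods must be at least 3")
  tt <- seq(0, n_periods * period, by = period)
  slope <- if (dark_control) 0 else preset$sosg_slope
  time_series(tt, apply_noise(slope * tt, noise), kind = "sosg",
              time_unit = "min", preset = preset$name,
              seed = if (noise$enabled) noise$seed else NA_integer_)
}

#' Simulate OD730 growth curves of cultures transferred to extreme light
#'
#' All cultures start at OD730 = 0.01 and dip during the first 24 h (death
#' of part of the population). A seeded draw marks
#' `round(acclim_fraction_96h * n_cultures)` cultures as acclimating: these
#' resume exponential growth and cross OD 0.05 before 96 h, a subset of
#' them (per `acclim_fraction_48h`) already by 48 h. The remaining cultures
#' stay below 0.05 throughout.
#'
#' @param preset a [fixture_preset()] or its name; the control preset
#'   carries the isolated-subpopulation acclimation fractions, the EL
#'   preset the single-cell-inoculum fractions.
#' @param n_cultures number of replicate cultures, >= 1.
#' @param seed integer seed for the culture-fate draw and jitter.
#' @return List of OD730 [time_series()] (time in hours, samples at
#'   0/24/48/96 h).
#' @examples
#' curves <- gen_growth_curves("control", n_cultures = 30, seed = 42)
#' acclimation_table(curves)$pct[["pct_96h"]]  # 80
#' @export
gen_growth_curves <- function(preset, n_cultures = 30, seed = 1) {
  preset <- as_preset(preset)
  if (n_cultures < 1) stop("n_cultures must be at least 1")
  n_96 <- round(preset$acclim_fraction_96h * n_cultures)
  n_48 <- min(round(preset$acclim_fraction_48h * n_cultures), n_96)
  with_local_seed(seed, {
    fate <- rep("none", n_cultures)
    acc <- if (n_96 > 0) sample.int(n_cultures, n_96) else integer(0)
    fate[acc] <- "by96"
    if (n_48 > 0) fate[sample(acc, n_48)] <- "by48"
    lapply(seq_len(n_cultures), function(i) {
      dip <- stats::runif(1, 0.005, 0.009)  # all cultures lose cells first
      od <- switch(fate[i],
        by48 = c(0.01, dip, stats::runif(1, 0.055, 0.09),
                 stats::runif(1, 0.12, 0.22)),
        by96 = c(0.01, dip, stats::runif(1, 0.015, 0.045),
                 stats::runif(1, 0.06, 0.16)),
        none = c(0.01, dip, stats::runif(1, 0.005, 0.012),
                 stats::runif(1, 0.012, 0.045)))
      time_series(c(0, 24, 48, 96), od, kind = "od", time_unit = "h",
                  value_unit = "OD730", preset = preset$name,
                  seed = seed)
    })
  })
}

#' Absorbance triplet that yields prescribed pigment concentrations
#'
#' Inverse of the Wellburn methanol equations: solves the 3x3 linear system
#' for (A470, A652.4, A665.2) such that [pigments_wellburn()] returns the
#' requested chlorophyll a, chlorophyll b and carotenoid concentrations.
#' Used for roundtrip testing of the pigment equations.
#'
#' @param chl_a,chl_b,car target concentrations, ug/ml, >= 0.
#' @return Named numeric vector `A470`, `A652_4`, `A665_2`.
#' @export
gen_pigment_absorbances <- function(chl_a, chl_b, car) {
  stopifnot(chl_a >= 0, chl_b >= 0, car >= 0)
  co <- WELLBURN_METHANOL
  # rows: chl_a, chl_b, car equations; columns: A470, A652_4, A665_2
  M <- rbind(
    c(0, co$chl_a[["A652_4"]], co$chl_a[["A665_2"]]),
    c(0, co$chl_b[["A652_4"]], co$chl_b[["A665_2"]]),
    c(co$car[["A470"]] / co$car[["denom"]], 0, 0))
  # carotenoid equation also involves chl_a and chl_b; fold them into rhs
  rhs <- c(chl_a, chl_b,
           car - (co$car[["chl_a"]] * chl_a + co$car[["chl_b"]] * chl_b) /
             co$car[["denom"]])
  sol <- unname(solve(M, rhs))
  c(A470 = sol[1], A652_4 = sol[2], A665_2 = sol[3])
}
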