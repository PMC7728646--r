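#' @title Fluorescence feature extraction
#' @description
#' Feature extractors for the three chlorophyll-a fluorescence measurements:
#' single-turnover flash decays (QA- reoxidation / recombination), OJIP
#' induction transients (F0, FM, FV/FM, J and I step levels), and 77 K
#' emission spectra (PSII/PSI stoichiometry).
#' @name fluorescence
NULL

#' Double-normalize a flash-fluorescence decay
#'
#' Normalizes a raw decay first to the zero-fluorescence level measured
#' before the flash (`F0_pre`) and then to the maximum fluorescence after
#' the single-turnover flash (`Fmax`):
#' v'(t) = (v(t) - F0_pre) / (Fmax - F0_pre).
#'
#' @param raw a [time_series()] of raw fluorescence.
#' @param F0_pre pre-flash fluorescence level, a.u.
#' @param Fmax post-flash maximum fluorescence, a.u.; must exceed `F0_pre`.
#' @return A [time_series()] with the normalized values.
#' @export
double_normalize_decay <- function(raw, F0_pre, Fmax) {
  if (!(Fmax > F0_pre)) stop("Fmax must exceed F0_pre")
  time_series(raw$time, (raw$value - F0_pre) / (Fmax - F0_pre),
              kind = attr(raw, "kind") %||% "flash",
              time_unit = attr(raw, "time_unit") %||% "s",
              value_unit = "relative",
              preset = attr(raw, "preset") %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract induction (OJIP) features from a fluorescence transient
#'
#' F0 is the earliest recorded sample (the minimal fluorescence of
#' dark-adapted cells), FM the global maximum, t_Fm its time, and
#' FV/FM = (FM - F0)/FM the maximum quantum yield of PSII photochemistry.
#' The J (2 ms) and I (30 ms) step levels are read by linear interpolation
#' on a logarithmic time axis. A transient that is still rising at the last
#' sample is flagged with a `"truncated induction"` warning.
#'
#' @param trace a [time_series()] covering at least 1e-4 s to 1 s.
#' @return A list of class `induction_features`: `F0`, `Fm`, `t_Fm` (s),
#'   `FvFm`, `step_values` (named vector with `J` and `I`).
#' @examples
#' feats <- induction_features(gen_ojip("control"))
#' feats$FvFm
#' @export
induction_features <- function(trace) {
  tt <- trace$time
  vv <- trace$value
  if (min(tt) > 1e-4 || max(tt) < 1)
    stop("trace must cover at least 1e-4 s to 1 s")
  F0 <- vv[1]
  if (F0 <= 0) stop("non-positive F0")
  i_max <- which.max(vv)
  Fm <- vv[i_max]
  t_Fm <- tt[i_max]
  if (i_max == length(vv))
    warning("truncated induction: trace is still rising at the last sample")
  steps <- stats::approx(log10(tt), vv, xout = log10(c(2e-3, 3e-2)))$y
  names(steps) <- c("J", "I")
  structure(list(F0 = F0, Fm = Fm, t_Fm = t_Fm,
                 FvFm = (Fm - F0) / Fm, step_values = steps),
            class = "induction_features")
}

#' @export
print.induction_features <- function(x, ...) {
  cat(sprintf("<induction_features F0=%.4g, Fm=%.4g, t_Fm=%.4g s, Fv/Fm=%.3f>\n",
              x$F0, x$Fm, x$t_Fm, x$FvFm))
  invisible(x)
}

#' Normalize a 77 K emission spectrum to its 713 nm value
#'
#' Divides all intensities by the (linearly interpolated) intensity at
#' 713 nm, the PSI emission reference wavelength, so spectra from samples
#' with different chlorophyll contents become comparable.
#'
#' @param spec a [light_spectrum()] whose range includes 713 nm.
#' @return A [light_spectrum()] with value 1 at 713 nm.
#' @export
normalize_spectrum_713 <- function(spec) {
  wl <- spec$wavelength
  if (min(wl) > 713 || max(wl) < 713)
    stop("713 nm must lie inside the wavelength range")
  ref <- stats::approx(wl, spec$intensity, xout = 713)$y
  if (!is.finite(ref) || ref <= 0)
    stop("intensity at 713 nm must be positive")
  light_spectrum(wl, spec$intensity / ref,
                 preset = attr(spec, "preset") %||% NA_character_)
}

#' PSII/PSI emission ratio of a 77 K spectrum
#'
#' The PSII value is the maximum intensity in the 675-700 nm band
#' (bracketing the classic 685-695 nm PSII emission), the PSI value the
#' maximum in 705-725 nm (bracketing the 713-720 nm PSI emission); the
#' ratio is their quotient, and is invariant to any positive rescaling of
#' the spectrum, in particular to 713 nm normalization.
#'
#' @param spec a [light_spectrum()] spanning both bands.
#' @param psii_band,psi_band numeric length-2 search windows, nm.
#' @return A list of class `spectrum_features`: `psii_peak_nm`,
#'   `psii_value`, `psi_peak_nm`, `psi_value`, `ratio`.
#' @examples
#' psii_psi_ratio(gen_77k_spectrum("control"))$ratio
#' @export
psii_psi_ratio <- function(spec, psii_band = c(675, 700),
                           psi_band = c(705, 725)) {
  wl <- spec$wavelength
  ii <- spec$intensity
  in_psii <- wl >= psii_band[1] & wl <= psii_band[2]
  in_psi <- wl >= psi_band[1] & wl <= psi_band[2]
  if (!any(in_psii) || !any(in_psi))
    stop("spectrum must span both the PSII and PSI search bands")
  i2 <- which(in_psii)[which.max(ii[in_psii])]
  i1 <- which(in_psi)[which.max(ii[in_psi])]
  structure(list(psii_peak_nm = wl[i2], psii_value = ii[i2],
                 psi_peak_nm = wl[i1], psi_value = ii[i1],
                 ratio = ii[i2] / ii[i1]),
            class = "spectrum_features")
}

#' @export
print.spectrum_features <- function(x, ...) {
  cat(sprintf("<spectrum_features PSII %.1f nm (%.4g), PSI %.1f nm (%.4g), ratio=%.3f>\n",
              x$psii_peak_nm, x$psii_value, x$psi_peak_nm, x$psi_value,
              x$ratio))
  invisible(x)
}
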