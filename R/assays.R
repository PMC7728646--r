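#' @title Pigment, singlet-oxygen, oxygen-rate and growth statistics
#' @name assays
NULL

# Wellburn (1994) coefficients for pigments in methanol, read on a
# spectrophotometer with 1-4 nm resolution; concentrations in ug/ml.
WELLBURN_METHANOL <- list(
  chl_a = c(A665_2 = 16.72, A652_4 = -9.16),
  chl_b = c(A652_4 = 34.09, A665_2 = -15.28),
  car = c(A470 = 1000, chl_a = -1.63, chl_b = -104.96, denom = 221)
)

#' Pigment concentrations from a methanol-extract absorbance triplet
#'
#' Applies the standard methanol equations for chlorophyll a, chlorophyll b
#' and total carotenoids from absorbances at 665.2, 652.4 and 470 nm:
#' chl_a = 16.72 A665.2 - 9.16 A652.4;
#' chl_b = 34.09 A652.4 - 15.28 A665.2;
#' carotenoids = (1000 A470 - 1.63 chl_a - 104.96 chl_b) / 221.
#' Results are multiplied by the dilution factor; slightly negative values
#' (possible with noisy absorbances) are clipped to 0 with a warning.
#'
#' @param A470,A652_4,A665_2 absorbances (>= 0).
#' @param dilution_factor multiplicative dilution correction, > 0.
#' @param coefficients coefficient set; the methanol 1-4 nm set is the
#'   default and the only one shipped.
#' @return A list of class `pigment_result`: `chl_a`, `chl_b`, `chl_total`,
#'   `carotenoids` (ug/ml), `chl_ab_ratio`, `car_chl_ratio`.
#' @examples
#' pigments_wellburn(A470 = 0.2, A652_4 = 0.05, A665_2 = 0.1)$chl_a  # 1.214
#' @export
pigments_wellburn <- function(A470, A652_4, A665_2, dilution_factor = 1,
                              coefficients = WELLBURN_METHANOL) {
  stopifnot(dilution_factor > 0)
  ca <- coefficients$chl_a[["A665_2"]] * A665_2 +
    coefficients$chl_a[["A652_4"]] * A652_4
  cb <- coefficients$chl_b[["A652_4"]] * A652_4 +
    coefficients$chl_b[["A665_2"]] * A665_2
  cc <- (coefficients$car[["A470"]] * A470 +
           coefficients$car[["chl_a"]] * ca +
           coefficients$car[["chl_b"]] * cb) / coefficients$car[["denom"]]
  conc <- c(chl_a = ca, chl_b = cb, carotenoids = cc) * dilution_factor
  if (any(conc < 0)) {
    warning("negative pigment concentration(s) clipped to 0")
    conc <- pmax(conc, 0)
  }
  chl_total <- conc[["chl_a"]] + conc[["chl_b"]]
  structure(list(chl_a = conc[["chl_a"]], chl_b = conc[["chl_b"]],
                 chl_total = chl_total, carotenoids = conc[["carotenoids"]],
                 chl_ab_ratio = if (conc[["chl_b"]] > 0)
                   conc[["chl_a"]] / conc[["chl_b"]] else NA_real_,
                 car_chl_ratio = if (chl_total > 0)
                   conc[["carotenoids"]] / chl_total else NA_real_),
            class = "pigment_result")
}

#' @export
print.pigment_result <- function(x, ...) {
  cat(sprintf("<pigment_result chl_a=%.3f, chl_b=%.3f, car=%.3f ug/ml, car/chl=%.3f>\n",
              x$chl_a, x$chl_b, x$carotenoids, x$car_chl_ratio))
  invisible(x)
}

#' Relative singlet-oxygen production rate from an SOSG trace
#'
#' SOSG (Singlet Oxygen Sensor Green) fluorescence increases upon reaction
#' with singlet oxygen; its average rate of increase over consecutive
#' illumination periods is a relative 1O2 production rate. Each period's
#' slope is the endpoint difference quotient (the signal is sampled once
#' per period boundary); the statistic is the mean of the per-period slopes.
#'
#' @param series a [time_series()] with time in minutes covering all
#'   periods from 0.
#' @param n_periods number of consecutive illumination periods (default 3).
#' @param period period length in minutes (default 10).
#' @return Mean slope, a.u. per minute, with per-period slopes attached as
#'   attribute `period_slopes`.
#' @export
sosg_rate <- function(series, n_periods = 3, period = 10) {
  bounds <- seq(0, n_periods * period, by = period)
  vals <- stats::approx(series$time, series$value, xout = bounds)$y
  if (anyNA(vals))
    stop("series does not cover all period endpoints")
  slopes <- diff(vals) / period
  structure(mean(slopes), period_slopes = slopes)
}

#' Normalize an oxygen-evolution rate to chlorophyll and to cell density
#'
#' @param raw_rate measured rate, umol O2 ml-1 h-1.
#' @param chl chlorophyll concentration, ug/ml, > 0.
#' @param od optical density at 730 nm, > 0.
#' @return List with `rate_per_chl` (umol O2 (ug Chl)-1 h-1) and
#'   `rate_per_od`.
#' @export
oxygen_rate_normalize <- function(raw_rate, chl, od) {
  if (chl <= 0 || od <= 0) stop("chl and od must be positive")
  list(rate_per_chl = raw_rate / chl, rate_per_od = raw_rate / od)
}

#' Normalize a photoinhibition time course to its initial value
#'
#' Measured oxygen-evolution rates are first divided by the chlorophyll
#' concentration and then by the control (t = 0) value of the sample, so
#' the output starts at exactly 1 and is dimensionless.
#'
#' @param rates a [time_series()] of oxygen-evolution rates.
#' @param chl chlorophyll concentration, ug/ml, > 0.
#' @return A [time_series()] of relative activity with first value 1.
#' @export
photoinhibition_relative <- function(rates, chl = 1) {
  stopifnot(chl > 0)
  per_chl <- rates$value / chl
  if (per_chl[1] <= 0) stop("initial rate must be positive")
  time_series(rates$time, per_chl / per_chl[1], kind = "o2_relative",
              value_unit = "relative",
              preset = attr(rates, "preset") %||% NA_character_)
}

#' Threshold-crossing statistics of extreme-light growth curves
#'
#' A culture counts as acclimated by a horizon if its OD730 reached the
#' threshold at any sampled time up to that horizon (cumulative
#' interpretation, matching daily OD readings).
#'
#' @param curves list of OD730 [time_series()] objects, time in hours,
#'   sampled at (at least) 0/24/48/96 h.
#' @param threshold OD730 threshold, default 0.05.
#' @param horizons horizons in hours.
#' @return A list of class `acclimation_table`: `n_cultures`, `threshold`,
#'   and `pct` (named percentage per horizon).
#' @examples
#' curves <- gen_growth_curves("control", n_cultures = 30, seed = 1)
#' acclimation_table(curves)$pct
#' @export
acclimation_table <- function(curves, threshold = 0.05,
                              horizons = c(24, 48, 96)) {
  if (length(curves) == 0) stop("empty list of growth curves")
  crossed <- vapply(curves, function(ts) {
    vapply(horizons, function(h) any(ts$value[ts$time <= h] >= threshold),
           logical(1))
  }, logical(length(horizons)))
  pct <- rowMeans(crossed) * 100
  names(pct) <- paste0("pct_", horizons, "h")
  structure(list(n_cultures = length(curves), threshold = threshold,
                 pct = pct),
            class = "acclimation_table")
}

#' @export
print.acclimation_table <- function(x, ...) {
  cat(sprintf("<acclimation_table n=%d, threshold OD730=%.2f>\n",
              x$n_cultures, x$threshold))
  print(round(x$pct, 1))
  invisible(x)
}
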