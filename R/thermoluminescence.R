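#' @title Randall-Wilkins first-order thermoluminescence
#' @description
#' Thermoluminescence of photosystem II arises from charge recombination of
#' trapped radical pairs (S2,3QA- for the Q band, S2,3QB- for the B band)
#' released thermally during a linear temperature ramp. In the
#' Randall-Wilkins picture the trapped population n(t) decays as a
#' first-order reaction whose rate constant follows the Arrhenius law
#' k(T) = s * exp(-Ea / (kB * T)), with T = T0 + beta * t, and the glow
#' intensity is the reaction rate itself, I = k(T) * n(T).
#' @name thermoluminescence
NULL

#' Boltzmann constant in eV/K
#' @export
K_BOLTZMANN_EV <- 8.617333e-5

#' Arrhenius model of a first-order glow band
#'
#' Parameter container for the Randall-Wilkins simulation: pre-exponential
#' factor `s` (s-1), activation energy `Ea` (eV, default 0.501 eV = 501 meV),
#' initial trapped-charge population `n0` (relative units), ramp start `T0`
#' (K), heating rate `beta` (K/s) and ramp end `Tend` (K). The defaults are
#' the instrument ramp used throughout: heating from 274 K to 340 K at
#' 0.66 K/s.
#'
#' @param s pre-exponential (frequency) factor, s-1, > 0.
#' @param Ea activation energy, eV, > 0.
#' @param n0 initial trapped-charge population (dimensionless).
#' @param T0 ramp start temperature, K.
#' @param beta heating rate, K/s, > 0.
#' @param Tend ramp end temperature, K, > T0.
#' @return A list of class `arrhenius_model`.
#' @examples
#' m <- arrhenius_model(s = 1.7e7)
#' arrhenius_rate(293.15, m)
#' @export
arrhenius_model <- function(s, Ea = 0.501, n0 = 1, T0 = 274, beta = 0.66,
                            Tend = 340) {
  stopifnot(s > 0, Ea > 0, n0 > 0, beta > 0, T0 < Tend, T0 > 0)
  structure(list(s = s, Ea = Ea, n0 = n0, T0 = T0, beta = beta, Tend = Tend),
            class = "arrhenius_model")
}

#' Arrhenius rate constant at a given temperature
#'
#' Evaluates k(T) = s * exp(-Ea / (kB * T)) with kB in eV/K.
#'
#' @param temp_K temperature(s) in kelvin, > 0.
#' @param model an [arrhenius_model()].
#' @return Rate constant(s), s-1.
#' @export
arrhenius_rate <- function(temp_K, model) {
  stopifnot(all(temp_K > 0))
  model$s * exp(-model$Ea / (K_BOLTZMANN_EV * temp_K))
}

#' Simulate a first-order glow curve over the heating ramp
#'
#' Integrates the first-order depletion of the trapped population along the
#' ramp, n(T) = n0 * exp(-(1/beta) * int_{T0}^{T} k(T') dT') (trapezoidal
#' quadrature on a uniform grid), and returns the glow intensity
#' I(T) = k(T) * n(T) in a.u. per second. Because the intensity is the
#' depletion rate, its integral over time equals the charge released,
#' n0 - n(Tend).
#'
#' @param model an [arrhenius_model()].
#' @param dT temperature grid step, K; must be positive and <= 0.1 K so the
#'   quadrature error stays far below the 0.1 degC reporting precision.
#' @return A data frame of class `glow_curve` with columns `temperature_K`,
#'   `intensity` and `n_remaining`, plus attributes `beta`, `T0` and the
#'   generating model.
#' @examples
#' gc <- simulate_glow(arrhenius_model(s = 1.7e7))
#' band_features(gc)$T_peak
#' @export
simulate_glow <- function(model, dT = 0.01) {
  stopifnot(inherits(model, "arrhenius_model"))
  if (!(dT > 0 && dT <= 0.1))
    stop("dT must be positive and at most 0.1 K")
  temps <- seq(model$T0, model$Tend, by = dT)
  k <- arrhenius_rate(temps, model)
  # cumulative trapezoid of k over T
  cumint <- c(0, cumsum((k[-1] + k[-length(k)]) / 2 * diff(temps)))
  n <- model$n0 * exp(-cumint / model$beta)
  structure(data.frame(temperature_K = temps, intensity = k * n,
                       n_remaining = n),
            class = c("glow_curve", "data.frame"),
            beta = model$beta, T0 = model$T0, model = model)
}

#' @export
print.glow_curve <- function(x, ...) {
  cat(sprintf("<glow_curve n=%d, %g-%g K, beta=%g K/s>\n",
              nrow(x), min(x$temperature_K), max(x$temperature_K),
              attr(x, "beta")))
  invisible(x)
}

#' Solve the first-order glow-peak condition for the peak temperature
#'
#' At the glow maximum dI/dT = 0, which for first-order kinetics gives the
#' classical peak condition
#' beta * Ea / (kB * Tm^2) = s * exp(-Ea / (kB * Tm)).
#' The root is bracketed on (T0, Tend) and located by bisection
#' (`stats::uniroot`) to 1e-4 K.
#'
#' @param model an [arrhenius_model()].
#' @return Peak temperature Tm in kelvin.
#' @export
solve_peak_condition <- function(model) {
  f <- function(Tm) {
    model$beta * model$Ea / (K_BOLTZMANN_EV * Tm^2) -
      model$s * exp(-model$Ea / (K_BOLTZMANN_EV * Tm))
  }
  lo <- model$T0 + 1e-9
  hi <- model$Tend - 1e-9
  if (f(lo) * f(hi) > 0)
    stop("peak outside ramp: the peak condition has no root in (T0, Tend)")
  stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
}

#' Pre-exponential factor that places the glow peak at a given temperature
#'
#' Closed-form inversion of the first-order peak condition:
#' s = beta * Ea / (kB * Tm^2) * exp(Ea / (kB * Tm)). Used by the fixture
#' generator so a simulated band peaks at a prescribed temperature.
#'
#' @param T_m desired peak temperature, K; must lie inside (T0, Tend).
#' @param Ea activation energy, eV.
#' @param beta heating rate, K/s.
#' @param T0,Tend ramp limits, K (validation only).
#' @return Pre-exponential factor s, s-1.
#' @export
s_from_peak <- function(T_m, Ea = 0.501, beta = 0.66, T0 = 274, Tend = 340) {
  if (!(T_m > T0 && T_m < Tend))
    stop("T_m must lie strictly inside the heating ramp (T0, Tend)")
  beta * Ea / (K_BOLTZMANN_EV * T_m^2) * exp(Ea / (K_BOLTZMANN_EV * T_m))
}

#' Extract peak and width features from a glow curve
#'
#' The peak temperature is the parabolic interpolation through the three
#' grid points around the discrete maximum (so its resolution is finer than
#' the grid); the full width at half maximum comes from linear interpolation
#' of the half-maximum crossings on each flank; the integral is the
#' trapezoidal time-integral of the intensity (a.u.).
#'
#' @param curve a `glow_curve` (or any data frame with `temperature_K` and
#'   `intensity` columns).
#' @return A list of class `band_features`: `T_peak` (degC), `I_peak`,
#'   `fwhm` (K), `hwhm` (K, = fwhm/2), `integral`.
#' @export
band_features <- function(curve) {
  temps <- curve$temperature_K
  ints <- curve$intensity
  i <- which.max(ints)
  if (i == 1L || i == length(ints))
    stop("truncated band: the glow maximum lies at a ramp endpoint")
  # parabola through the top three points
  x <- temps[(i - 1):(i + 1)]
  y <- ints[(i - 1):(i + 1)]
  denom <- (y[1] - 2 * y[2] + y[3])
  if (denom == 0) {
    T_peak_K <- x[2]
    I_peak <- y[2]
  } else {
    h <- x[2] - x[1]
    delta <- 0.5 * (y[1] - y[3]) / denom
    T_peak_K <- x[2] + delta * h
    I_peak <- y[2] - 0.25 * (y[1] - y[3]) * delta
  }
  half <- I_peak / 2
  left <- cross_at(temps[1:i], ints[1:i], half, rising = TRUE)
  right <- cross_at(temps[i:length(temps)], ints[i:length(ints)], half,
                    rising = FALSE)
  fwhm <- if (is.na(left) || is.na(right)) NA_real_ else right - left
  beta <- attr(curve, "beta")
  dt <- diff(temps) / (if (is.null(beta)) 1 else beta)
  integral <- sum((ints[-1] + ints[-length(ints)]) / 2 * dt)
  structure(list(T_peak = T_peak_K - 273.15, I_peak = I_peak,
                 fwhm = fwhm, hwhm = fwhm / 2, integral = integral),
            class = "band_features")
}

#' @export
print.band_features <- function(x, ...) {
  cat(sprintf("<band_features T_peak=%.2f degC, hwhm=%.2f K, integral=%.4g>\n",
              x$T_peak, x$hwhm, x$integral))
  invisible(x)
}

# First crossing of `level` on a monotone flank, by linear interpolation.
cross_at <- function(xs, ys, level, rising) {
  if (rising) {
    idx <- which(ys[-length(ys)] < level & ys[-1] >= level)
    if (length(idx) == 0) return(NA_real_)
    j <- idx[1]
  } else {
    idx <- which(ys[-length(ys)] >= level & ys[-1] < level)
    if (length(idx) == 0) return(NA_real_)
    j <- idx[1]
  }
  frac <- (level - ys[j]) / (ys[j + 1] - ys[j])
  xs[j] + frac * (xs[j + 1] - xs[j])
}
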