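#' @title First-order kinetics and the damage-repair equilibrium
#' @description
#' Two first-order rate constants characterise the photosystem II (PSII)
#' phenotypes handled here: the S2QA- charge-recombination rate constant
#' fitted to +DCMU flash-fluorescence decays, and the photoinhibition rate
#' constant k_PI fitted to the loss of oxygen evolution under illumination
#' with the repair inhibitor lincomycin. Without lincomycin, damage and
#' repair run concurrently and PSII activity settles at the equilibrium
#' A_eq = A0 * k_rec / (k_PI + k_rec) of the two-state damage-repair model.
#' @name kinetics
NULL

#' Fit a single first-order (exponential) decay to a time series
#'
#' Least-squares fit of v(t) = baseline + amplitude * exp(-k * t) by
#' Levenberg-Marquardt nonlinear least squares (`minpack.lm::nlsLM`). With
#' `fit_baseline = FALSE` the baseline is fixed at 0 (full decay), the form
#' used for both recombination and photoinhibition kinetics. The automatic
#' initial rate is ln 2 divided by the time at which the signal has decayed
#' halfway from its first to its last value; on non-convergence the fit is
#' restarted at 10x and 0.1x that initial rate.
#'
#' @param series a [time_series()] (or data frame with `time` and `value`).
#' @param fit_baseline logical; float the baseline (default `FALSE`).
#' @param init_k `"auto"` or a positive numeric starting value for k.
#' @param role label stored with the fit: `"recombination"`, `"k_PI"` or
#'   `"generic"`.
#' @return A list of class `first_order_fit` with elements `k` (s-1),
#'   `amplitude`, `baseline`, `role`, `rss`, `n_points`, `fitted`.
#' @examples
#' ts <- time_series(seq(0, 20, 0.5), exp(-0.24 * seq(0, 20, 0.5)))
#' fit_first_order(ts)$k
#' @export
fit_first_order <- function(series, fit_baseline = FALSE, init_k = "auto",
                            role = c("generic", "recombination", "k_PI")) {
  role <- match.arg(role)
  tt <- series$time
  vv <- series$value
  if (length(tt) < 3L) stop("at least 3 points are required")
  if (anyNA(vv) || any(!is.finite(vv))) stop("values must be finite")
  if (stats::sd(vv) == 0)
    stop(errorCondition("no decay: the series is constant",
                        class = c("photoacclim_no_decay", "error", "condition")))

  k0 <- if (identical(init_k, "auto")) auto_init_k(tt, vv) else {
    stopifnot(is.numeric(init_k), init_k > 0)
    init_k
  }
  b0 <- if (fit_baseline) min(vv) else 0
  a0 <- max(vv[1] - b0, 1e-12)

  dat <- data.frame(t = tt, v = vv)
  do_fit <- function(kstart) {
    if (fit_baseline) {
      minpack.lm::nlsLM(v ~ b + a * exp(-k * t), data = dat,
                        start = list(b = b0, a = a0, k = kstart),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(v ~ a * exp(-k * t), data = dat,
                        start = list(a = a0, k = kstart),
                        lower = c(a = 0, k = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  fit <- NULL
  last_err <- NULL
  for (kstart in c(k0, 10 * k0, 0.1 * k0)) {
    fit <- tryCatch(do_fit(kstart), error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop(errorCondition(
      paste0("first-order fit did not converge: ", conditionMessage(last_err)),
      class = c("photoacclim_fit_error", "error", "condition"),
      init_k = k0))
  cf <- stats::coef(fit)
  structure(list(k = unname(cf[["k"]]),
                 amplitude = unname(cf[["a"]]),
                 baseline = if (fit_baseline) unname(cf[["b"]]) else 0,
                 role = role,
                 rss = sum(stats::residuals(fit)^2),
                 n_points = length(tt),
                 fitted = stats::fitted(fit)),
            class = "first_order_fit")
}

# ln2 / time of half-amplitude decay, clamped to the observed time window.
auto_init_k <- function(tt, vv) {
  half <- (vv[1] + vv[length(vv)]) / 2
  below <- which(vv <= half)
  t_half <- if (length(below) == 0) tt[length(tt)] else tt[below[1]]
  if (t_half <= 0) t_half <- tt[length(tt)] / 10
  log(2) / max(t_half, .Machine$double.eps)
}

#' @export
print.first_order_fit <- function(x, ...) {
  cat(sprintf("<first_order_fit role=%s k=%.6g s-1, amplitude=%.4g, baseline=%.4g, rss=%.3g, n=%d>\n",
              x$role, x$k, x$amplitude, x$baseline, x$rss, x$n_points))
  invisible(x)
}

#' Photoinhibition rate constant from a relative oxygen-evolution series
#'
#' Fits the normalised loss of light-saturated oxygen evolution (first
#' point = 1, see [photoinhibition_relative()]) to a pure first-order decay
#' with the baseline fixed at 0 and labels the rate constant `"k_PI"`.
#'
#' @param rates a [time_series()] of relative PSII activity, first value 1.
#' @return A `first_order_fit` with role `"k_PI"`.
#' @export
kpi_from_oxygen <- function(rates) {
  if (abs(rates$value[1] - 1) > 1e-6)
    stop("rates must be normalized so the first point equals 1 (see photoinhibition_relative)")
  fit_first_order(rates, fit_baseline = FALSE, role = "k_PI")
}

#' Two-state damage-repair model of PSII activity
#'
#' Under illumination, active PSII (activity A) is damaged at rate k_PI and
#' repaired at rate k_rec: dA/dt = -k_PI * A + k_rec * (A0 - A). The
#' activity relaxes exponentially with rate k_PI + k_rec to the equilibrium
#' A_eq = A0 * k_rec / (k_PI + k_rec).
#'
#' @param k_PI damaging rate constant, s-1, >= 0.
#' @param k_rec repair rate constant, s-1, >= 0.
#' @param A0 initial (fully active) PSII activity, activity units.
#' @return A list of class `damage_repair_model` with the derived `A_eq`.
#' @examples
#' m <- damage_repair_model(k_PI = 1.47e-3, k_rec = 1.1e-3, A0 = 50)
#' m$A_eq
#' @export
damage_repair_model <- function(k_PI, k_rec, A0) {
  if (k_PI < 0 || k_rec < 0) stop("rates must be nonnegative")
  stopifnot(A0 > 0)
  A_eq <- if (k_PI + k_rec == 0) A0 else A0 * k_rec / (k_PI + k_rec)
  structure(list(k_PI = k_PI, k_rec = k_rec, A0 = A0, A_eq = A_eq),
            class = "damage_repair_model")
}

#' @export
print.damage_repair_model <- function(x, ...) {
  cat(sprintf("<damage_repair_model k_PI=%.4g, k_rec=%.4g s-1, A0=%.4g, A_eq=%.4g>\n",
              x$k_PI, x$k_rec, x$A0, x$A_eq))
  invisible(x)
}

#' Closed-form time course of the damage-repair model
#'
#' A(t) = A_eq + (A0 - A_eq) * exp(-(k_PI + k_rec) * t). With k_rec = 0 this
#' reduces to the pure first-order photoinhibition decay A0 * exp(-k_PI t).
#'
#' @param model a [damage_repair_model()].
#' @param times nonnegative, increasing sampling times, s.
#' @return A [time_series()] of activity.
#' @export
simulate_damage_repair <- function(model, times) {
  stopifnot(inherits(model, "damage_repair_model"))
  if (any(times < 0)) stop("times must be nonnegative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  a <- model$A_eq + (model$A0 - model$A_eq) *
    exp(-(model$k_PI + model$k_rec) * times)
  time_series(times, a, kind = "o2",
              value_unit = "umol O2 (ug Chl)-1 h-1")
}

#' Fit the damage-repair model with the damaging rate held fixed
#'
#' Inverse problem for a no-lincomycin photoinhibition time course: k_PI is
#' taken from the matching +lincomycin experiment and (A0, k_rec) are
#' estimated by Levenberg-Marquardt least squares on the closed form.
#'
#' @param series a [time_series()] of absolute PSII activity, >= 4 points.
#' @param k_PI_fixed damaging rate constant, s-1, > 0.
#' @return A [damage_repair_model()] with fitted `A0`, `k_rec` and the
#'   implied `A_eq`; the residual sum of squares is attached as `rss`.
#' @export
fit_damage_repair <- function(series, k_PI_fixed) {
  stopifnot(k_PI_fixed > 0)
  if (nrow(series) < 4L) stop("at least 4 points are required")
  dat <- data.frame(t = series$time, v = series$value)
  kpi <- k_PI_fixed
  a0_start <- max(dat$v[1], 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ (A0 * krec / (kpi + krec)) +
        (A0 - A0 * krec / (kpi + krec)) * exp(-(kpi + krec) * t),
      data = dat,
      start = list(A0 = a0_start, krec = kpi),
      lower = c(A0 = 0, krec = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(errorCondition(
        paste0("damage-repair fit did not converge: ", conditionMessage(e)),
        class = c("photoacclim_fit_error", "error", "condition"))))
  cf <- stats::coef(fit)
  out <- damage_repair_model(k_PI = kpi, k_rec = unname(cf[["krec"]]),
                             A0 = unname(cf[["A0"]]))
  attr(out, "rss") <- sum(stats::residuals(fit)^2)
  out
}
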