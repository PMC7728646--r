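#' Uniform time-series container
#'
#' A `time_series` is a plain two-column data frame (`time`, `value`) with
#' attributes describing what was sampled. It is the common currency of the
#' package: flash-fluorescence decays, SOSG fluorescence traces, oxygen
#' evolution time courses and OD730 growth curves are all `time_series`
#' objects that differ only in their `kind` and units.
#'
#' @param time numeric vector of sampling times, strictly increasing after
#'   sorting; duplicates are an error.
#' @param value numeric vector of the recorded signal, same length as `time`.
#' @param kind short label for the signal type, e.g. `"flash"`, `"ojip"`,
#'   `"o2"`, `"sosg"`, `"od"`.
#' @param time_unit,value_unit unit strings carried as attributes (`"s"`,
#'   `"h"`, `"a.u."`, ...).
#' @param preset optional name of the generating fixture preset.
#' @param seed optional integer seed used when noise was added.
#'
#' @return A data frame of class `time_series`.
#' @export
time_series <- function(time, value, kind = "generic",
                        time_unit = "s", value_unit = "a.u.",
                        preset = NA_character_, seed = NA_integer_) {
  stopifnot(is.numeric(time), is.numeric(value), length(time) == length(value))
  if (length(time) == 0L) stop("time series must contain at least one sample")
  if (anyNA(time) || anyNA(value) || any(!is.finite(time)) || any(!is.finite(value)))
    stop("time series values must be finite")
  if (anyDuplicated(time)) stop("duplicate time points are not allowed")
  if (is.unsorted(time)) {
    ord <- order(time)
    time <- time[ord]
    value <- value[ord]
    warning("time points were out of order and have been sorted")
  }
  out <- data.frame(time = as.numeric(time), value = as.numeric(value))
  structure(out,
            class = c("time_series", "data.frame"),
            kind = kind, time_unit = time_unit, value_unit = value_unit,
            preset = preset, seed = seed)
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series kind=%s, n=%d, t in [%g, %g] %s, preset=%s>\n",
              attr(x, "kind"), nrow(x), min(x$time), max(x$time),
              attr(x, "time_unit"), attr(x, "preset")))
  invisible(x)
}

#' Emission / excitation spectrum container
#'
#' Two-column data frame (`wavelength`, `intensity`) with nm wavelengths,
#' used for 77 K chlorophyll fluorescence emission spectra.
#'
#' @param wavelength numeric, nm, strictly increasing.
#' @param intensity numeric, arbitrary units, same length.
#' @param preset optional generating preset name.
#' @return A data frame of class `light_spectrum`.
#' @export
light_spectrum <- function(wavelength, intensity, preset = NA_character_) {
  stopifnot(is.numeric(wavelength), is.numeric(intensity),
            length(wavelength) == length(intensity))
  if (length(wavelength) < 2L) stop("spectrum needs at least two samples")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(data.frame(wavelength = as.numeric(wavelength),
                       intensity = as.numeric(intensity)),
            class = c("light_spectrum", "data.frame"),
            preset = preset)
}

#' @export
print.light_spectrum <- function(x, ...) {
  cat(sprintf("<light_spectrum n=%d, %g-%g nm, preset=%s>\n",
              nrow(x), min(x$wavelength), max(x$wavelength), attr(x, "preset")))
  invisible(x)
}

#' Additive-noise specification for the synthetic generators
#'
#' Gaussian i.i.d. measurement noise added to generated signals. A seed is
#' mandatory whenever `sd > 0` so that every fixture is reproducible.
#'
#' @param sd standard deviation of the additive noise (signal units); 0
#'   disables noise.
#' @param seed integer seed; required when `sd > 0`.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0, seed = NULL) {
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  if (sd > 0 && is.null(seed))
    stop("a seed is required whenever noise is enabled (sd > 0)")
  structure(list(enabled = sd > 0, sd = sd,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "noise_spec")
}

# Run expr with a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Apply a noise_spec to a numeric vector (deterministic given the seed).
apply_noise <- function(values, noise) {
  if (is.null(noise) || !inherits(noise, "noise_spec") || !noise$enabled)
    return(values)
  values + with_local_seed(noise$seed, stats::rnorm(length(values), 0, noise$sd))
}
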