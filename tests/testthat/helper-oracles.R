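# Independent oracles used across the suite.

# Numerical ODE solution of the damage-repair system
# dA/dt = -k_PI * A + k_rec * (A0 - A), A(0) = A0.
ode_damage_repair <- function(k_PI, k_rec, A0, times) {
  out <- deSolve::lsoda(
    y = c(A = A0), times = times,
    func = function(t, y, p) list(-p$k_PI * y[1] + p$k_rec * (p$A0 - y[1])),
    parms = list(k_PI = k_PI, k_rec = k_rec, A0 = A0),
    rtol = 1e-10, atol = 1e-12)
  unname(out[, "A"])
}

# Brute-force glow-peak location: argmax of the simulated curve on a fine grid.
grid_scan_peak <- function(model, dT = 0.001) {
  gc <- simulate_glow(model, dT = dT)
  gc$temperature_K[which.max(gc$intensity)]
}

# A symmetric Gaussian "glow band" with known centre and width, for testing
# the band-feature extractor independently of the Randall-Wilkins simulator.
gaussian_band <- function(center_K = 293, sigma_K = 5, beta = 0.66,
                          from = 274, to = 340, dT = 0.01) {
  temps <- seq(from, to, by = dT)
  structure(data.frame(temperature_K = temps,
                       intensity = exp(-(temps - center_K)^2 / (2 * sigma_K^2))),
            class = c("glow_curve", "data.frame"), beta = beta, T0 = from)
}
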