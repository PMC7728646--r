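test_that("fit_first_order recovers exact parameters across four decades of k", {
  for (k in 10^seq(-4, 2, by = 2)) {
    for (a in c(0.1, 1, 10)) {
      tt <- seq(0, 5 / k, length.out = 60)
      fit <- fit_first_order(time_series(tt, a * exp(-k * tt)))
      expect_lt(abs(fit$k - k) / k, 1e-6)
      expect_lt(abs(fit$amplitude - a) / a, 1e-6)
      # with a floated baseline
      fitb <- fit_first_order(time_series(tt, 0.5 + a * exp(-k * tt)),
                              fit_baseline = TRUE)
      expect_lt(abs(fitb$k - k) / k, 1e-6)
      expect_lt(abs(fitb$baseline - 0.5), 1e-6)
    }
  }
})

test_that("fitted rate is unbiased (<5% ) on noisy decays over 50 seeds", {
  ks <- vapply(1:50, function(s) {
    ts <- gen_flash_decay("EL", with_dcmu = TRUE,
                          noise = noise_spec(sd = 0.01, seed = s))
    fit_first_order(ts)$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.08) / 0.08, 0.05)
})

test_that("degenerate inputs fail with explicit conditions", {
  expect_error(fit_first_order(time_series(0:9, rep(1, 10))),
               class = "photoacclim_no_decay")
  expect_error(fit_first_order(time_series(0:1, c(1, 0))), "3 points")
  expect_error(kpi_from_oxygen(time_series(0:5, 0.5 * exp(-0.1 * 0:5))),
               "normalized")
})

test_that("rates are scale-equivariant, amplitudes and baselines scale", {
  tt <- seq(0, 30, 0.5)
  base <- time_series(tt, 0.2 + 2 * exp(-0.3 * tt))
  f1 <- fit_first_order(base, fit_baseline = TRUE)
  f2 <- fit_first_order(time_series(tt, 7 * base$value), fit_baseline = TRUE)
  expect_equal(f2$k, f1$k, tolerance = 1e-7)
  expect_equal(f2$amplitude, 7 * f1$amplitude, tolerance = 1e-7)
  expect_equal(f2$baseline, 7 * f1$baseline, tolerance = 1e-7)
})

test_that("damage-repair closed form agrees with ODE integration to 1e-6", {
  times <- seq(0, 7200, by = 300)
  for (krec in c(0, 5e-4, 1.115e-3, 5e-3)) {
    m <- damage_repair_model(k_PI = 1.47e-3, k_rec = krec, A0 = 50)
    closed <- simulate_damage_repair(m, times)$value
    numeric <- ode_damage_repair(1.47e-3, krec, 50, times)
    expect_lt(max(abs(closed - numeric)), 1e-6)
  }
  # k_rec = 0 reduces to pure first-order decay to zero
  m0 <- damage_repair_model(k_PI = 2e-3, k_rec = 0, A0 = 10)
  expect_equal(simulate_damage_repair(m0, times)$value,
               10 * exp(-2e-3 * times))
  expect_equal(m0$A_eq, 0)
})

test_that("equilibrium activity increases strictly with the repair rate", {
  aeq <- vapply(seq(1e-4, 5e-3, length.out = 20), function(krec)
    damage_repair_model(k_PI = 1.47e-3, k_rec = krec, A0 = 50)$A_eq,
    numeric(1))
  expect_true(all(diff(aeq) > 0))
  expect_true(all(aeq > 0 & aeq < 50))
})

test_that("fit_damage_repair roundtrips the generating parameters", {
  times <- seq(0, 7200, by = 600)
  m <- damage_repair_model(k_PI = 1.47e-3, k_rec = 1.2e-3, A0 = 48)
  fit <- fit_damage_repair(simulate_damage_repair(m, times),
                           k_PI_fixed = 1.47e-3)
  expect_lt(abs(fit$A0 - 48) / 48, 1e-6)
  expect_lt(abs(fit$k_rec - 1.2e-3) / 1.2e-3, 1e-6)
  expect_lt(abs(fit$A_eq - m$A_eq) / m$A_eq, 1e-6)
  # boundary: no repair -> k_rec ~ 0 and A_eq ~ 0
  m0 <- damage_repair_model(k_PI = 1.47e-3, k_rec = 0, A0 = 50)
  fit0 <- fit_damage_repair(simulate_damage_repair(m0, times),
                            k_PI_fixed = 1.47e-3)
  expect_lt(fit0$k_rec, 1e-8)
  expect_lt(fit0$A_eq, 1e-6)
})

test_that("lincomycin fixtures return the published photoinhibition rates", {
  for (case in list(list(p = "control", k = 1.47e-3),
                    list(p = "EL", k = 1.38e-3))) {
    ts <- gen_photoinhibition_series(case$p, lincomycin = TRUE,
                                     duration = 3600, interval = 600)
    rel <- photoinhibition_relative(ts, chl = fixture_preset(case$p)$chl_per_od)
    fit <- kpi_from_oxygen(rel)
    expect_equal(fit$k, case$k, tolerance = 1e-6)
    expect_identical(fit$role, "k_PI")
  }
})
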