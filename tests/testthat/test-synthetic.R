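test_that("flash-decay fixtures are exact exponentials with preset rates", {
  ts <- gen_flash_decay("control", with_dcmu = TRUE)
  expect_equal(ts$value, exp(-0.24 * ts$time))
  # value at t = 1/k is e^-1 of the initial amplitude
  expect_equal(stats::approx(ts$time, ts$value, xout = 1 / 0.24)$y,
               exp(-1), tolerance = 1e-3)
  expect_equal(min(ts$time), 3e-4)
  expect_equal(max(ts$time), 120)
  expect_error(gen_flash_decay("control", duration = -1), "positive")
})

test_that("the fast -DCMU phase is larger in EL than in control", {
  ctrl <- gen_flash_decay("control", with_dcmu = FALSE)
  el <- gen_flash_decay("EL", with_dcmu = FALSE)
  # after the fast phase (t ~ 50 ms) EL has lost more of its amplitude
  v_ctrl <- stats::approx(ctrl$time, ctrl$value, xout = 0.05)$y
  v_el <- stats::approx(el$time, el$value, xout = 0.05)$y
  expect_lt(v_el, v_ctrl)
})

test_that("generators are deterministic given preset, arguments and seed", {
  n1 <- noise_spec(sd = 0.01, seed = 7)
  a <- gen_flash_decay("EL", noise = n1)
  b <- gen_flash_decay("EL", noise = n1)
  expect_identical(a$value, b$value)
  c <- gen_flash_decay("EL", noise = noise_spec(sd = 0.01, seed = 8))
  expect_false(identical(a$value, c$value))
  g1 <- gen_glow_curve(13.6)
  g2 <- gen_glow_curve(13.6)
  expect_identical(g1$intensity, g2$intensity)
  expect_error(noise_spec(sd = 0.01), "seed")
})

test_that("noise injection does not perturb the caller's RNG stream", {
  set.seed(123)
  expected <- stats::rnorm(3)
  set.seed(123)
  invisible(gen_flash_decay("EL", noise = noise_spec(sd = 0.01, seed = 5)))
  expect_identical(stats::rnorm(3), expected)
})

test_that("OJIP fixtures peak exactly at t_Fm and decline afterwards in EL", {
  for (p in c("control", "EL")) {
    for (dcmu in c(FALSE, TRUE)) {
      ts <- gen_ojip(p, with_dcmu = dcmu)
      expect_equal(ts$time[which.max(ts$value)], 0.161)
    }
  }
  el <- gen_ojip("EL")
  # clear post-peak decline of the variable fluorescence in EL
  r_end <- (el$value[nrow(el)] - el$value[1]) / (max(el$value) - el$value[1])
  expect_lt(r_end, 0.75)
  expect_equal(gen_ojip("control")$value[1], 0.24)    # F0 = F0_rel * FM
})

test_that("photoinhibition fixtures follow the two kinetic regimes", {
  linc <- gen_photoinhibition_series("control", lincomycin = TRUE,
                                     duration = 3600, interval = 600, A0 = 50)
  expect_equal(linc$value, 50 * exp(-1.47e-3 * linc$time))
  expect_equal(linc$time, seq(0, 3600, 600))
  # pure first-order decay heads to zero at long times
  long <- gen_photoinhibition_series("control", lincomycin = TRUE,
                                     duration = 2e4, interval = 2e3)
  expect_lt(long$value[nrow(long)] / long$value[1], 1e-12)
  # no lincomycin: plateau at the preset equilibrium rate
  free <- gen_photoinhibition_series("control", lincomycin = FALSE,
                                     duration = 2e4, interval = 2e3)
  expect_equal(free$value[nrow(free)], 21.57, tolerance = 1e-6)
  expect_error(gen_photoinhibition_series("control", A0 = 0), "positive")
})

test_that("SOSG fixtures have constant per-period slopes with preset ratio", {
  ctrl <- sosg_rate(gen_sosg_series("control"))
  el <- sosg_rate(gen_sosg_series("EL"))
  expect_equal(as.numeric(el) / as.numeric(ctrl), 0.102)
  expect_equal(diff(range(attr(ctrl, "period_slopes"))), 0)
  dark <- sosg_rate(gen_sosg_series("control", dark_control = TRUE))
  expect_equal(as.numeric(dark), 0)
})

test_that("growth fixtures start at OD 0.01 and respect acclimation fractions", {
  curves <- gen_growth_curves("control", n_cultures = 30, seed = 11)
  expect_true(all(vapply(curves, function(ts) ts$value[1] == 0.01,
                         logical(1))))
  tab <- acclimation_table(curves)
  expect_equal(unname(tab$pct), c(0, 40 / 3, 80), tolerance = 1e-9)
  # degenerate fraction: nobody crosses the threshold
  p0 <- fixture_preset("control")
  p0$acclim_fraction_96h <- 0
  p0$acclim_fraction_48h <- 0
  none <- gen_growth_curves(p0, n_cultures = 10, seed = 2)
  expect_equal(unname(acclimation_table(none)$pct), c(0, 0, 0))
})

test_that("pigment absorbance triplets invert the Wellburn equations", {
  expect_equal(unname(gen_pigment_absorbances(0, 0, 0)), c(0, 0, 0))
  set.seed(4)
  for (i in 1:20) {
    target <- stats::runif(3, 0, 20)
    abs3 <- gen_pigment_absorbances(target[1], target[2], target[3])
    res <- pigments_wellburn(A470 = abs3[["A470"]], A652_4 = abs3[["A652_4"]],
                             A665_2 = abs3[["A665_2"]])
    expect_lt(max(abs(c(res$chl_a, res$chl_b, res$carotenoids) - target)),
              1e-9)
  }
})
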