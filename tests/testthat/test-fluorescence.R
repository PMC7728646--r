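test_that("double normalization has its algebraic fixed points", {
  tt <- 10^seq(-3, 2, length.out = 50)
  expect_equal(double_normalize_decay(time_series(tt, rep(5, 50)), 1, 5)$value,
               rep(1, 50))
  expect_equal(double_normalize_decay(time_series(tt, rep(1, 50)), 1, 5)$value,
               rep(0, 50))
  raw <- time_series(tt, 1 + 4 * exp(-0.2 * tt))
  once <- double_normalize_decay(raw, 1, 5)
  twice <- double_normalize_decay(once, 0, 1)
  expect_equal(twice$value, once$value)
  expect_error(double_normalize_decay(raw, 5, 5), "exceed")
})

test_that("induction features recover the preset OJIP phenotypes", {
  ctrl <- induction_features(gen_ojip("control"))
  el <- induction_features(gen_ojip("EL"))
  expect_equal(ctrl$FvFm, 0.76, tolerance = 1e-10)
  expect_equal(el$FvFm, 0.30, tolerance = 1e-10)
  expect_equal(ctrl$t_Fm, 0.161)
  expect_equal(el$t_Fm, 0.161)
  # J and I step levels lie between F0 and FM, control resolves J < I
  expect_true(all(ctrl$step_values > ctrl$F0 & ctrl$step_values < ctrl$Fm))
  expect_lt(ctrl$step_values[["J"]], ctrl$step_values[["I"]])
})

test_that("FvFm is invariant under detector rescaling and 0 for flat traces", {
  trace <- gen_ojip("control")
  scaled <- time_series(trace$time, 37.2 * trace$value)
  expect_equal(induction_features(scaled)$FvFm,
               induction_features(trace)$FvFm)
  flat <- time_series(trace$time, rep(2, nrow(trace)))
  expect_equal(induction_features(flat)$FvFm, 0)
  expect_error(induction_features(time_series(trace$time,
                                              rep(0, nrow(trace)))),
               "F0")
})

test_that("a monotonically rising trace is flagged as truncated", {
  tt <- 10^seq(-5, 0.3, length.out = 100)
  rising <- time_series(tt, 0.2 + 0.8 * stats::plogis(log10(tt) + 1))
  expect_warning(feats <- induction_features(rising), "truncated")
  expect_equal(feats$t_Fm, tt[length(tt)])
})

test_that("713 nm normalization is exact, scale-invariant and reversible", {
  spec <- gen_77k_spectrum("control")
  norm <- normalize_spectrum_713(spec)
  expect_equal(stats::approx(norm$wavelength, norm$intensity, 713)$y, 1)
  scaled <- light_spectrum(spec$wavelength, 3.7 * spec$intensity)
  expect_equal(normalize_spectrum_713(scaled)$intensity, norm$intensity)
  ref <- stats::approx(spec$wavelength, spec$intensity, 713)$y
  expect_lt(max(abs(norm$intensity * ref - spec$intensity)), 1e-12)
  expect_error(normalize_spectrum_713(light_spectrum(400:500, rep(1, 101))),
               "713")
})

test_that("PSII/PSI ratio matches presets and is scale/normalization invariant", {
  ctrl <- gen_77k_spectrum("control")
  el <- gen_77k_spectrum("EL")
  expect_equal(psii_psi_ratio(ctrl)$ratio, 1.5, tolerance = 1e-9)
  expect_equal(psii_psi_ratio(el)$ratio, 0.95, tolerance = 1e-9)
  scaled <- light_spectrum(ctrl$wavelength, 0.01 * ctrl$intensity)
  expect_equal(psii_psi_ratio(scaled)$ratio, psii_psi_ratio(ctrl)$ratio)
  expect_equal(psii_psi_ratio(normalize_spectrum_713(ctrl))$ratio,
               psii_psi_ratio(ctrl)$ratio)
  # peaks are found inside their search bands
  feats <- psii_psi_ratio(ctrl)
  expect_true(feats$psii_peak_nm >= 675 && feats$psii_peak_nm <= 700)
  expect_true(feats$psi_peak_nm >= 705 && feats$psi_peak_nm <= 725)
})

test_that("equal non-overlapping emission bands give ratio 1", {
  spec <- photoacclim:::two_band_spectrum(a_psii = 1, a_psi = 1,
                                          sigma_psii = 1.5, sigma_psi = 1.5)
  expect_equal(psii_psi_ratio(spec)$ratio, 1, tolerance = 1e-10)
})
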