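test_that("noiseless melts are recovered and the midpoint is half-unfolded", {
  g <- gen_melt(Tm_C = 67.4, dH_vH = 60, sigma = 0)
  f <- fit_melt(g$data)
  expect_rel(f$Tm, 340.55, 1e-6)
  expect_rel(f$dH_vH, 60, 1e-4)
  expect_equal(acpdyn:::melt_funfolded(f$Tm, f$Tm, f$dH_vH), 0.5)
  expect_equal(acpdyn:::melt_funfolded(340.55, 340.55, 123.4), 0.5)
})

test_that("a pair of melts differing only in Tm recovers the Tm difference", {
  # generator truths at the metal-free and calcium conditions
  f_apo <- fit_melt(gen_melt(Tm_C = 54.5, sigma = 0)$data)
  f_ca <- fit_melt(gen_melt(Tm_C = 67.4, sigma = 0)$data)
  expect_equal(f_ca$Tm - f_apo$Tm, 12.9, tolerance = 1e-4)
})

test_that("melt fitting rejects unbracketed transitions", {
  g <- gen_melt(Tm_C = 120, sigma = 0)  # midpoint above the scanned range
  expect_error(fit_melt(g$data), "not bracketed")
  expect_error(fit_melt(data.frame(T = seq(298, 360, length.out = 9), y = 1:9)),
               ">= 10")
})

test_that("DSC quadrature reproduces the analytic peak area", {
  g <- gen_dsc(base_a = 0, sigma = 0)
  r <- dsc_analyze(g$data, baseline = "none")
  expect_rel(r$dH_cal, 71.2, 1e-3)  # within 0.1%
  # halving the temperature step barely changes the integral
  g2 <- gen_dsc(base_a = 0, sigma = 0, T_C = seq(20, 100, by = 0.1))
  r2 <- dsc_analyze(g2$data, baseline = "none")
  expect_lt(abs(r2$dH_cal - r$dH_cal) / r$dH_cal, 1e-4)
  # axis relabeling C <-> K leaves the integral unchanged
  r3 <- dsc_analyze(data.frame(T = g$data$T - 273.15, y = g$data$y),
                    baseline = "none", temperature_unit = "C")
  expect_equal(r3$dH_cal, r$dH_cal)
})

test_that("baseline estimation recovers enthalpy and peak position", {
  g <- gen_dsc(base_a = 0.5, base_b = 0.002, sigma = 0)
  for (bl in c("progress", "linear")) {
    r <- dsc_analyze(g$data, baseline = bl)
    expect_rel(r$dH_cal, 71.2, 0.05)
    expect_lt(abs(r$Tm - 339.55), 0.5)
    expect_rel(r$Cp_max, g$truth$Cp_max, 0.05)
  }
})

test_that("flat thermograms yield zero enthalpy and no melting point", {
  r <- dsc_analyze(data.frame(T = seq(293, 373, by = 1), y = rep(0.5, 81)))
  expect_equal(r$dH_cal, 0)
  expect_true(is.na(r$Tm))
  # inverted peak = baseline misfit
  g <- gen_dsc(base_a = 0, sigma = 0)
  expect_error(dsc_analyze(data.frame(T = g$data$T, y = 0.5 - g$data$y)),
               "baseline misfit")
})

test_that("the two-state excess model round-trips through its fitter", {
  g <- gen_dsc(base_a = 0, sigma = 0)  # Tm 339.55 K, dH_vH = dH_cal = 71.2
  f <- dsc_two_state_fit(g$data)
  expect_rel(f$Tm, 339.55, 1e-5)
  expect_rel(f$dH_vH, 71.2, 1e-4)
  expect_rel(f$dH_cal, 71.2, 1e-4)
  # closed-form peak height at Tm where K = 1
  expect_equal(dsc_excess_model(339.55, 339.55, 71.2, 71.2),
               71.2 * 71.2 / (4 * gas_constant_kcal() * 339.55^2))
  # unequal enthalpies are distinguished
  g2 <- gen_dsc(base_a = 0, dH_vH = 50, dH_cal = 71.2, sigma = 0)
  f2 <- dsc_two_state_fit(g2$data)
  expect_rel(f2$dH_vH, 50, 1e-4)
  expect_rel(f2$dH_cal, 71.2, 1e-4)
})

test_that("two-state recovery is unbiased at 1% noise", {
  set.seed(99)
  peak <- gen_dsc(base_a = 0, sigma = 0)$truth$Cp_max
  seeds <- sample.int(1e6, 500)
  tms <- vapply(seeds, function(s) {
    g <- gen_dsc(base_a = 0, sigma = 0.01 * peak, seed = s)
    dsc_two_state_fit(g$data)$Tm
  }, numeric(1))
  expect_lt(abs(mean(tms) - 339.55) / 339.55, 1e-4)
})
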