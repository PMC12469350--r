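test_that("noiseless exponential decays are recovered to high precision", {
  t <- seq(0, 60000, by = 600)
  for (k in c(0.2, 1, 5, 20) / 60000) {  # k * t_max in [0.2, 20]
    d <- data.frame(t = t, y = 1.0 * exp(-k * t) + 0.1)
    f <- fit_exchange_decay(d)
    expect_rel(f$k_ex, k, 1e-6)
    expect_rel(f$I0, 1.0, 1e-6)
    expect_lt(abs(f$C - 0.1), 1e-6)
    expect_false(f$censored)
  }
  # the worked example: 0.005 min^-1
  d <- data.frame(t = t, y = 1.0 * exp(-8.33e-5 * t) + 0.1)
  f <- fit_exchange_decay(d)
  expect_rel(f$k_ex, 8.33e-5, 1e-6)
})

test_that("exchange fit is invariant under intensity rescaling", {
  t <- seq(0, 60000, by = 1200)
  y <- 1.3 * exp(-2e-5 * t) + 0.2
  f1 <- fit_exchange_decay(data.frame(t = t, y = y))
  f2 <- fit_exchange_decay(data.frame(t = t, y = 1e6 * y))
  expect_rel(f2$k_ex, f1$k_ex, 1e-8)
})

test_that("flat and unresolvably slow decays are censored with an upper bound", {
  t <- seq(0, 60000, by = 600)
  f <- fit_exchange_decay(data.frame(t = t, y = rep(0.9, length(t))))
  expect_true(f$censored)
  expect_equal(f$k_ex, -log(0.95) / 60000, tolerance = 1e-12)
  expect_error(fit_exchange_decay(data.frame(t = 1:4, y = rep(1, 4))), ">= 5")
  expect_error(fit_exchange_decay(data.frame(t = t, y = -exp(-t / 1e4))), "negative")
})

test_that("fitted rates fall within 3 standard errors at calibrated coverage", {
  # Monte-Carlo calibration: truth I0=1, k=8.33e-5 s^-1, C=0.1, sigma=0.02
  set.seed(421)
  t <- seq(0, 60000, length.out = 100)
  truth_k <- 8.33e-5
  y0 <- 1.0 * exp(-truth_k * t) + 0.1
  hits <- vapply(1:500, function(i) {
    f <- fit_exchange_decay(data.frame(t = t, y = y0 + rnorm(100, 0, 0.02)))
    abs(f$k_ex - truth_k) <= 3 * f$k_err
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("intrinsic rates match the brute-force oracle on all triplets", {
  centers <- setdiff(rownames(acpdyn:::RC_CORRECTIONS), "P")
  neighbors <- rownames(acpdyn:::RC_CORRECTIONS)
  worst <- 0
  for (aa in centers) {
    for (left in neighbors) {
      for (right in neighbors) {
        got <- intrinsic_rate(aa, left, right, pD = 6.5, temperature = 293.15)
        want <- oracle_intrinsic_rate(aa, left, right, pD = 6.5, temp = 293.15)
        worst <- max(worst, abs(got - want) / want)
      }
    }
  }
  expect_lt(worst, 1e-10)
  # reference poly-alanine context at reference conditions
  expect_rel(intrinsic_rate("A", "A", "A", pD = 6.5, temperature = 293.15),
             oracle_intrinsic_rate("A", "A", "A", pD = 6.5, temp = 293.15), 1e-12)
})

test_that("intrinsic rate is V-shaped in pD and increasing in temperature", {
  pDs <- seq(1, 7, by = 0.05)
  k <- vapply(pDs, function(p) intrinsic_rate("L", "A", "K", pD = p), numeric(1))
  sign_changes <- sum(diff(sign(diff(k))) != 0)
  expect_equal(sign_changes, 1)  # single minimum between acid and base limbs
  temps <- seq(283.15, 313.15, by = 2)
  kT <- vapply(temps, function(tt) intrinsic_rate("L", "A", "K", temperature = tt),
               numeric(1))
  expect_true(all(diff(kT) > 0))
  expect_error(intrinsic_rate("P", "A", "A"), "proline")
})

test_that("protection factors obey the free-energy identity exactly", {
  f <- structure(list(residue = 10L, aa = "I", I0 = 1, C = 0, k_ex = 1e-3,
                      k_err = 1e-5, censored = FALSE), class = "exchange_fit")
  p <- protection(f, k_rc = 10, temperature = 298.15)
  expect_equal(p$P, 1e4)
  expect_equal(p$logP, 4)
  expect_equal(p$dG_local, log(10) * gas_constant_kcal() * 298.15 * p$logP)
  # identity case k_prot = k_rc
  f$k_ex <- 10
  p0 <- protection(f, k_rc = 10)
  expect_equal(p0$logP, 0)
  expect_equal(p0$dG_local, 0)
  # logP = 4.2 at 298.15 K sits at the 1.5 x global-stability line
  expect_equal(4.2 * log(10) * gas_constant_kcal() * 298.15, 5.73, tolerance = 2e-3)
  expect_error(protection(f, k_rc = -1), "positive")
})

test_that("end-to-end hdx analysis recovers generator truth", {
  g <- gen_hdx(sigma = 0, seed = 11)
  p <- hdx_analyze(g$data)
  expect_equal(p$logP, g$truth$logP, tolerance = 1e-7)
  expect_equal(p$dG_local, g$truth$dG_local, tolerance = 1e-7)
  expect_equal(p$dG_local, log(10) * gas_constant_kcal() * 298.15 * p$logP)
})
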