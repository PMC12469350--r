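test_that("noiseless relaxation decays are recovered exactly across rates", {
  for (rate in c(0.5, 2, 9.86, 20)) {
    g <- gen_relaxation(rates = rate, kind = "R2", sigma = 0)
    f <- fit_relaxation(g$data, kind = "R2", residue = 2L)
    expect_rel(f$rate, rate, 1e-8)
  }
  g1 <- gen_relaxation(rates = c(1.2, 1.9), kind = "R1", sigma = 0)
  out <- fit_relaxation_set(g1$data, kind = "R1")
  expect_equal(out$rate, c(1.2, 1.9), tolerance = 1e-8)
  expect_equal(out$kind, c("R1", "R1"))
})

test_that("rate fits are invariant under intensity rescaling", {
  g <- gen_relaxation(rates = 7, sigma = 0.02, seed = 5)
  f1 <- fit_relaxation(g$data, kind = "R2")
  d2 <- g$data
  d2$y <- d2$y * 4.2e5
  f2 <- fit_relaxation(d2, kind = "R2")
  expect_rel(f2$rate, f1$rate, 1e-9)
})

test_that("duplicate delays give a zero sigma for identical intensities", {
  tau <- relaxation_delays("R1")
  y <- 2 * exp(-1.5 * tau)  # duplicates identical by construction
  f <- fit_relaxation(data.frame(tau = tau, y = y), kind = "R1")
  expect_equal(f$sigma, 0)
  expect_error(fit_relaxation(data.frame(tau = rep(0.1, 6), y = rep(1, 6))),
               "distinct delays")
  expect_error(fit_relaxation(data.frame(tau = c(0, 0.1), y = c(1, 0.5))), ">= 6")
})

test_that("rate estimates are unbiased and sigma is recovered from duplicates", {
  set.seed(2024)
  seeds <- sample.int(1e6, 500)
  res <- vapply(seeds, function(s) {
    g <- gen_relaxation(rates = 9.86, kind = "R2", sigma = 0.02, seed = s)
    f <- fit_relaxation(g$data, kind = "R2")
    c(f$rate, f$sigma)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 9.86) / 9.86, 0.01)   # bias < 1%
  expect_lt(abs(sqrt(mean(res[2, ]^2)) - 0.02) / 0.02, 0.15)
})

test_that("hNOE ratios pass through, including sign inversion", {
  g <- gen_hnoe_tables(c(0.8, -0.2, 1.0), sigma = 0)
  h <- hnoe(g$data$sat, g$data$unsat, sigma = 0.01)
  expect_equal(h$hnoe, c(0.8, -0.2, 1.0), tolerance = 1e-12)
  expect_true(all(is.finite(h$err)))
  # missing residue excluded with warning
  sat <- g$data$sat[-2, ]
  expect_warning(h2 <- hnoe(sat, g$data$unsat, 0.01), "excluding")
  expect_equal(nrow(h2), 2)
})

test_that("dynamics classification flags exactly the constructed outliers", {
  set.seed(8)
  n <- 40
  resid <- 2:(n + 1)
  # homogeneous cohort recovered noiselessly through the fitting stage,
  # with two residues inflated well beyond the cohort spread
  rates <- rep(5, n)
  rates[c(9, 24)] <- c(9.86, 8.72)
  g <- gen_relaxation(rates = rates, residues = resid, kind = "R2", sigma = 0)
  r2 <- fit_relaxation_set(g$data, kind = "R2")
  noe <- tibble::tibble(residue = resid, hnoe = rep(0.8, n))
  noe$hnoe[c(5, 30)] <- c(0.3, 0.2)
  cls <- classify_dynamics(r2, noe)
  expect_identical(sort(cls$residue[cls$exchange_broadened]), resid[c(9, 24)])
  expect_identical(sort(cls$residue[cls$flexible]), resid[c(5, 30)])
  # permutation invariance
  perm <- sample(n)
  cls2 <- classify_dynamics(r2[perm, ], noe[sample(n), ])
  expect_identical(cls2$exchange_broadened, cls$exchange_broadened)
  # homogeneous rates: nothing flagged
  r2h <- tibble::tibble(residue = resid, rate = rep(5, n))
  noeh <- tibble::tibble(residue = resid, hnoe = rep(0.8, n))
  clsh <- classify_dynamics(r2h, noeh)
  expect_false(any(clsh$exchange_broadened))
  expect_false(any(clsh$flexible))
})
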