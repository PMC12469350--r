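test_that("the weighted CSP formula matches hand evaluations", {
  ref <- data.frame(residue = 1:3, aa = c("L", "G", "A"),
                    dH = c(8, 8, 8), dN = c(120, 110, 115))
  st <- data.frame(residue = 1:3, aa = c("L", "G", "A"),
                   dH = c(8.1, 8, 8), dN = c(120.5, 111, 115))
  out <- csp(ref, st)
  expect_lt(abs(out$dd[1] - 0.1), 1e-12)           # sqrt(0.5(0.01+0.01))
  expect_lt(abs(out$dd[2] - 0.14 / sqrt(2)), 1e-12)  # Gly alpha = 0.14
  expect_equal(out$dd[3], 0)
  # outside-the-root convention
  alt <- csp(ref, st, half = "outside")
  expect_lt(abs(alt$dd[1] - 0.5 * sqrt(0.02)), 1e-12)
})

test_that("csp is homogeneous and direction-symmetric", {
  set.seed(5)
  ref <- data.frame(residue = 1:8, aa = sample(c("L", "G", "K", "S"), 8, TRUE),
                    dH = runif(8, 7, 9), dN = runif(8, 105, 130))
  st <- ref
  st$dH <- st$dH + rnorm(8, 0, 0.05)
  st$dN <- st$dN + rnorm(8, 0, 0.4)
  base <- csp(ref, st)$dd
  # swap reference and state
  expect_equal(csp(st, ref)$dd, base)
  # scale both shift differences by lambda
  lam <- 3.7
  st2 <- ref
  st2$dH <- ref$dH + lam * (st$dH - ref$dH)
  st2$dN <- ref$dN + lam * (st$dN - ref$dN)
  expect_equal(csp(ref, st2)$dd, lam * base, tolerance = 1e-12)
  # residue mismatch is an error
  bad <- st
  bad$aa[1] <- "W"
  expect_error(csp(ref, bad), "mismatch")
})

test_that("mean + sd significance flags work and are scale-invariant", {
  rec <- tibble::tibble(residue = 1:10, aa = "A", dd = c(rep(0.1, 9), 1.0))
  out <- significance_flags(rec)
  expect_equal(attr(out, "threshold"), mean(rec$dd) + sd(rec$dd))
  expect_lt(abs(attr(out, "threshold") - 0.4746), 1e-3)
  expect_identical(which(out$significant), 10L)
  # all equal: sd = 0 and the strict inequality flags nothing
  none <- significance_flags(tibble::tibble(dd = rep(0.3, 6)))
  expect_false(any(none$significant))
  # global rescaling leaves the flag set unchanged
  out2 <- significance_flags(dplyr::mutate(rec, dd = dd * 123.4))
  expect_identical(out$significant, out2$significant)
  # missing values excluded from the statistics, never flagged
  withna <- significance_flags(tibble::tibble(dd = c(rep(0.1, 9), 1.0, NA)))
  expect_identical(which(withna$significant), 10L)
})

test_that("paramagnetic ratios follow the vanished-peak convention", {
  ref <- data.frame(residue = 1:3, aa = c("E", "D", "L"),
                    intensity = c(1e6, 2e6, 1.5e6))
  met <- data.frame(residue = 1:3, aa = c("E", "D", "L"),
                    intensity = c(1e6, NA, 0.3e6))
  r <- paramagnetic_ratio(ref, met)
  expect_equal(r$ratio, c(1, 0, 0.2))
  # absent from reference -> excluded with warning
  ref$intensity[3] <- NA
  expect_warning(r2 <- paramagnetic_ratio(ref, met), "reference")
  expect_equal(nrow(r2), 2)
})

test_that("generated attenuation profiles decrease monotonically with metal", {
  pm <- gen_paramagnetic(detection_floor = 0)
  ratios <- sapply(seq_along(pm$data), function(i) {
    paramagnetic_ratio(pm$data[[1]], pm$data[[i]])$ratio
  })
  for (i in seq_len(nrow(ratios))) {
    expect_true(all(diff(ratios[i, ]) <= 0))
  }
  # site residues attenuate far more than remote ones at the top concentration
  last <- paramagnetic_ratio(pm$data[[1]], pm$data[[length(pm$data)]])
  site <- last$ratio[last$residue %in% c(35, 51)]
  remote <- last$ratio[last$residue %in% c(20, 25)]
  expect_true(all(site < 0.05))
  expect_true(all(remote > 0.9))
})

test_that("titration trajectories are monotone saturating with correct endpoints", {
  ti <- gen_titration_states()
  tr <- titration_trajectory(ti$data, ti$concentrations)
  prof <- tr$profile
  # two identical states give an all-zero profile
  zero <- titration_trajectory(ti$data[c(1, 1)], c(0, 1))
  expect_true(all(zero$profile$dd == 0))
  # endpoint CSP of a site residue equals the closed-form bound fraction
  for (res in ti$truth$site_residues) {
    end <- prof$dd[prof$residue == res & prof$concentration == 30]
    i <- match(res, ti$truth$site_residues)
    expect_equal(end, ti$truth$fb[length(ti$truth$fb)] * ti$truth$bound_csp[i],
                 tolerance = 1e-10)
  }
  # site residues rank above non-site residues by endpoint CSP
  endpoints <- prof[prof$concentration == 30, ]
  site_min <- min(endpoints$dd[endpoints$residue %in% ti$truth$site_residues])
  other_max <- max(endpoints$dd[!endpoints$residue %in% ti$truth$site_residues])
  expect_gt(site_min, other_max)
  # site profiles are perfectly monotone in concentration (sigma = 0)
  mono <- tr$monotonicity
  expect_true(all(mono$spearman[mono$residue %in% ti$truth$site_residues] == 1))
  expect_error(titration_trajectory(ti$data, c(0, 1)), "length")
})
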