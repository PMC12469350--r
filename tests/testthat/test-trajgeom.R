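test_that("dihedral kernel matches trivial geometries and the atan2 oracle", {
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  set.seed(101)
  for (i in 1:1000) {
    pts <- matrix(rnorm(12), 4, 3)
    got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_lt(abs(got - want), 1e-10)
  }
  # reversal flips the sign but keeps the magnitude
  set.seed(7)
  pts <- matrix(rnorm(12), 4, 3)
  a <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  b <- dihedral_angle(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
  expect_equal(abs(a), abs(b), tolerance = 1e-10)
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincide")
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

simple_frames <- function(xyz, atoms = paste0("A", seq_len(nrow(xyz))),
                          residue = 1L, frame = 1L, mass = NULL) {
  tb <- tibble::tibble(frame = frame, residue = residue, atom = atoms,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  if (!is.null(mass)) tb$mass <- mass
  tb
}

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  one <- simple_frames(matrix(c(3, 4, 5), 1))
  expect_equal(radius_of_gyration(one)$rg, 0)
  two <- simple_frames(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two)$rg, 1)
  set.seed(31)
  cloud <- simple_frames(matrix(rnorm(60), 20), mass = runif(20, 1, 16))
  rg0 <- radius_of_gyration(cloud)$rg
  for (i in 1:100) {
    tf <- random_rigid_transform()
    rg <- radius_of_gyration(apply_rigid(cloud, tf$Q, tf$t))$rg
    expect_lt(abs(rg - rg0), 1e-10)
  }
  expect_error(radius_of_gyration(simple_frames(matrix(0, 2, 3), mass = c(0, 0))),
               "zero total mass")
})

test_that("COM distances match the brute-force averaging oracle", {
  set.seed(17)
  xyz <- matrix(rnorm(30, sd = 5), 10)
  fr <- simple_frames(xyz)
  sel <- data.frame(residue = 1L, atom = paste0("A", 1:9))
  d <- com_distance(fr, sel, list(residue = 1L, atom = "A10"))$distance
  expect_equal(d, sqrt(sum((oracle_com(xyz[1:9, ]) - xyz[10, ])^2)), tolerance = 1e-12)
  # selection = target atom alone: zero
  d0 <- com_distance(fr, data.frame(residue = 1L, atom = "A10"),
                     list(residue = 1L, atom = "A10"))$distance
  expect_equal(d0, 0)
  # symmetric pair about the target: zero
  sym <- simple_frames(rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 0)),
                       atoms = c("L", "R", "B"))
  expect_equal(com_distance(sym, data.frame(residue = 1L, atom = c("L", "R")),
                            list(residue = 1L, atom = "B"))$distance, 0)
  expect_error(com_distance(fr, sel, list(residue = 9L, atom = "ZZ")), "not found")
  # rigid invariance
  tf <- random_rigid_transform()
  d2 <- com_distance(apply_rigid(fr, tf$Q, tf$t), sel,
                     list(residue = 1L, atom = "A10"))$distance
  expect_lt(abs(d2 - d), 1e-10)
})

test_that("hydrogen-bond occupancy counts frames at the cutoff correctly", {
  dists <- c(3.0, 3.6, 3.4, 4.0)
  fr <- dplyr::bind_rows(lapply(seq_along(dists), function(f) {
    tibble::tibble(frame = f, residue = c(1L, 2L), atom = c("NE", "O"),
                   x = c(0, dists[f]), y = 0, z = 0)
  }))
  hb <- hbond_occupancy(fr, list(residue = 1L, atom = "NE"),
                        list(residue = 2L, atom = "O"))
  expect_equal(hb$occupancy, 0.5)
  expect_equal(hbond_occupancy(fr, list(residue = 1L, atom = "NE"),
                               list(residue = 2L, atom = "O"), cutoff = 5)$occupancy, 1)
  expect_equal(hbond_occupancy(fr, list(residue = 1L, atom = "NE"),
                               list(residue = 2L, atom = "O"), cutoff = 0)$occupancy, 0)
  # monotone non-decreasing in the cutoff
  occs <- vapply(seq(0, 5, by = 0.25), function(co) {
    hbond_occupancy(fr, list(residue = 1L, atom = "NE"),
                    list(residue = 2L, atom = "O"), cutoff = co)$occupancy
  }, numeric(1))
  expect_true(all(diff(occs) >= 0))
})

test_that("state assignment is wrap-aware and recovers telegraph dwell", {
  s <- switch_detect(c(-70, -180, -70, -180, -70), states = c(-70, -180),
                     tolerance = 30)
  expect_equal(s$transitions, 4)
  expect_equal(unname(s$occupancy), c(0.6, 0.4))
  # -179 and +179 land in the same -180 state
  w <- switch_detect(c(-179, 179), states = c(-70, -180), tolerance = 30)
  expect_equal(w$labels, c(-180, -180))
  expect_equal(w$transitions, 0)
  expect_error(switch_detect(1:5, states = c(-70, -100), tolerance = 30),
               "overlapping")
  # telegraph series at 1e4 frames: occupancy within 2%
  set.seed(55)
  n <- 1e4
  sched <- ifelse(runif(n) < 0.63, -70, -180)
  angles <- sched + rnorm(n, 0, 8)
  tel <- switch_detect(angles, states = c(-70, -180), tolerance = 30)
  expect_lt(abs(tel$occupancy[["-70"]] - mean(sched == -70)), 0.02)
})

test_that("chi1 series and packaged atom tables behave", {
  expect_equal(chi1_atoms("I"), c("N", "CA", "CB", "CG1"))
  expect_equal(chi1_atoms("S"), c("N", "CA", "CB", "OG"))
  expect_error(chi1_atoms("A"), "no chi1")
  expect_error(chi1_atoms("G"), "no chi1")
  g <- gen_trajectory(n_frames = 60, sigma = 0, seed = 21)
  ch <- chi1_series(g$data, 1, "L")
  truth <- g$truth$chi1_states[g$truth$chi1_schedule]
  err <- ((ch$chi1 - truth + 180) %% 360) - 180
  expect_lt(max(abs(err)), 1e-9)
})

test_that("multi-model PDB and table dialects load the same frames", {
  g <- gen_trajectory(n_frames = 3, sigma = 0, seed = 4, rigid_motion = FALSE)
  fr <- g$data
  # write a minimal multi-model PDB
  pdbf <- withr::local_tempfile(fileext = ".pdb")
  lines <- c()
  for (f in unique(fr$frame)) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    sub <- fr[fr$frame == f, ]
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, sub$atom[i], "ALA", sub$residue[i], sub$x[i], sub$y[i], sub$z[i]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), pdbf)
  got <- read_frames(pdbf)
  expect_equal(nrow(got), nrow(fr))
  expect_equal(got$x, fr$x, tolerance = 1e-3)
  expect_setequal(unique(got$atom), unique(fr$atom))

  tabf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("frame residue atom x y z",
               apply(fr, 1, function(r) paste(r, collapse = " "))), tabf)
  got2 <- read_frames(tabf)
  expect_equal(got2$x, fr$x, tolerance = 1e-6)
})
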