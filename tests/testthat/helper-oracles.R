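# Independent oracles, deliberately coded on different paths from the
# package implementations they check.

# Brute-force random-coil rate: explicit log10 bookkeeping per catalytic
# term, using the packaged correction constants as data.
oracle_intrinsic_rate <- function(aa, left, right, pD = 6.5, temp = 298.15,
                                  position = "internal") {
  tab <- acpdyn:::RC_CORRECTIONS
  ref <- acpdyn:::RC_REFERENCE
  R <- gas_constant_kcal()
  la <- ref$log_kA + tab[aa, "acid_self"] + tab[left, "acid_next"] - pD
  lb <- ref$log_kB + tab[aa, "base_self"] + tab[left, "base_next"] + pD - ref$pKD
  lw <- ref$log_kW + tab[aa, "base_self"] + tab[left, "base_next"]
  if (position == "nterm") {
    la <- la + ref$nterm_acid
    lb <- lb + ref$nterm_base
    lw <- lw + ref$nterm_base
  }
  if (position == "cterm") {
    la <- la + ref$cterm_acid
    lb <- lb + ref$cterm_base
    lw <- lw + ref$cterm_base
  }
  scale_a <- exp(-(ref$Ea_acid / R) * (1 / temp - 1 / ref$T_ref))
  scale_b <- exp(-(ref$Ea_base / R) * (1 / temp - 1 / ref$T_ref))
  scale_w <- exp(-(ref$Ea_water / R) * (1 / temp - 1 / ref$T_ref))
  (10^la * scale_a + 10^lb * scale_b + 10^lw * scale_w) / 60
}

# Dihedral via the plane-normal atan2 construction (sign from the triple
# product with the central bond), independent of the package kernel.
oracle_dihedral <- function(p1, p2, p3, p4) {
  v <- function(a, b) b - a
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- v(p1, p2); b2 <- v(p2, p3); b3 <- v(p3, p4)
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# brute-force mass-weighted averaging for COM checks
oracle_com <- function(xyz, m = rep(1, nrow(xyz))) {
  c(sum(xyz[, 1] * m), sum(xyz[, 2] * m), sum(xyz[, 3] * m)) / sum(m)
}

random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(Q = q, t = rnorm(3, 0, 20))
}

apply_rigid <- function(frames, Q, tr) {
  xyz <- cbind(frames$x, frames$y, frames$z) %*% t(Q)
  frames$x <- xyz[, 1] + tr[1]
  frames$y <- xyz[, 2] + tr[2]
  frames$z <- xyz[, 3] + tr[3]
  frames
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps), tol)
}
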