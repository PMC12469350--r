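# Synthetic-data generators. Each returns list(data = <input table(s)>,
# truth = <manifest>) where truth records the seed and every generating
# parameter, so each paired analysis stage can be checked against ground
# truth. Defaults reproduce the study conditions that the analyses model:
# HSQC intensity decays sampled every 10 min over 1000 min, the printed
# relaxation delay schedules, Gdn-HCl curves with dG = 3.83 kcal/mol and
# Cm = 3.7 M, melts/thermograms at the printed Tm and enthalpy values,
# Ca2+ ladder 0-30 mM and Mn2+ ladder 0-0.1 mM.

default_hdx_residues <- function(n, sequence) {
  aa <- strsplit(sequence, "")[[1]]
  # interior residues only: termini exchange near the random-coil limit
  candidates <- setdiff(which(aa != "P"), c(1L, 2L, length(aa)))
  candidates[round(seq(1, length(candidates), length.out = n))]
}

#' Generate H/D exchange decay tables
#'
#' Per-residue mono-exponential decays `I0 exp(-k t) + C` with Gaussian
#' noise. Rates can be given directly or derived from target `logP`
#' values via the residue's intrinsic rate (`k = k_rc 10^-logP`).
#'
#' @param n_residues Number of residues (ignored when `residues` given).
#' @param residues Residue indices into `sequence`.
#' @param logP True protection factors (log10); recycled. Used unless
#'   `rates` is given.
#' @param rates True exchange rates in s^-1 (within 1e-7 to 1e-2).
#' @param schedule_min Sampling times in minutes (default every 10 min to
#'   1000 min).
#' @param I0,C0 Amplitude and plateau.
#' @param sigma Gaussian noise sd (intensity units; default 2% of `I0`).
#' @param sequence,pD,temperature Conditions for the intrinsic rates.
#' @param seed Integer seed.
#' @return `list(data, truth)`; `data` has columns
#'   `(residue, aa, t, y)` with `t` in seconds.
#' @export
gen_hdx <- function(n_residues = 12, residues = NULL, logP = c(3, 3.5, 4, 4.2, 4.4, 4.6),
                    rates = NULL, schedule_min = seq(0, 1000, by = 10),
                    I0 = 1, C0 = 0.1, sigma = 0.02,
                    sequence = acp_sequence(), pD = 6.5, temperature = 298.15,
                    seed = 1) {
  aa_all <- strsplit(sequence, "")[[1]]
  if (is.null(residues)) residues <- default_hdx_residues(n_residues, sequence)
  aa <- aa_all[residues]
  krc <- intrinsic_rates(sequence, pD = pD, temperature = temperature)
  krc <- krc$k_rc[match(residues, krc$residue)]
  if (is.null(rates)) {
    logP <- rep_len(logP, length(residues))
    rates <- krc * 10^(-logP)
  } else {
    rates <- rep_len(rates, length(residues))
    logP <- log10(krc / rates)
  }
  if (any(rates < 1e-7 | rates > 1e-2)) {
    abort("gen_hdx: rates outside [1e-7, 1e-2] s^-1")
  }
  t_s <- schedule_min * 60
  data <- with_seed(child_seed(seed, "hdx"), {
    bind_rows(lapply(seq_along(residues), function(i) {
      y <- I0 * exp(-rates[i] * t_s) + C0
      tibble(residue = residues[i], aa = aa[i], t = t_s,
             y = y + stats::rnorm(length(t_s), 0, sigma))
    }))
  })
  truth <- list(seed = seed, residues = residues, aa = aa, rates = rates,
                k_rc = krc, logP = logP,
                dG_local = log(10) * R_KCAL * temperature * logP,
                I0 = I0, C = C0, sigma = sigma, pD = pD,
                temperature = temperature, schedule_min = schedule_min)
  list(data = data, truth = truth)
}

#' Generate a chemical denaturation curve
#'
#' @param dG_H2O,m_value Two-state LEM truth (defaults 3.83 kcal/mol and
#'   3.83/3.7, i.e. midpoint 3.7 M).
#' @param aN,bN,aU,bU Baselines.
#' @param D Denaturant grid, M.
#' @param sigma Noise sd as a fraction of the baseline span at zero
#'   denaturant (default 0.01).
#' @param temperature Kelvin.
#' @param seed Integer seed.
#' @return `list(data, truth)`; `data` has columns `(D, y)`.
#' @export
gen_denaturation <- function(dG_H2O = 3.83, m_value = 3.83 / 3.7,
                             aN = 1, bN = -0.005, aU = 0.05, bU = 0.004,
                             D = seq(0, 6.5, length.out = 27), sigma = 0.01,
                             temperature = 298.15, seed = 1) {
  if (m_value <= 0) abort("gen_denaturation: m must be positive")
  span <- abs(aN - aU)
  y <- lem_signal(D, dG_H2O, m_value, aN, bN, aU, bU, temperature)
  data <- with_seed(child_seed(seed, "denat"), {
    tibble(D = D, y = y + stats::rnorm(length(D), 0, sigma * span))
  })
  truth <- list(seed = seed, dG_H2O = dG_H2O, m_value = m_value,
                Cm = dG_H2O / m_value, aN = aN, bN = bN, aU = aU, bU = bU,
                sigma = sigma, temperature = temperature)
  list(data = data, truth = truth)
}

#' Generate a CD thermal melt
#'
#' @param Tm_C Midpoint in Celsius (default 67.4, the calcium-stabilized
#'   condition).
#' @param dH_vH van 't Hoff enthalpy, kcal/mol.
#' @param aN,bN,aU,bU Baselines (vs Kelvin).
#' @param T_C Temperature grid in Celsius.
#' @param sigma Noise sd as fraction of baseline span.
#' @param seed Integer seed.
#' @return `list(data, truth)`; `data` has `(T, y)` with `T` in Kelvin.
#' @export
gen_melt <- function(Tm_C = 67.4, dH_vH = 60, aN = -12, bN = 0.01,
                     aU = -2, bU = 0.005, T_C = seq(25, 100, length.out = 51),
                     sigma = 0.01, seed = 1) {
  Tm <- Tm_C + 273.15
  Tk <- T_C + 273.15
  span <- abs(aN - aU)
  y <- melt_signal(Tk, Tm, dH_vH, aN, bN, aU, bU)
  data <- with_seed(child_seed(seed, "melt"), {
    tibble(T = Tk, y = y + stats::rnorm(length(Tk), 0, sigma * span))
  })
  truth <- list(seed = seed, Tm = Tm, Tm_C = Tm_C, dH_vH = dH_vH,
                aN = aN, bN = bN, aU = aU, bU = bU, sigma = sigma)
  list(data = data, truth = truth)
}

#' Generate a DSC thermogram
#'
#' Two-state excess heat-capacity peak plus a linear instrumental
#' baseline (and optional unfolding heat-capacity step weighted by the
#' transition progress).
#'
#' @param Tm_C Peak position in Celsius (default 66.4).
#' @param dH_vH,dH_cal van 't Hoff and calorimetric enthalpies, kcal/mol
#'   (defaults 71.2 both).
#' @param base_a,base_b Linear baseline.
#' @param dCp Heat-capacity step across the transition (kcal/mol/K).
#' @param T_C Temperature grid in Celsius (default 20-100 at 0.2).
#' @param sigma Absolute noise sd on Cp.
#' @param seed Integer seed.
#' @return `list(data, truth)`; `data` has `(T, y)` with `T` in Kelvin,
#'   `y` in kcal/mol/K.
#' @export
gen_dsc <- function(Tm_C = 66.4, dH_vH = 71.2, dH_cal = 71.2,
                    base_a = 0.5, base_b = 0, dCp = 0,
                    T_C = seq(20, 100, by = 0.2), sigma = 0, seed = 1) {
  Tm <- Tm_C + 273.15
  Tk <- T_C + 273.15
  exc <- dsc_excess_model(Tk, Tm, dH_vH, dH_cal)
  K <- exp(-(dH_vH / R_KCAL) * (1 / Tk - 1 / Tm))
  alpha <- K / (1 + K)
  y <- base_a + base_b * Tk + dCp * alpha + exc
  data <- with_seed(child_seed(seed, "dsc"), {
    tibble(T = Tk, y = y + stats::rnorm(length(Tk), 0, sigma))
  })
  truth <- list(seed = seed, Tm = Tm, Tm_C = Tm_C, dH_vH = dH_vH,
                dH_cal = dH_cal, Cp_max = dH_cal * dH_vH / (4 * R_KCAL * Tm^2),
                base_a = base_a, base_b = base_b, dCp = dCp, sigma = sigma)
  list(data = data, truth = truth)
}

base_shift_table <- function(residues, aa, seed) {
  with_seed(child_seed(seed, "shifts-ref"), {
    tibble(residue = residues, aa = aa,
           dH = stats::runif(length(residues), 7.5, 9.5),
           dN = stats::runif(length(residues), 105, 130),
           intensity = stats::runif(length(residues), 0.5, 1.5) * 1e6)
  })
}

#' Generate paired reference/perturbed shift tables
#'
#' Designated site residues receive a deterministic shift perturbation;
#' all residues receive Gaussian shift noise. Glycines from the sequence
#' are present so the glycine CSP weighting is exercised.
#'
#' @param n_residues Number of residues (taken in order from `sequence`,
#'   skipping residue 1 and prolines).
#' @param site_residues Residue indices that are truly perturbed.
#' @param ddH,ddN Perturbation sizes (ppm) applied at site residues.
#' @param sigma_H,sigma_N Shift noise sd (ppm).
#' @param sequence Protein sequence.
#' @param seed Integer seed.
#' @return `list(data = list(ref, state), truth)`.
#' @export
gen_shift_tables <- function(n_residues = 40, site_residues = c(30, 35, 38),
                             ddH = 0.12, ddN = 0.8,
                             sigma_H = 0.002, sigma_N = 0.01,
                             sequence = acp_sequence(), seed = 1) {
  aa_all <- strsplit(sequence, "")[[1]]
  residues <- head(setdiff(which(aa_all != "P"), 1L), n_residues)
  if (!all(site_residues %in% residues)) {
    abort("gen_shift_tables: site residues outside the residue range")
  }
  aa <- aa_all[residues]
  ref <- base_shift_table(residues, aa, seed)
  state <- with_seed(child_seed(seed, "shifts-state"), {
    is_site <- residues %in% site_residues
    mutate(ref,
           dH = .data$dH + ifelse(is_site, ddH, 0) +
             stats::rnorm(length(residues), 0, sigma_H),
           dN = .data$dN + ifelse(is_site, ddN, 0) +
             stats::rnorm(length(residues), 0, sigma_N))
  })
  alpha <- ifelse(aa_all[site_residues] == "G", 0.14, 0.2)
  truth <- list(seed = seed, residues = residues, site_residues = site_residues,
                ddH = ddH, ddN = ddN,
                site_csp = sqrt(0.5 * (ddH^2 + (alpha * ddN)^2)),
                sigma_H = sigma_H, sigma_N = sigma_N)
  list(data = list(ref = ref, state = state), truth = truth)
}

#' Generate a fast-exchange metal titration series
#'
#' Two-site fast exchange: at ligand concentration `c` the observed shift
#' is the population-weighted average, `delta(c) = delta_free +
#' f_b(c) * delta_bound_shift` with `f_b = c / (c + Kd)` (ligand in
#' excess). Site residues carry the bound-state perturbation; all states
#' get independent shift noise.
#'
#' @param concentrations Ladder in mM, starting at 0 (default the Ca2+
#'   ladder 0, 0.5, 1, 2, 5, 10, 20, 30 mM).
#' @param Kd Dissociation constant, mM.
#' @param site_residues,ddH,ddN Bound-state perturbation at site residues.
#' @param n_residues,sequence,sigma_H,sigma_N,seed As in
#'   [gen_shift_tables()].
#' @return `list(data = list of state tables, concentrations, truth)`.
#' @export
gen_titration_states <- function(concentrations = c(0, 0.5, 1, 2, 5, 10, 20, 30),
                                 Kd = 2, site_residues = c(30, 35, 38, 47, 51, 56),
                                 ddH = 0.15, ddN = 1.0, n_residues = 60,
                                 sigma_H = 0, sigma_N = 0,
                                 sequence = acp_sequence(), seed = 1) {
  aa_all <- strsplit(sequence, "")[[1]]
  residues <- head(setdiff(which(aa_all != "P"), 1L), n_residues)
  if (!all(site_residues %in% residues)) {
    abort("gen_titration_states: site residues outside the residue range")
  }
  ref <- base_shift_table(residues, aa_all[residues], seed)
  is_site <- residues %in% site_residues
  states <- lapply(seq_along(concentrations), function(i) {
    fb <- concentrations[i] / (concentrations[i] + Kd)
    with_seed(child_seed(seed, paste0("titr-", i)), {
      mutate(ref,
             dH = .data$dH + ifelse(is_site, fb * ddH, 0) +
               stats::rnorm(length(residues), 0, sigma_H),
             dN = .data$dN + ifelse(is_site, fb * ddN, 0) +
               stats::rnorm(length(residues), 0, sigma_N))
    })
  })
  alpha <- ifelse(aa_all[site_residues] == "G", 0.14, 0.2)
  truth <- list(seed = seed, Kd = Kd, residues = residues,
                site_residues = site_residues, ddH = ddH, ddN = ddN,
                bound_csp = sqrt(0.5 * (ddH^2 + (alpha * ddN)^2)),
                fb = concentrations / (concentrations + Kd))
  list(data = states, concentrations = concentrations, truth = truth)
}

#' Generate paramagnetic attenuation spectra
#'
#' Distance-dependent intensity attenuation under a paramagnetic ion:
#' `I(c) = I(0) exp(-c * lambda_i)` with `lambda_i` proportional to
#' `r_i^-6` for the residue's distance `r_i` from the metal site. Peaks
#' falling below the detection floor are removed (intensity `NA`).
#'
#' @param concentrations Ladder in mM (default the Mn2+ ladder).
#' @param distances Named numeric: per-residue distance to the metal, in
#'   Angstrom (names are residue indices); unspecified residues default
#'   to 25 A.
#' @param lambda0 Attenuation constant at 10 A, per mM.
#' @param detection_floor Fraction of reference intensity below which a
#'   peak vanishes.
#' @param n_residues,sequence,seed As elsewhere.
#' @return `list(data = list of peak tables, concentrations, truth)`.
#' @export
gen_paramagnetic <- function(concentrations = c(0, 0.001, 0.005, 0.01, 0.02, 0.05, 0.1),
                             distances = c(`30` = 8, `35` = 6, `38` = 7,
                                           `47` = 6.5, `51` = 6, `56` = 7.5),
                             lambda0 = 50, detection_floor = 0.02,
                             n_residues = 60, sequence = acp_sequence(), seed = 1) {
  aa_all <- strsplit(sequence, "")[[1]]
  residues <- head(setdiff(which(aa_all != "P"), 1L), n_residues)
  ref <- base_shift_table(residues, aa_all[residues], seed)
  r <- rep(25, length(residues))
  named <- as.integer(names(distances))
  r[match(named, residues)] <- unname(distances)
  lambda <- lambda0 * (10 / r)^6
  states <- lapply(concentrations, function(cc) {
    att <- exp(-cc * lambda)
    mutate(ref, intensity = ifelse(att < detection_floor, NA_real_,
                                   .data$intensity * att))
  })
  truth <- list(seed = seed, residues = residues, distances = r,
                lambda = lambda, detection_floor = detection_floor)
  list(data = states, concentrations = concentrations, truth = truth)
}

#' Generate relaxation decay tables
#'
#' @param rates Named or plain numeric vector of true rates (s^-1), one
#'   per residue.
#' @param residues Residue indices (default 2, 3, ...).
#' @param kind `"R1"` or `"R2"` (selects the default delay schedule).
#' @param schedule Delay list in seconds (default [relaxation_delays()]).
#' @param I0 Amplitude.
#' @param sigma Noise sd as a fraction of `I0` (default 0.02).
#' @param sequence,seed As elsewhere.
#' @return `list(data, truth)`; `data` has `(residue, aa, tau, y)`.
#' @export
gen_relaxation <- function(rates, residues = NULL, kind = c("R2", "R1"),
                           schedule = NULL, I0 = 1, sigma = 0.02,
                           sequence = acp_sequence(), seed = 1) {
  kind <- match.arg(kind)
  if (is.null(schedule)) schedule <- relaxation_delays(kind)
  aa_all <- strsplit(sequence, "")[[1]]
  if (is.null(residues)) residues <- seq_along(rates) + 1L
  aa <- aa_all[residues]
  data <- with_seed(child_seed(seed, paste0("relax-", kind)), {
    bind_rows(lapply(seq_along(rates), function(i) {
      y <- I0 * exp(-rates[i] * schedule)
      tibble(residue = residues[i], aa = aa[i], tau = schedule,
             y = y + stats::rnorm(length(schedule), 0, sigma * I0))
    }))
  })
  truth <- list(seed = seed, residues = residues, rates = unname(rates),
                kind = kind, schedule = schedule, I0 = I0, sigma = sigma)
  list(data = data, truth = truth)
}

#' Generate paired saturated/unsaturated tables for hNOE
#'
#' @param hnoe_values True per-residue hNOE ratios.
#' @param residues Residue indices (default 2, 3, ...).
#' @param I_unsat Reference intensity.
#' @param sigma Intensity noise sd (absolute).
#' @param sequence,seed As elsewhere.
#' @return `list(data = list(sat, unsat), truth)`.
#' @export
gen_hnoe_tables <- function(hnoe_values, residues = NULL, I_unsat = 1,
                            sigma = 0, sequence = acp_sequence(), seed = 1) {
  aa_all <- strsplit(sequence, "")[[1]]
  if (is.null(residues)) residues <- seq_along(hnoe_values) + 1L
  aa <- aa_all[residues]
  out <- with_seed(child_seed(seed, "hnoe"), {
    unsat <- tibble(residue = residues, aa = aa,
                    intensity = I_unsat + stats::rnorm(length(residues), 0, sigma))
    sat <- tibble(residue = residues, aa = aa,
                  intensity = hnoe_values * I_unsat +
                    stats::rnorm(length(residues), 0, sigma))
    list(sat = sat, unsat = unsat)
  })
  list(data = out, truth = list(seed = seed, residues = residues,
                                hnoe = hnoe_values, sigma = sigma))
}

# rotation matrix from a seeded random orthonormal frame (det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# NeRF placement: position D given A, B, C with bond length l, angle
# B-C-D theta (deg), dihedral A-B-C-D phi (deg, IUPAC convention)
place_dihedral <- function(A, B, C, l, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- (C - B) / sqrt(sum((C - B)^2))
  ab <- (B - A) / sqrt(sum((B - A)^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + l * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

# exactly round(f * n) TRUEs, arranged by a seeded permutation
exact_schedule <- function(n, fraction) {
  k <- round(fraction * n)
  sample(c(rep(TRUE, k), rep(FALSE, n - k)))
}

#' Generate a coordinate trajectory with known switching and H-bonding
#'
#' Builds a small synthetic frame series: a chi1-bearing side chain whose
#' torsion follows a scheduled two-state sequence exactly; a donor/
#' acceptor pair whose distance crosses the hydrogen-bond cutoff with a
#' scheduled dwell fraction (exact frame counts at zero noise); and a
#' rigid five-atom template for radius-of-gyration checks. Each frame is
#' optionally subjected to a random rigid rotation + translation, which
#' leaves all internal metrics unchanged.
#'
#' @param n_frames Number of frames.
#' @param chi1_states Two (or more) state centers in degrees.
#' @param chi1_dwell Fraction of frames in the first state (ignored when
#'   `chi1_schedule` is given).
#' @param chi1_schedule Optional explicit per-frame state indices.
#' @param hbond_dwell Scheduled bonded fraction (default 0.4).
#' @param bonded_distance,unbonded_distance Donor-acceptor distances (A)
#'   in the bonded / broken states (straddling the 3.5 A cutoff).
#' @param sigma Gaussian positional noise on the H-bond distance (A).
#' @param rigid_motion Apply a random rigid transform per frame.
#' @param seed Integer seed.
#' @return `list(data = frames tibble, truth)`. The switching residue is
#'   residue 1 (Leu-like, atoms N/CA/CB/CG); the donor is residue 2 atom
#'   NE; the acceptor residue 3 atom O; the template residue 4 atoms
#'   T1-T5.
#' @export
gen_trajectory <- function(n_frames = 500, chi1_states = c(-70, -180),
                           chi1_dwell = 0.6, chi1_schedule = NULL,
                           hbond_dwell = 0.4, bonded_distance = 3.2,
                           unbonded_distance = 4.2, sigma = 0,
                           rigid_motion = TRUE, seed = 1) {
  if (hbond_dwell <= 0 || hbond_dwell >= 1) abort("gen_trajectory: dwell fraction outside (0,1)")
  out <- with_seed(child_seed(seed, "traj"), {
    if (is.null(chi1_schedule)) {
      in1 <- exact_schedule(n_frames, chi1_dwell)
      chi1_schedule <- ifelse(in1, 1L, 2L)
    }
    chi1_true <- chi1_states[chi1_schedule]
    hb <- exact_schedule(n_frames, hbond_dwell)
    d_hb <- ifelse(hb, bonded_distance, unbonded_distance) +
      stats::rnorm(n_frames, 0, sigma)

    N <- c(0, 0, 0); CA <- c(1.46, 0, 0)
    CB <- CA + 1.53 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
    template <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0.6, 1.1, 0),
                      c(0.6, 0.4, 1.0), c(0.6, 0.4, -1.0))
    frames <- lapply(seq_len(n_frames), function(f) {
      CG <- place_dihedral(N, CA, CB, 1.52, 114, chi1_true[f])
      donor <- c(10, 0, 0)
      acceptor <- donor + c(d_hb[f], 0, 0)
      xyz <- rbind(N, CA, CB, CG, donor, acceptor,
                   sweep(template, 2, c(20, 0, 0), `+`))
      if (rigid_motion) {
        Q <- random_rotation()
        tr <- stats::rnorm(3, 0, 10)
        xyz <- xyz %*% t(Q) + matrix(tr, nrow(xyz), 3, byrow = TRUE)
      }
      tibble(frame = f,
             residue = c(1L, 1L, 1L, 1L, 2L, 3L, rep(4L, 5)),
             atom = c("N", "CA", "CB", "CG", "NE", "O", paste0("T", 1:5)),
             x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3]))
    })
    list(data = bind_rows(frames), chi1_schedule = chi1_schedule, hb = hb,
         d_hb = d_hb)
  })
  transitions <- sum(diff(out$chi1_schedule) != 0)
  truth <- list(seed = seed, chi1_states = chi1_states,
                chi1_schedule = out$chi1_schedule,
                chi1_occupancy = tabulate(out$chi1_schedule,
                                          length(chi1_states)) / n_frames,
                chi1_transitions = transitions,
                hbond_dwell = hbond_dwell,
                hbond_occupancy = mean(out$hb),
                bonded_distance = bonded_distance,
                unbonded_distance = unbonded_distance, sigma = sigma)
  list(data = out$data, truth = truth)
}

#' Write a generated dataset and its truth manifest
#'
#' Serializes `gen$data` (a tibble or named list of tibbles) as CSV files
#' plus `truth.json`. Regeneration with the same seed is byte-identical.
#'
#' @param gen A generator result `list(data, truth, ...)`.
#' @param dir Output directory (created if needed).
#' @param stage File-name stem.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(gen, dir, stage = "stage") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- if (is.data.frame(gen$data)) setNames(list(gen$data), stage) else gen$data
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(gen$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
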