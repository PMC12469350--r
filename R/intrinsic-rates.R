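# Random-coil amide exchange parameterization (poly-DL-alanine reference
# with log-additive side-chain and terminal corrections, D2O/pD scale).
# Columns: acid/base corrections exerted by a side chain on its own amide
# (*_self) and on the amide of the following residue (*_next). Ionized
# side-chain forms are used for Asp/Glu (experiments are near pD 6.5);
# His uses the protonated-imidazole entries.
RC_CORRECTIONS <- local({
  m <- rbind(
    #      acid_self acid_next base_self base_next
    A = c( 0.00,  0.00,  0.00,  0.00),
    R = c(-0.59, -0.32,  0.08,  0.22),
    N = c(-0.58, -0.13,  0.49,  0.32),
    D = c( 0.90,  0.58, -0.30, -0.18),
    C = c(-0.54, -0.46,  0.62,  0.55),
    Q = c(-0.47, -0.27,  0.06,  0.20),
    E = c(-0.90,  0.31, -0.51, -0.15),
    G = c(-0.22,  0.22, -0.03,  0.17),
    H = c(-0.80, -0.51,  0.80,  0.83),
    I = c(-0.91, -0.59, -0.73, -0.23),
    L = c(-0.57, -0.13, -0.58, -0.21),
    K = c(-0.56, -0.29, -0.04,  0.12),
    M = c(-0.64, -0.28, -0.01,  0.11),
    F = c(-0.52, -0.43, -0.24,  0.06),
    P = c( 0.00, -0.19,  0.00, -0.24),
    S = c(-0.44, -0.39,  0.37,  0.30),
    T = c(-0.79, -0.47, -0.07,  0.20),
    W = c(-0.40, -0.44, -0.41, -0.11),
    Y = c(-0.41, -0.37, -0.27,  0.05),
    V = c(-0.74, -0.30, -0.70, -0.14)
  )
  colnames(m) <- c("acid_self", "acid_next", "base_self", "base_next")
  m
})

# Reference poly-alanine rates (log10, min^-1 scale with molar acid/base),
# deuteroxide pK, and Arrhenius activation energies (kcal/mol).
RC_REFERENCE <- list(
  log_kA = 1.62,    # acid-catalyzed, M^-1 min^-1
  log_kB = 10.05,   # base-catalyzed, M^-1 min^-1
  log_kW = -1.5,    # water-catalyzed, min^-1
  pKD = 15.05,
  T_ref = 293.15,
  Ea_acid = 14, Ea_base = 17, Ea_water = 19,
  # terminal-group corrections: free alpha-ammonium acting on the amide of
  # residue 2; C-terminal carboxylate acting on the final residue's amide
  nterm_acid = -1.32, nterm_base = 1.62,
  cterm_acid = 0.96,  cterm_base = -1.80
)

#' Intrinsic random-coil amide exchange rate
#'
#' Computes the intrinsic (unprotected) backbone-amide H/D exchange rate
#' for a residue in a random coil: acid-, base- and water-catalyzed terms
#' with log-additive corrections from the residue's own side chain and its
#' left (preceding) neighbor, optional terminal-group corrections, and
#' Arrhenius temperature scaling of each catalytic term. The right
#' neighbor is accepted for interface completeness; in this
#' parameterization the following side chain does not modulate the amide.
#'
#' @param aa One-letter code of the residue bearing the amide (`"P"` has
#'   no backbone amide and is rejected).
#' @param left,right One-letter codes of the preceding and following
#'   residues.
#' @param pD Corrected pH-meter reading in D2O (default 6.5 = meter 6.1
#'   plus the standard 0.4 glass-electrode correction).
#' @param temperature Kelvin (default 298.15).
#' @param position `"internal"`, `"nterm"` (residue 2, the first amide
#'   after the free alpha-ammonium) or `"cterm"` (final residue).
#' @return Rate in s^-1.
#' @export
#' @examples
#' intrinsic_rate("A", "A", "A")              # poly-alanine reference context
#' intrinsic_rate("I", "Y", "N", pD = 6.5)    # Ile72 in ...Y I N...
intrinsic_rate <- function(aa, left, right, pD = 6.5, temperature = 298.15,
                           position = c("internal", "nterm", "cterm")) {
  position <- match.arg(position)
  if (!(aa %in% AA_CODES) || !(left %in% AA_CODES) || !(right %in% AA_CODES)) {
    abort("intrinsic_rate: invalid one-letter amino-acid code")
  }
  if (aa == "P") abort("intrinsic_rate: proline has no backbone amide proton")
  if (pD < 1 || pD > 12) abort("intrinsic_rate: pD outside [1, 12]")
  if (temperature <= 273 || temperature >= 373) {
    abort("intrinsic_rate: temperature outside (273, 373) K")
  }
  p <- RC_REFERENCE
  lacid <- RC_CORRECTIONS[aa, "acid_self"] + RC_CORRECTIONS[left, "acid_next"]
  lbase <- RC_CORRECTIONS[aa, "base_self"] + RC_CORRECTIONS[left, "base_next"]
  if (position == "nterm") {
    lacid <- lacid + p$nterm_acid
    lbase <- lbase + p$nterm_base
  }
  if (position == "cterm") {
    lacid <- lacid + p$cterm_acid
    lbase <- lbase + p$cterm_base
  }
  arrh <- function(Ea) exp(-(Ea / R_KCAL) * (1 / temperature - 1 / p$T_ref))
  k_acid <- 10^(p$log_kA + lacid) * 10^(-pD) * arrh(p$Ea_acid)
  k_base <- 10^(p$log_kB + lbase) * 10^(pD - p$pKD) * arrh(p$Ea_base)
  k_water <- 10^(p$log_kW + lbase) * arrh(p$Ea_water)
  (k_acid + k_base + k_water) / 60  # min^-1 -> s^-1
}

#' Intrinsic rates along a protein sequence
#'
#' Vectorizes [intrinsic_rate()] over a full one-letter sequence, handling
#' terminal positions and skipping prolines and the first residue (whose
#' alpha-amine is not an amide).
#'
#' @param sequence One-letter protein sequence (character scalar).
#' @inheritParams intrinsic_rate
#' @return A tibble `(residue, aa, k_rc)` with rates in s^-1; residues
#'   without an observable backbone amide are omitted.
#' @export
intrinsic_rates <- function(sequence, pD = 6.5, temperature = 298.15) {
  aa <- strsplit(sequence, "")[[1]]
  assert_residue_ids(seq_along(aa), aa, "sequence")
  rows <- lapply(seq_along(aa), function(i) {
    if (i == 1 || aa[i] == "P") return(NULL)
    pos <- if (i == 2) "nterm" else if (i == length(aa)) "cterm" else "internal"
    right <- if (i == length(aa)) aa[i - 1] else aa[i + 1]
    k <- intrinsic_rate(aa[i], aa[i - 1], right, pD = pD,
                        temperature = temperature, position = pos)
    tibble(residue = i, aa = aa[i], k_rc = k)
  })
  bind_rows(rows)
}
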