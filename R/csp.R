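#' Weighted chemical-shift perturbation between two states
#'
#' Combined amide CSP per residue:
#' `dd = sqrt(0.5 * ((ddH)^2 + (alpha * ddN)^2))`, with the nitrogen
#' weight `alpha = 0.14` for glycine and `0.2` otherwise. The alternative
#' convention with the 1/2 factor outside the root
#' (`dd = 0.5 * sqrt((ddH)^2 + (alpha * ddN)^2)`) is available via
#' `half = "outside"`.
#'
#' @param ref,state Peak tables `(residue, aa, dH, dN, ...)` for the
#'   reference and perturbed states; residues are matched by index and
#'   must agree in type.
#' @param alpha,alpha_gly Nitrogen scalings for non-glycine / glycine.
#' @param half Where the 1/2 factor sits: `"inside"` (default) or
#'   `"outside"` the square root.
#' @return Tibble `(residue, aa, dd)` with `dd >= 0` in ppm, for residues
#'   present in both states.
#' @export
#' @examples
#' ref <- data.frame(residue = 1, aa = "L", dH = 8.0, dN = 120)
#' st  <- data.frame(residue = 1, aa = "L", dH = 8.1, dN = 120.5)
#' csp(ref, st)$dd  # 0.100 ppm
csp <- function(ref, state, alpha = 0.2, alpha_gly = 0.14,
                half = c("inside", "outside")) {
  half <- match.arg(half)
  require_columns(ref, c("residue", "aa", "dH", "dN"), "reference state")
  require_columns(state, c("residue", "aa", "dH", "dN"), "perturbed state")
  merged <- dplyr::inner_join(
    select(as_tibble(ref), "residue", "aa", ref_dH = "dH", ref_dN = "dN"),
    select(as_tibble(state), "residue", aa2 = "aa", dH = "dH", dN = "dN"),
    by = "residue"
  )
  if (any(merged$aa != merged$aa2)) {
    abort("csp: residue type mismatch between states")
  }
  a <- ifelse(merged$aa == "G", alpha_gly, alpha)
  ddH <- merged$dH - merged$ref_dH
  ddN <- merged$dN - merged$ref_dN
  dd <- if (half == "inside") {
    sqrt(0.5 * (ddH^2 + (a * ddN)^2))
  } else {
    0.5 * sqrt(ddH^2 + (a * ddN)^2)
  }
  tibble(residue = merged$residue, aa = merged$aa, dd = dd)
}

#' Flag significant chemical-shift perturbations
#'
#' Marks residues whose CSP strictly exceeds the mean plus one sample
#' standard deviation (n-1 denominator) of all finite CSPs — the
#' customary bar-plot threshold. Missing values are excluded from the
#' statistics and never flagged.
#'
#' @param records Tibble with a `dd` column (>= 3 finite values).
#' @return The input with a logical `significant` column; the threshold
#'   is attached as attribute `threshold`.
#' @export
significance_flags <- function(records) {
  require_columns(records, "dd", "CSP records")
  dd <- records$dd[is.finite(records$dd)]
  if (length(dd) < 3) abort("significance_flags: need >= 3 finite CSP values")
  thr <- mean(dd) + sd(dd)
  out <- mutate(as_tibble(records),
                significant = is.finite(.data$dd) & .data$dd > thr)
  attr(out, "threshold") <- thr
  out
}

#' Paramagnetic intensity ratios
#'
#' Normalizes peak intensities of a metal-added spectrum against the
#' metal-free reference, residue by residue: `ratio = I(c) / I(0)`. A
#' residue whose peak has vanished under the paramagnetic ion (absent
#' from the metal spectrum) receives ratio 0 — the broadening-beyond-
#' detection convention. Residues absent from the reference are excluded
#' with a warning.
#'
#' @param ref Reference peak table `(residue, aa, intensity)`, intensities
#'   positive.
#' @param plus_metal Peak table in the presence of the paramagnetic ion;
#'   missing residues and `NA` intensities are treated as vanished peaks.
#' @return Tibble `(residue, aa, ratio)`.
#' @export
paramagnetic_ratio <- function(ref, plus_metal) {
  require_columns(ref, c("residue", "aa", "intensity"), "reference")
  require_columns(plus_metal, c("residue", "intensity"), "metal spectrum")
  ref <- as_tibble(ref)
  drop <- !is.finite(ref$intensity) | ref$intensity <= 0
  if (any(drop)) {
    warn(sprintf("paramagnetic_ratio: excluding %d residue(s) absent from the reference spectrum",
                 sum(drop)))
    ref <- ref[!drop, ]
  }
  merged <- left_join(select(ref, "residue", "aa", ref_int = "intensity"),
                      select(as_tibble(plus_metal), "residue", met_int = "intensity"),
                      by = "residue")
  ratio <- ifelse(is.finite(merged$met_int), merged$met_int / merged$ref_int, 0)
  tibble(residue = merged$residue, aa = merged$aa, ratio = ratio)
}

#' Titration CSP trajectories
#'
#' Computes per-residue CSPs of each titration point against the
#' zero-concentration reference (the first state) and a per-residue
#' Spearman monotonicity score of CSP against concentration.
#'
#' @param states Ordered list of peak tables `(residue, aa, dH, dN)`,
#'   first element the reference at concentration 0.
#' @param concentrations Numeric vector matching `states`, starting at 0
#'   and increasing.
#' @param ... Passed to [csp()].
#' @return A list with `profile` — tibble `(residue, aa, concentration,
#'   dd)` — and `monotonicity` — tibble `(residue, aa, spearman)`.
#' @export
titration_trajectory <- function(states, concentrations, ...) {
  if (length(states) != length(concentrations)) {
    abort("titration_trajectory: states and concentrations differ in length")
  }
  if (concentrations[1] != 0 || is.unsorted(concentrations, strictly = TRUE)) {
    abort("titration_trajectory: concentrations must start at 0 and increase")
  }
  ref <- states[[1]]
  prof <- bind_rows(lapply(seq_along(states), function(i) {
    mutate(csp(ref, states[[i]], ...), concentration = concentrations[i])
  }))
  prof <- select(prof, "residue", "aa", "concentration", "dd")
  mono <- prof |>
    group_by(.data$residue, .data$aa) |>
    summarise(spearman = if (sd(.data$dd) > 0) {
      suppressWarnings(cor(.data$concentration, .data$dd, method = "spearman"))
    } else NA_real_, .groups = "drop")
  list(profile = prof, monotonicity = mono)
}
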