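#' Packaged relaxation delay schedules
#'
#' Default inversion-recovery (R1) and CPMG-type (R2) delay lists used by
#' the synthetic-data generator, in seconds, including the duplicate
#' delays used for noise estimation. The R2 list is reproduced verbatim
#' from the acquisition schedule it models; two of its entries break the
#' otherwise monotone spacing, an anomaly of the printed schedule that is
#' kept as-is (fits do not require sorted delays).
#'
#' @param kind `"R1"` or `"R2"`.
#' @return Numeric vector of delays (s).
#' @export
#' @examples
#' relaxation_delays("R1")
relaxation_delays <- function(kind = c("R1", "R2")) {
  kind <- match.arg(kind)
  switch(kind,
    R1 = c(0.01, 0.01, 0.05, 0.1, 0.2, 0.3, 0.3, 0.5, 0.8, 1.2),
    R2 = c(0, 0, 0.01696, 0.03392, 0.05088, 0.05088, 0.0848,
           0.013568, 0.022048, 0.32224)
  )
}

# rms of paired differences at duplicated delays, divided by sqrt(2)
duplicate_sigma <- function(tau, y) {
  d2 <- c()
  for (u in unique(tau)) {
    idx <- which(tau == u)
    if (length(idx) >= 2) {
      pairs <- utils::combn(idx, 2)
      d2 <- c(d2, (y[pairs[1, ]] - y[pairs[2, ]])^2)
    }
  }
  if (length(d2) == 0) return(NA_real_)
  sqrt(mean(d2) / 2)
}

#' Fit a mono-exponential relaxation decay
#'
#' Fits `I(tau) = I0 * exp(-rate * tau)` (no plateau, the standard model
#' for R1/R2 peak-height decays; set `plateau = TRUE` if baselines demand
#' one). Per-point noise is estimated as the rms of paired differences at
#' duplicated delays divided by sqrt(2), and the rate standard error is
#' the covariance-based error rescaled to that noise estimate.
#'
#' @param data Data frame with delay column `tau` (or `t`/`x`, seconds)
#'   and intensity `y`; at least 6 delays, duplicates permitted and used.
#' @param kind `"R1"` or `"R2"` (label only).
#' @param residue,aa Optional labels.
#' @param plateau Include an additive plateau term (default `FALSE`).
#' @return Object of class `relaxation_fit`: `rate` (s^-1), `rate_err`,
#'   `I0`, `sigma` (duplicate-based noise), `kind`, labels, `n`.
#' @export
fit_relaxation <- function(data, kind = c("R1", "R2"),
                           residue = NA_integer_, aa = NA_character_,
                           plateau = FALSE) {
  kind <- match.arg(kind)
  tcol <- intersect(c("tau", "t", "x"), names(data))[1]
  if (is.na(tcol)) abort("fit_relaxation: no delay column (tau/t/x)")
  tau <- as.numeric(data[[tcol]]); y <- as.numeric(data$y)
  ok <- is.finite(tau) & is.finite(y)
  tau <- tau[ok]; y <- y[ok]
  if (length(tau) < 6) abort(sprintf("relaxation fit (residue %s): need >= 6 delays", residue))
  if (length(unique(tau)) < 3) {
    abort(sprintf("relaxation fit (residue %s): too few distinct delays", residue))
  }
  starts <- lapply(c(0.5, 2, 8, 20), function(r) {
    list(I0 = max(abs(y)), k = r, C = 0)
  })
  best <- run_exp_multistart(tau, y, starts, plateau = plateau)
  if (is.null(best)) abort(sprintf("relaxation fit did not converge for residue %s", residue))
  cf <- coef(best$fit)
  rate <- unname(cf[["k"]])
  if (rate <= 0) abort(sprintf("relaxation fit (residue %s): non-positive rate", residue))
  sigma <- duplicate_sigma(tau, y)
  se_fit <- tryCatch(summary(best$fit)$coefficients["k", "Std. Error"],
                     error = function(e) NA_real_)
  sigma_fit <- tryCatch(summary(best$fit)$sigma, error = function(e) NA_real_)
  rate_err <- if (is.finite(sigma) && is.finite(sigma_fit) && sigma_fit > 0) {
    se_fit / sigma_fit * sigma
  } else se_fit
  structure(list(
    residue = residue, aa = aa, kind = kind,
    rate = rate, rate_err = rate_err,
    I0 = unname(cf[["I0"]]), sigma = sigma,
    n = length(tau), sse = best$sse
  ), class = "relaxation_fit")
}

#' Fit relaxation decays for every residue in a long table
#'
#' @param data Long-format tibble `(residue, aa, tau, y)`.
#' @inheritParams fit_relaxation
#' @return Tibble `(residue, aa, kind, rate, rate_err, sigma)`.
#' @export
fit_relaxation_set <- function(data, kind = c("R1", "R2"), plateau = FALSE) {
  kind <- match.arg(kind)
  require_columns(data, c("residue", "aa", "y"), "relaxation table")
  bind_rows(lapply(split(data, data$residue), function(g) {
    tidy(fit_relaxation(g, kind = kind, residue = g$residue[[1]],
                        aa = g$aa[[1]], plateau = plateau))
  }))
}

#' Heteronuclear NOE ratios
#'
#' `hNOE = I_sat / I_unsat` per residue, from paired saturated and
#' unsaturated peak tables, with first-order error propagation from a
#' per-spectrum intensity noise estimate. Negative saturated intensities
#' pass through (flexible termini can invert the NOE). Residues missing
#' from either spectrum are excluded with a warning.
#'
#' @param sat,unsat Peak tables `(residue, aa, intensity)`.
#' @param sigma Intensity noise (same units as intensities); used for the
#'   error column. Default `NA` (errors reported as `NA`).
#' @return Tibble `(residue, aa, hnoe, err)`.
#' @export
hnoe <- function(sat, unsat, sigma = NA_real_) {
  require_columns(sat, c("residue", "intensity"), "saturated spectrum")
  require_columns(unsat, c("residue", "aa", "intensity"), "unsaturated spectrum")
  merged <- dplyr::inner_join(
    select(as_tibble(unsat), "residue", "aa", I_unsat = "intensity"),
    select(as_tibble(sat), "residue", I_sat = "intensity"),
    by = "residue"
  )
  n_union <- length(union(unsat$residue, sat$residue))
  bad <- !is.finite(merged$I_unsat) | merged$I_unsat <= 0 | !is.finite(merged$I_sat)
  n_excluded <- n_union - nrow(merged) + sum(bad)
  if (n_excluded > 0) {
    warn(sprintf("hnoe: excluding %d residue(s) missing from one spectrum or with non-positive reference",
                 as.integer(n_excluded)))
    merged <- merged[!bad, ]
  }
  ratio <- merged$I_sat / merged$I_unsat
  err <- abs(ratio) * sqrt((sigma / merged$I_sat)^2 + (sigma / merged$I_unsat)^2)
  tibble(residue = merged$residue, aa = merged$aa, hnoe = ratio, err = err)
}

trimmed_stats <- function(x, trim = 0.05) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(trim, 1 - trim), names = FALSE, type = 7)
  xt <- x[x >= q[1] & x <= q[2]]
  list(mean = mean(xt), sd = sd(xt))
}

#' Classify dynamic residues from R2 and hNOE
#'
#' Threshold-based highlighting: residues are `exchange_broadened` where
#' R2 strictly exceeds the trimmed mean + sd, and `flexible` where hNOE
#' falls strictly below the trimmed mean - sd. Trimmed statistics exclude
#' the 5% tails on each side so that the outliers being sought do not
#' inflate their own threshold.
#'
#' @param r2 Tibble `(residue, rate)` from [fit_relaxation_set()].
#' @param hnoe_tbl Tibble `(residue, hnoe)` from [hnoe()].
#' @param trim Tail fraction excluded on each side (default 0.05).
#' @return Tibble `(residue, aa, R2, hnoe, exchange_broadened, flexible)`
#'   with thresholds attached as attributes `r2_threshold` and
#'   `hnoe_threshold`.
#' @export
classify_dynamics <- function(r2, hnoe_tbl, trim = 0.05) {
  require_columns(r2, c("residue", "rate"), "R2 table")
  require_columns(hnoe_tbl, c("residue", "hnoe"), "hNOE table")
  merged <- dplyr::inner_join(
    select(as_tibble(r2), "residue", dplyr::any_of("aa"), R2 = "rate"),
    select(as_tibble(hnoe_tbl), "residue", "hnoe"),
    by = "residue"
  )
  s_r2 <- trimmed_stats(merged$R2, trim)
  s_noe <- trimmed_stats(merged$hnoe, trim)
  thr_r2 <- s_r2$mean + s_r2$sd
  thr_noe <- s_noe$mean - s_noe$sd
  out <- mutate(merged,
                exchange_broadened = .data$R2 > thr_r2,
                flexible = .data$hnoe < thr_noe)
  attr(out, "r2_threshold") <- thr_r2
  attr(out, "hnoe_threshold") <- thr_noe
  arrange(out, .data$residue)
}
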