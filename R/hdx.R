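#' Fit a single-exponential H/D exchange decay
#'
#' Fits `I(t) = I0 * exp(-k_ex * t) + C` to one residue's amide-intensity
#' time series by nonlinear least squares with multi-start initialization
#' over `k` (1e-6 to 1e-3 s^-1 decades plus a log-linear heuristic),
#' tie-broken by lowest SSE. When the fitted decay over the observation
#' window is below 5% (`k_ex * t_max < 0.05`) the rate is not resolved;
#' the result is flagged `censored` and `k_ex` is replaced by the rate
#' producing exactly 5% decay over the window, an upper bound.
#'
#' @param data Data frame with time column `t` (seconds) and intensity
#'   column `y` (non-negative); at least 5 points.
#' @param residue,aa Optional labels carried into the result.
#' @return An object of class `exchange_fit`: a list with `residue`,
#'   `aa`, `I0`, `C`, `k_ex` (s^-1), `k_err`, `censored`, `sse`, `n`,
#'   and `t_max`. `tidy()` turns it into a one-row tibble.
#' @export
#' @examples
#' t <- seq(0, 60000, by = 600)
#' d <- data.frame(t = t, y = 1.0 * exp(-8.33e-5 * t) + 0.1)
#' fit_exchange_decay(d)$k_ex
fit_exchange_decay <- function(data, residue = NA_integer_, aa = NA_character_) {
  tcol <- if ("t" %in% names(data)) "t" else "x"
  require_columns(data, c(tcol, "y"), "exchange series")
  t <- as.numeric(data[[tcol]]); y <- as.numeric(data$y)
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 5) abort(sprintf("exchange fit (residue %s): need >= 5 points", residue))
  if (any(y < 0)) abort(sprintf("exchange fit (residue %s): negative intensities", residue))
  t_max <- max(t)

  starts <- exp_decay_starts(t, y, k_grid = c(1e-6, 1e-5, 1e-4, 1e-3))
  # physical bounds: the amplitude cannot exceed the initial-intensity
  # scale and the plateau is a non-negative intensity; without them a
  # barely-decaying series is degenerate (tiny k with huge I0 mimics a
  # straight line)
  best <- run_exp_multistart(t, y, starts, plateau = TRUE,
                             lower = c(I0 = 1e-12, k = 0, C = 0),
                             upper = c(I0 = 1.5 * max(y), k = Inf, C = max(y)))
  if (is.null(best)) {
    abort(sprintf("exchange fit did not converge for residue %s", residue))
  }
  cf <- coef(best$fit)
  k_hat <- unname(cf[["k"]])
  se <- tryCatch(summary(best$fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  # unresolved when the window sees < 5% decay, either because the rate is
  # too slow or because the fitted amplitude is negligible (flat series)
  amp_frac <- cf[["I0"]] * (1 - exp(-k_hat * t_max)) /
    max(cf[["I0"]] + abs(cf[["C"]]), .Machine$double.eps)
  censored <- (k_hat * t_max < 0.05) || (amp_frac < 0.05)
  if (censored) {
    k_hat <- -log(0.95) / t_max
    se <- NA_real_
  }
  structure(list(
    residue = residue, aa = aa,
    I0 = max(unname(cf[["I0"]]), .Machine$double.eps),
    C = unname(cf[["C"]]),
    k_ex = k_hat, k_err = se,
    censored = censored,
    sse = best$sse, n = length(t), t_max = t_max
  ), class = "exchange_fit")
}

# shared exponential-decay machinery (also used by relaxation fits)
exp_decay_starts <- function(t, y, k_grid) {
  span <- max(y) - min(y)
  c0 <- min(y)
  i0 <- max(span, 0.1 * max(abs(y), .Machine$double.eps))
  # log-linear heuristic on the upper half of the decay
  pos <- y - c0 > 0.05 * max(span, .Machine$double.eps)
  k_heur <- if (sum(pos) >= 3 && span > 0) {
    sl <- stats::coef(stats::lm(log(y[pos] - c0 + 1e-12 * i0) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -sl else NULL
  } else NULL
  lapply(unique(c(k_grid, k_heur)), function(k) list(I0 = i0, k = k, C = c0))
}

run_exp_multistart <- function(t, y, starts, plateau = TRUE,
                               lower = NULL, upper = NULL) {
  best <- NULL
  clamp <- function(s) {
    p <- unlist(s)[if (plateau) c("I0", "k", "C") else c("I0", "k")]
    # keep starts strictly interior: a start sitting on a bound makes the
    # scaled gradient singular
    if (!is.null(lower)) {
      lo <- ifelse(is.finite(lower), lower + 1e-6 * pmax(1, abs(lower)), lower)
      p <- pmax(p, lo)
    }
    if (!is.null(upper)) {
      up <- ifelse(is.finite(upper), upper - 1e-6 * pmax(1, abs(upper)), upper)
      p <- pmin(p, up)
    }
    as.list(p)
  }
  for (s in starts) {
    fit <- tryCatch({
      if (plateau) {
        minpack.lm::nlsLM(y ~ I0 * exp(-k * t) + C,
                          start = clamp(s),
                          lower = lower %||% c(I0 = 1e-12, k = 0, C = -Inf),
                          upper = upper %||% c(I0 = Inf, k = Inf, C = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(y ~ I0 * exp(-k * t),
                          start = clamp(s)[c("I0", "k")],
                          lower = (lower %||% c(I0 = 1e-12, k = 0))[c("I0", "k")],
                          upper = (upper %||% c(I0 = Inf, k = Inf))[c("I0", "k")],
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  best
}

#' Fit exchange decays for every residue in a long table
#'
#' @param data Long-format tibble `(residue, aa, t or x, y)` with time in
#'   seconds (use [read_series()] with `x_unit = "min"` for minute data).
#' @return A tibble with one row per residue: `residue, aa, I0, C, k_ex,
#'   k_err, censored`.
#' @export
fit_hdx <- function(data) {
  tcol <- if ("t" %in% names(data)) "t" else "x"
  require_columns(data, c("residue", "aa", tcol, "y"), "hdx table")
  groups <- split(data, data$residue)
  bind_rows(lapply(groups, function(g) {
    f <- fit_exchange_decay(g, residue = g$residue[[1]], aa = g$aa[[1]])
    tidy(f)
  }))
}

#' Protection factors and local unfolding free energies
#'
#' Combines fitted exchange rates (`k_prot`, identified with the fitted
#' `k_ex`) with intrinsic random-coil rates: `P = k_rc / k_prot`,
#' `logP = log10(P)`, and `dG_local = -R T ln(k_prot / k_rc) =
#' ln(10) R T logP` with `R` = 1.9872e-3 kcal mol^-1 K^-1. For censored
#' fits `k_ex` is an upper bound, so `logP` and `dG_local` are reported
#' as lower bounds (the `censored` flag is carried through).
#'
#' @param fits Tibble from [fit_hdx()] (or a single `exchange_fit`).
#' @param k_rc Tibble `(residue, k_rc)` (e.g. from [intrinsic_rates()])
#'   or a numeric vector aligned with `fits`.
#' @param temperature Kelvin.
#' @return Tibble `(residue, aa, k_ex, k_rc, P, logP, dG_local, censored)`.
#' @export
protection <- function(fits, k_rc, temperature = 298.15) {
  if (inherits(fits, "exchange_fit")) fits <- tidy(fits)
  require_columns(fits, c("residue", "k_ex", "censored"), "fits")
  if (is.data.frame(k_rc)) {
    require_columns(k_rc, c("residue", "k_rc"), "k_rc")
    fits <- left_join(fits, select(k_rc, "residue", "k_rc"), by = "residue")
  } else {
    fits$k_rc <- as.numeric(k_rc)
  }
  if (any(!is.finite(fits$k_rc) | fits$k_rc <= 0)) {
    abort("protection: k_rc must be positive for every residue")
  }
  if (any(fits$k_ex <= 0)) abort("protection: non-positive k_prot")
  mutate(fits,
         P = .data$k_rc / .data$k_ex,
         logP = log10(.data$P),
         dG_local = log(10) * R_KCAL * temperature * .data$logP,
         temperature = temperature)
}

#' End-to-end H/D exchange analysis
#'
#' Runs [fit_hdx()], computes intrinsic rates from the protein sequence,
#' and returns the per-residue protection table.
#'
#' @inheritParams fit_hdx
#' @param sequence One-letter protein sequence (defaults to mature E. coli
#'   ACP, [acp_sequence()]); residue indices in `data` index into it.
#' @param pD,temperature Exchange conditions (defaults: pD 6.5, 298.15 K).
#' @return See [protection()].
#' @export
hdx_analyze <- function(data, sequence = acp_sequence(), pD = 6.5,
                        temperature = 298.15) {
  fits <- fit_hdx(data)
  rates <- intrinsic_rates(sequence, pD = pD, temperature = temperature)
  missing <- setdiff(fits$residue, rates$residue)
  if (length(missing) > 0) {
    abort(sprintf("hdx_analyze: no intrinsic rate for residue(s) %s (first residue or proline?)",
                  paste(missing, collapse = ", ")))
  }
  protection(fits, rates, temperature = temperature)
}
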