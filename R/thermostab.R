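#' Two-state thermal melt model for CD ellipticity
#'
#' `dG(T) = dH_vH (1 - T/Tm)`, `f_U = 1 / (1 + exp(dG/RT))`, observed
#' signal `y = (aN + bN T)(1 - f_U) + (aU + bU T) f_U`. The van 't Hoff
#' enthalpy is a fitting auxiliary; the heat-capacity change of unfolding
#' is neglected (documented limitation).
#'
#' @param temperature Kelvin (vectorized).
#' @param Tm Midpoint temperature, K.
#' @param dH_vH van 't Hoff enthalpy, kcal mol^-1 (positive).
#' @param aN,bN,aU,bU Linear baseline parameters.
#' @return Signal value(s).
#' @export
melt_signal <- function(temperature, Tm, dH_vH, aN = 1, bN = 0, aU = 0, bU = 0) {
  fU <- melt_funfolded(temperature, Tm, dH_vH)
  (aN + bN * temperature) * (1 - fU) + (aU + bU * temperature) * fU
}

melt_funfolded <- function(temperature, Tm, dH_vH) {
  dG <- dH_vH * (1 - temperature / Tm)
  stats::plogis(-dG / (R_KCAL * temperature))
}

#' Fit a CD thermal melt
#'
#' Two-state fit of an ellipticity-vs-temperature curve (typically the
#' 222 nm channel of an alpha-helical protein) with linear native and
#' unfolded baselines, by multi-start nonlinear least squares.
#'
#' @param data Data frame with columns `T` (or `x`) and `y`; at least 10
#'   points bracketing the transition.
#' @param temperature_unit `"K"` or `"C"` for the input axis.
#' @return Object of class `melt_fit`: `Tm` (K), `dH_vH`, baselines,
#'   standard errors, `vcov`, `sse`, `n`, `data`. Methods: `tidy()`,
#'   `glance()`, `autoplot()`.
#' @export
fit_melt <- function(data, temperature_unit = c("K", "C")) {
  temperature_unit <- match.arg(temperature_unit)
  tcol <- if ("T" %in% names(data)) "T" else "x"
  require_columns(data, c(tcol, "y"), "melt curve")
  Tk <- as.numeric(data[[tcol]]); y <- as.numeric(data$y)
  if (temperature_unit == "C") Tk <- Tk + 273.15
  ok <- is.finite(Tk) & is.finite(y)
  Tk <- Tk[ok]; y <- y[ok]
  if (length(Tk) < 10) abort("fit_melt: need >= 10 points")

  span <- diff(range(Tk))
  grid <- two_state_grid_start(
    Tk, y, NA,
    mid_grid = seq(min(Tk) + 0.05 * span, max(Tk) - 0.05 * span, length.out = 25),
    slope_grid = c(30, 60, 100, 150),
    funfold = function(x, mid, slope, temp) melt_funfolded(x, mid, slope)
  )
  if (is.null(grid)) abort("fit_melt: transition not bracketed by the data")
  start <- grid$start
  names(start)[names(start) == "Cm"] <- "Tm"
  names(start)[names(start) == "m"] <- "dH"

  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ (aN + bN * Tk) * (1 - stats::plogis(-(dH * (1 - Tk / Tm)) / (R_KCAL * Tk))) +
      (aU + bU * Tk) * stats::plogis(-(dH * (1 - Tk / Tm)) / (R_KCAL * Tk)),
    start = start,
    lower = c(Tm = min(Tk), dH = 1, aN = -Inf, bN = -Inf, aU = -Inf, bU = -Inf),
    upper = c(Tm = max(Tk), dH = Inf, aN = Inf, bN = Inf, aU = Inf, bU = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  ), error = function(e) NULL)
  if (is.null(fit)) abort("fit_melt: nonlinear fit failed to converge")
  cf <- as.list(coef(fit))
  edge <- 0.02 * span
  if (cf$Tm <= min(Tk) + edge || cf$Tm >= max(Tk) - edge) {
    abort("fit_melt: transition not bracketed by the data")
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 6), names(coef(fit))))
  structure(list(
    Tm = cf$Tm, dH_vH = cf$dH,
    aN = cf$aN, bN = cf$bN, aU = cf$aU, bU = cf$bU,
    se = se, vcov = tryCatch(vcov(fit), error = function(e) NULL),
    sse = sum(stats::residuals(fit)^2), n = length(Tk),
    data = tibble(T = Tk, y = y)
  ), class = "melt_fit")
}

#' Baseline-subtract and integrate a DSC thermogram
#'
#' Subtracts a baseline from a heat-capacity thermogram and reports the
#' calorimetric enthalpy (trapezoidal integral of the excess heat
#' capacity over temperature), the peak excess heat capacity, and the
#' peak position Tm. Baselines: `"linear"` interpolates between straight
#' lines fitted to the pre- and post-transition segments (outer 15% of
#' the temperature range); `"progress"` (default) weights the two segment
#' lines by the integrated fractional progress of the transition,
#' iterated to self-consistency, which follows common DSC software
#' practice; `"none"` treats the input as already baseline-subtracted
#' and only integrates.
#'
#' @param data Data frame with columns `T` (or `x`) and `y` (`Cp`,
#'   kcal mol^-1 K^-1) on a monotone temperature grid.
#' @param baseline `"progress"`, `"linear"` or `"none"`.
#' @param temperature_unit `"K"` or `"C"`.
#' @return Object of class `dsc_result`: `Tm` (K, `NA` when no peak),
#'   `dH_cal` (kcal mol^-1), `Cp_max`, `baseline` descriptor, and the
#'   excess-heat-capacity table `excess` (`T`, `Cp_exc`).
#' @export
dsc_analyze <- function(data, baseline = c("progress", "linear", "none"),
                        temperature_unit = c("K", "C")) {
  baseline <- match.arg(baseline)
  temperature_unit <- match.arg(temperature_unit)
  tcol <- if ("T" %in% names(data)) "T" else "x"
  require_columns(data, c(tcol, "y"), "thermogram")
  Tk <- as.numeric(data[[tcol]]); y <- as.numeric(data$y)
  if (temperature_unit == "C") Tk <- Tk + 273.15
  o <- order(Tk); Tk <- Tk[o]; y <- y[o]
  n <- length(Tk)
  if (n < 10) abort("dsc_analyze: need >= 10 points")

  if (baseline == "none") {
    exc <- y
    T_on <- Tk[1]; T_off <- Tk[n]
  } else {
    fitline <- function(idx) {
      cf <- coef(stats::lm(y[idx] ~ Tk[idx]))
      cf[1] + cf[2] * Tk
    }
    seg <- max(3L, ceiling(0.15 * n))
    base_pre <- fitline(seq_len(seg)); base_post <- fitline(seq.int(n - seg + 1L, n))
    T_on <- Tk[seg]; T_off <- Tk[n - seg + 1L]
    # refine: locate the peak and its half-height width from the current
    # excess estimate, exclude +/- 5 half-widths (a two-state peak holds
    # < 0.1% of its height there), and refit the segment lines outside
    for (iter in 1:3) {
      wlin <- pmin(pmax((Tk - T_on) / max(T_off - T_on, .Machine$double.eps), 0), 1)
      exc0 <- y - ((1 - wlin) * base_pre + wlin * base_post)
      pk <- max(exc0)
      if (pk <= 0) break
      ip <- which.max(exc0)
      below <- exc0 < pk / 2
      lo_half <- if (any(below[seq_len(ip)])) max(which(below[seq_len(ip)])) else 1L
      up_rel <- which(below[seq.int(ip, n)])
      hi_half <- if (length(up_rel) > 0) ip + min(up_rel) - 1L else n
      w1 <- max(Tk[ip] - Tk[lo_half], diff(range(Tk)) / 50)
      w2 <- max(Tk[hi_half] - Tk[ip], diff(range(Tk)) / 50)
      keep <- max(5L, ceiling(0.08 * n))  # retain some anchor points per side
      T_on <- max(min(Tk[ip] - 5 * w1, Tk[n]), Tk[keep])
      T_off <- min(max(Tk[ip] + 5 * w2, Tk[1]), Tk[n - keep + 1L])
      pre_idx <- which(Tk < T_on); post_idx <- which(Tk > T_off)
      if (length(pre_idx) >= 5) base_pre <- fitline(pre_idx)
      if (length(post_idx) >= 5) base_post <- fitline(post_idx)
    }
    wlin <- pmin(pmax((Tk - T_on) / max(T_off - T_on, .Machine$double.eps), 0), 1)
    base <- (1 - wlin) * base_pre + wlin * base_post
    if (baseline == "progress") {
      for (iter in 1:8) {
        exc <- pmax(y - base, 0)
        area <- cumtrapz(Tk, exc)
        alpha <- if (max(area) > 0) area / max(area) else wlin
        base <- (1 - alpha) * base_pre + alpha * base_post
      }
    }
    exc <- y - base
  }
  dH <- trapz(Tk, exc)
  peak <- max(exc)
  scale <- max(abs(y), 1e-12)
  win <- which(Tk > T_on & Tk < T_off)
  if (length(win) > 0 && mean(exc[win] < -1e-8 * scale) > 0.5) {
    abort("dsc_analyze: negative excess heat capacity over most of the transition (baseline misfit)")
  }
  if (-min(exc) > 1e-3 * scale && -min(exc) > peak) {
    abort("dsc_analyze: negative excess heat capacity over most of the transition (baseline misfit)")
  }
  if (peak <= 1e-8 * scale) {
    return(structure(list(Tm = NA_real_, dH_cal = 0, Cp_max = 0,
                          baseline = baseline,
                          excess = tibble(T = Tk, Cp_exc = exc)),
                     class = "dsc_result"))
  }
  structure(list(
    Tm = Tk[which.max(exc)], dH_cal = dH, Cp_max = peak,
    baseline = baseline,
    excess = tibble(T = Tk, Cp_exc = exc)
  ), class = "dsc_result")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))

#' Two-state excess heat capacity model
#'
#' `Cp_exc(T) = dH_cal dH_vH K / (R T^2 (1 + K)^2)` with
#' `K = exp(-(dH_vH/R)(1/T - 1/Tm))`. At `T = Tm`, `K = 1` and the peak
#' height is `dH_cal dH_vH / (4 R Tm^2)`.
#'
#' @param temperature Kelvin (vectorized).
#' @param Tm Midpoint, K.
#' @param dH_vH van 't Hoff enthalpy, kcal mol^-1.
#' @param dH_cal Calorimetric enthalpy, kcal mol^-1.
#' @return Excess heat capacity, kcal mol^-1 K^-1.
#' @export
dsc_excess_model <- function(temperature, Tm, dH_vH, dH_cal) {
  K <- exp(-(dH_vH / R_KCAL) * (1 / temperature - 1 / Tm))
  dH_cal * dH_vH * K / (R_KCAL * temperature^2 * (1 + K)^2)
}

#' Fit the two-state model to a baseline-subtracted DSC peak
#'
#' @param data Data frame with columns `T` (or `x`, Kelvin) and `y`
#'   (excess heat capacity, kcal mol^-1 K^-1).
#' @param drift Also fit a residual linear offset `c0 + c1 T`, absorbing
#'   imperfections left by the upstream baseline subtraction (default
#'   `FALSE`: pure two-state model).
#' @return Object of class `dsc_fit` with `Tm`, `dH_vH`, `dH_cal`,
#'   standard errors, `sse`, `n`, `data`.
#' @export
dsc_two_state_fit <- function(data, drift = FALSE) {
  tcol <- if ("T" %in% names(data)) "T" else "x"
  require_columns(data, c(tcol, "y"), "excess Cp")
  Tk <- as.numeric(data[[tcol]]); y <- as.numeric(data$y)
  o <- order(Tk); Tk <- Tk[o]; y <- y[o]
  Tm0 <- Tk[which.max(y)]
  area0 <- max(trapz(Tk, pmax(y, 0)), 1e-6)
  dHvH0 <- max(4 * R_KCAL * Tm0^2 * max(y) / area0, 5)
  fit <- tryCatch(if (drift) {
    minpack.lm::nlsLM(
      y ~ dsc_excess_model(Tk, Tm, dHvH, dHcal) + c0 + c1 * (Tk - Tm0),
      start = list(Tm = Tm0, dHvH = dHvH0, dHcal = area0, c0 = 0, c1 = 0),
      lower = c(Tm = min(Tk), dHvH = 1, dHcal = 1e-3, c0 = -Inf, c1 = -Inf),
      upper = c(Tm = max(Tk), dHvH = Inf, dHcal = Inf, c0 = Inf, c1 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  } else {
    minpack.lm::nlsLM(
      y ~ dsc_excess_model(Tk, Tm, dHvH, dHcal),
      start = list(Tm = Tm0, dHvH = dHvH0, dHcal = area0),
      lower = c(Tm = min(Tk), dHvH = 1, dHcal = 1e-3),
      upper = c(Tm = max(Tk), dHvH = Inf, dHcal = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  }, error = function(e) NULL)
  if (is.null(fit)) {
    abort(sprintf("dsc_two_state_fit: did not converge (start Tm=%.2f K, dHvH=%.1f, area=%.2f)",
                  Tm0, dHvH0, area0))
  }
  cf <- as.list(coef(fit))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(coef(fit))))
  structure(list(
    Tm = cf$Tm, dH_vH = cf$dHvH, dH_cal = cf$dHcal, se = se,
    sse = sum(stats::residuals(fit)^2), n = length(Tk),
    data = tibble(T = Tk, y = y)
  ), class = "dsc_fit")
}
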