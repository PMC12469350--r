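#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for fitted objects
#'
#' One-row (or per-term) tibble summaries of the package's fitted
#' objects, in the broom style.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.exchange_fit <- function(x, ...) {
  tibble(residue = x$residue, aa = x$aa, I0 = x$I0, C = x$C,
         k_ex = x$k_ex, k_err = x$k_err, censored = x$censored)
}

#' @rdname tidiers
#' @export
tidy.lem_fit <- function(x, ...) {
  tibble(term = c("dG_H2O", "m_value", "Cm", "aN", "bN", "aU", "bU"),
         estimate = c(x$dG_H2O, x$m_value, x$Cm, x$aN, x$bN, x$aU, x$bU),
         std.error = c(x$dG_se,
                       unname(x$se[c("m", "Cm")]),
                       unname(x$se[c("aN", "bN", "aU", "bU")])))
}

#' @rdname tidiers
#' @export
glance.lem_fit <- function(x, ...) {
  tibble(dG_H2O = x$dG_H2O, m_value = x$m_value, Cm = x$Cm,
         Cm_crossing = x$Cm_crossing, temperature = x$temperature,
         sse = x$sse, n = x$n)
}

#' @rdname tidiers
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble(term = c("Tm", "dH_vH", "aN", "bN", "aU", "bU"),
         estimate = c(x$Tm, x$dH_vH, x$aN, x$bN, x$aU, x$bU),
         std.error = unname(x$se[c("Tm", "dH", "aN", "bN", "aU", "bU")]))
}

#' @rdname tidiers
#' @export
glance.melt_fit <- function(x, ...) {
  tibble(Tm = x$Tm, Tm_C = x$Tm - 273.15, dH_vH = x$dH_vH, sse = x$sse, n = x$n)
}

#' @rdname tidiers
#' @export
tidy.dsc_result <- function(x, ...) {
  tibble(Tm = x$Tm, Tm_C = x$Tm - 273.15, dH_cal = x$dH_cal,
         Cp_max = x$Cp_max, baseline = x$baseline)
}

#' @rdname tidiers
#' @export
tidy.dsc_fit <- function(x, ...) {
  tibble(term = c("Tm", "dH_vH", "dH_cal"),
         estimate = c(x$Tm, x$dH_vH, x$dH_cal),
         std.error = unname(x$se[c("Tm", "dHvH", "dHcal")]))
}

#' @rdname tidiers
#' @export
glance.dsc_fit <- function(x, ...) {
  tibble(Tm = x$Tm, Tm_C = x$Tm - 273.15, dH_vH = x$dH_vH,
         dH_cal = x$dH_cal, sse = x$sse, n = x$n)
}

#' @rdname tidiers
#' @export
tidy.relaxation_fit <- function(x, ...) {
  tibble(residue = x$residue, aa = x$aa, kind = x$kind,
         rate = x$rate, rate_err = x$rate_err, sigma = x$sigma)
}

#' @rdname tidiers
#' @export
tidy.stability_report <- function(x, ...) x$table

#' @rdname tidiers
#' @export
glance.stability_report <- function(x, ...) {
  tibble(dG_global = x$dG_global, factor = x$factor,
         threshold_fx = x$threshold_fx,
         logP_threshold_1x = x$logP_threshold_1x,
         logP_threshold_fx = x$logP_threshold_fx,
         n_above_global = length(x$above_global),
         n_above_factor = length(x$above_factor),
         temperature = x$temperature)
}
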