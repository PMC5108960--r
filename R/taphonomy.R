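#' Taphonomic survival model
#'
#' Power-law model for the loss of archaeological material with time since
#' deposition, \eqn{n(t) = a (t + b)^c} with \eqn{c < 0} (Surovell-style
#' taphonomic correction). The correction used by the proxies is the
#' survival *relative to the present*, \eqn{s(t) = (t+b)^c / b^c}, so
#' \eqn{s(0) = 1} and \eqn{s} decreases strictly with age. Default
#' constants are the published values for the global volcanic-tephra
#' calibration of the model; all three are overridable.
#'
#' @param a Scale constant (cancels in the relative survival).
#' @param b Offset in years, `> 0`.
#' @param c Exponent, `< 0`.
#' @return A list of class `taph_model`.
#' @export
taph_model <- function(a = 5726442, b = 2176.4, c = -1.3925309) {
  if (b <= 0 || c >= 0) {
    abort("Taphonomic model needs b > 0 and c < 0.", class = "chronopop_usage_error")
  }
  structure(list(a = a, b = b, c = c), class = "taph_model")
}

#' Relative taphonomic survival
#'
#' @param t Calendar age(s), years cal BP, all `>= 0`.
#' @param model A [taph_model()].
#' @return Survival proportion(s) relative to the present: `s(0) = 1`,
#'   strictly decreasing in `t`.
#' @export
#' @examples
#' taph_survival(c(0, 1000, 5000))
taph_survival <- function(t, model = taph_model()) {
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("Ages must be finite and non-negative.", class = "chronopop_domain_error")
  }
  (t + model$b)^model$c / model$b^model$c
}

#' Correct a proxy series for taphonomic loss
#'
#' Divides each grid value by the relative survival at that calendar age,
#' converting an observed series into a deposition-rate (corrected) series.
#' Values at 0 cal BP are unchanged (`s(0) = 1`); older values are scaled
#' up. Correcting an already corrected series is an error.
#'
#' @param series A grid series from [kde_series()] or
#'   [site_count_series()].
#' @param model A [taph_model()].
#' @return The corrected series (`corrected = TRUE`), same proxy tag.
#' @export
apply_taph_correction <- function(series, model = taph_model()) {
  check_grid_series(series)
  if (any(series$corrected)) {
    abort("Series is already taphonomically corrected.", class = "chronopop_usage_error")
  }
  s <- taph_survival(series$cal_bp, model)
  out <- series
  out$value <- series$value / s
  out$corrected <- TRUE
  attr(out, "n_dates") <- attr(series, "n_dates")
  out
}
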