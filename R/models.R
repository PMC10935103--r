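#' Lloyd-Taylor ecosystem respiration model
#'
#' Exponential-in-inverse-temperature respiration model
#' \deqn{RE(T_s) = R_{ref} \exp\left(E_0 \left[\frac{1}{T_{ref}-T_0} -
#'   \frac{1}{T_s + 273.15 - T_0}\right]\right)}
#' with the original formulation's standard constants: reference temperature
#' 283.15 K (10 degC) and lower temperature bound 227.13 K.  At a soil
#' temperature of 10 degC the prediction equals \code{r_ref} exactly.
#'
#' @param ts_c soil temperature in degrees Celsius.
#' @param r_ref respiration at the reference temperature (mg CO2 m-2 s-1).
#' @param e0 temperature-sensitivity parameter (K).
#' @param t_ref reference temperature (K), fixed at 283.15 by convention.
#' @param t0 lower temperature bound (K), fixed at 227.13 by convention.
#' @return respiration in mg CO2 m-2 s-1, strictly increasing in `ts_c`
#'   whenever `e0 > 0`.
#' @export
lloyd_taylor <- function(ts_c, r_ref, e0, t_ref = 283.15, t0 = 227.13) {
  r_ref * exp(e0 * (1 / (t_ref - t0) - 1 / (ts_c + 273.15 - t0)))
}

#' Rectangular-hyperbola gross light response
#'
#' Michaelis-Menten style saturation of gross CO2 uptake with light:
#' \deqn{P(PAR) = \frac{\alpha \, PAR \, P_{max}}{\alpha \, PAR + P_{max}}}
#' The initial slope at PAR = 0 is \eqn{\alpha} and the asymptote is
#' \eqn{P_{max}}.
#'
#' @param par photosynthetically active radiation (umol m-2 s-1).
#' @param alpha apparent quantum efficiency (mg CO2 umol-1).
#' @param pmax maximum photosynthetic rate (mg CO2 m-2 s-1).
#' @return gross uptake in mg CO2 m-2 s-1 (non-negative).
#' @export
light_response_gross <- function(par, alpha, pmax) {
  alpha * par * pmax / (alpha * par + pmax)
}

#' Modelled net ecosystem exchange
#'
#' Combines the rectangular-hyperbola light response with Lloyd-Taylor
#' respiration: NEE = RE(Ts) - P(PAR).  Negative values denote net uptake.
#' At night (PAR = 0) the model reduces to NEE = RE(Ts).
#'
#' @inheritParams light_response_gross
#' @inheritParams lloyd_taylor
#' @return NEE in mg CO2 m-2 s-1.
#' @export
nee_model <- function(par, ts_c, alpha, pmax, r_ref, e0) {
  lloyd_taylor(ts_c, r_ref, e0) - light_response_gross(par, alpha, pmax)
}
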