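#' Respiration model coefficients
#'
#' Empirical coefficients of the power-law respiration-heat model for
#' Chinese cabbage, Q(T) = (10.7 f / 3600) * (9 T / 5 + 32)^g with T in
#' degrees C (the base is the Fahrenheit temperature).
#'
#' @param f Dimensionless pre-factor.  Default 6.0803e-4.
#' @param g Dimensionless exponent.  Default 2.6183.
#' @param gas_constant Universal gas constant, J/mol K.
#' @export
respiration_params <- function(f = 6.0803e-4, g = 2.6183, gas_constant = 8.314) {
  if (f <= 0 || g <= 0) stop("`f` and `g` must be positive", call. = FALSE)
  structure(list(f = f, g = g, gas_constant = gas_constant),
            class = "respiration_params")
}

#' Sealed-chamber CO2 trace
#'
#' Container for a respiration measurement: produce sealed in a wrapped
#' basket, CO2 concentration and temperature logged over time.
#'
#' @param times Sample times, hours, strictly increasing.
#' @param co2 CO2 concentration, ppm (nonnegative).
#' @param temperature Chamber temperature, degrees C (scalar or per sample).
#' @param chamber_volume Free volume of the sealed basket, m^3.
#' @param loaded_mass Produce mass in the basket, kg.
#' @param pressure Total pressure, Pa.
#' @return Object of class `sealed_chamber_trace`.
#' @export
sealed_chamber_trace <- function(times, co2, temperature, chamber_volume,
                                 loaded_mass, pressure = 101325) {
  if (length(times) != length(co2))
    stop("`times` and `co2` must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(co2 < 0)) stop("`co2` must be nonnegative", call. = FALSE)
  if (chamber_volume <= 0 || loaded_mass <= 0)
    stop("`chamber_volume` and `loaded_mass` must be positive", call. = FALSE)
  if (length(temperature) == 1L) temperature <- rep(temperature, length(times))
  structure(list(times = times, co2 = co2, temperature = temperature,
                 chamber_volume = chamber_volume, loaded_mass = loaded_mass,
                 pressure = pressure),
            class = "sealed_chamber_trace")
}

#' Molar respiration rate from a sealed-chamber trace
#'
#' Ideal-gas conversion of the CO2 accumulation rate: the CO2 mole-fraction
#' slope dx/dt (least-squares over the whole trace, ppm converted by 1e-6)
#' gives R = P V (dx/dt) / (M Rgas Tbar), with Tbar the trace-mean absolute
#' temperature.  The least-squares slope, rather than endpoint differencing,
#' makes the estimate robust to sensor noise.
#'
#' @param trace A [sealed_chamber_trace()].
#' @param params A [respiration_params()] (supplies the gas constant).
#' @return Respiration rate, mol CO2 / kg h.
#' @export
estimate_respiration_rate <- function(trace, params = respiration_params()) {
  stopifnot(inherits(trace, "sealed_chamber_trace"))
  if (length(trace$times) < 2L)
    stop("at least two samples are required", call. = FALSE)
  slope_ppm <- unname(coef(lm(trace$co2 ~ trace$times))[2])    # ppm / h
  Tbar <- mean(trace$temperature) + 273.15
  trace$pressure * trace$chamber_volume * slope_ppm * 1e-6 /
    (trace$loaded_mass * params$gas_constant * Tbar)
}

#' Respiration heat per unit mass
#'
#' Q(T) = (10.7 f / 3600) * (9 T / 5 + 32)^g in W/kg, strictly increasing
#' in temperature.  `9 T / 5 + 32` is the Fahrenheit conversion of the
#' Celsius produce temperature; setting `literal_9T = TRUE` evaluates the
#' base as `9 T + 32` instead (an alternative reading of the model, kept
#' for comparison).
#'
#' @param T Produce temperature, degrees C (vectorised).
#' @param params A [respiration_params()].
#' @param literal_9T Use base 9T + 32 instead of the Fahrenheit 9T/5 + 32.
#' @return Heat generation, W/kg.
#' @export
respiration_heat <- function(T, params = respiration_params(),
                             literal_9T = FALSE) {
  base <- if (literal_9T) 9 * T + 32 else 9 * T / 5 + 32
  if (any(base <= 0))
    stop("temperature outside model domain: 9T/5 + 32 must be positive",
         call. = FALSE)
  (10.7 * params$f / 3600) * base^params$g
}

#' Volumetric heat-source strength of a loaded basket
#'
#' q = Q * m / V, i.e. the per-mass respiration heat times the bulk density
#' of produce in the basket.
#'
#' @param Q_T Respiration heat, W/kg.
#' @param mass_in_basket Produce mass, kg.
#' @param basket_volume Basket volume, m^3.
#' @return Source strength, W/m^3.
#' @export
volumetric_source <- function(Q_T, mass_in_basket, basket_volume) {
  if (any(basket_volume <= 0)) stop("`basket_volume` must be positive", call. = FALSE)
  if (any(mass_in_basket <= 0)) stop("`mass_in_basket` must be positive", call. = FALSE)
  Q_T * mass_in_basket / basket_volume
}

# Heat released per mole of CO2 for full oxidative respiration of glucose:
# 2816 kJ per mole glucose over 6 moles CO2.
.J_PER_MOL_CO2 <- 2816e3 / 6

#' Convert between respiration heat and molar CO2 rate
#'
#' Oxidative respiration releases about 2816 kJ per mole of glucose, i.e.
#' 469.3 kJ per mole of CO2; these helpers convert a per-mass heat rate
#' (W/kg) to the corresponding molar CO2 rate (mol/kg h) and back.
#'
#' @param Q_T Respiration heat, W/kg.
#' @param rate Molar respiration rate, mol CO2 / kg h.
#' @return `heat_to_molar_rate`: mol CO2 / kg h; `molar_rate_to_heat`: W/kg.
#' @export
heat_to_molar_rate <- function(Q_T) Q_T * 3600 / .J_PER_MOL_CO2

#' @rdname heat_to_molar_rate
#' @export
molar_rate_to_heat <- function(rate) rate * .J_PER_MOL_CO2 / 3600
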