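#' Class-indexed thermal and physical properties of cabbage heads
#'
#' Measured property models for the three morphological size classes:
#' thermal conductivity is linear in temperature, specific heat quadratic,
#' and density a per-class constant.  Coefficients are stored per class and
#' evaluated by [conductivity()] and [specific_heat()].
#'
#' @format Internal list, one entry per class, with elements `k_coeffs`
#'   (intercept, slope; W/m K), `cp_coeffs` (intercept, linear, quadratic;
#'   J/kg K) and `density` (kg/m^3).
#' @name cabbage_properties
NULL

.property_table <- list(
  `1` = list(k_coeffs  = c(2.2e-2,  8.1e-5),
             cp_coeffs = c(1770, 1.76,  -0.0048),
             density   = 601.64),
  `2` = list(k_coeffs  = c(2.27e-2, 8.3e-5),
             cp_coeffs = c(1775, 1.765, -0.00475),
             density   = 675.70),
  `3` = list(k_coeffs  = c(2.3e-2,  8.5e-5),
             cp_coeffs = c(1780, 1.78,  -0.0047),
             density   = 754.34)
)

.check_class_id <- function(class_id) {
  if (length(class_id) != 1L || !class_id %in% 1:3)
    stop("`class_id` must be 1, 2 or 3", call. = FALSE)
  as.character(class_id)
}

#' Water-vapour fluid properties for the porous interior
#'
#' The pore fluid of the cabbage matrix is taken to be water vapour at
#' storage temperature.  Defaults are saturated-vapour values at about 4
#' degrees C: density 6.8e-3 kg/m^3, specific heat 1880 J/kg K, conductivity
#' 0.0184 W/m K, dynamic viscosity 9.7e-6 Pa s.
#'
#' @param density kg/m^3.
#' @param specific_heat J/kg K.
#' @param conductivity W/m K.
#' @param viscosity Pa s.
#' @return A list with elements `density`, `specific_heat`, `conductivity`,
#'   `viscosity`.
#' @export
water_vapour_properties <- function(density = 6.8e-3, specific_heat = 1880,
                                    conductivity = 0.0184, viscosity = 9.7e-6) {
  stopifnot(density > 0, specific_heat > 0, conductivity > 0, viscosity > 0)
  list(density = density, specific_heat = specific_heat,
       conductivity = conductivity, viscosity = viscosity)
}

#' Bundle the thermal properties of one size class
#'
#' @param class_id Size class, 1 (smallest) to 3 (largest).
#' @param porosity Void fraction of the head, in (0, 1).  Default 0.31, the
#'   vacuum-impregnation value for whole heads.
#' @param fluid Pore-fluid properties, see [water_vapour_properties()].
#' @return An object of class `thermal_properties`: list with `class_id`,
#'   `k_coeffs`, `cp_coeffs`, `density`, `porosity` and `fluid`.
#' @export
thermal_properties <- function(class_id, porosity = 0.31,
                               fluid = water_vapour_properties()) {
  key <- .check_class_id(class_id)
  if (!is.numeric(porosity) || porosity <= 0 || porosity >= 1)
    stop("`porosity` must lie strictly between 0 and 1", call. = FALSE)
  out <- c(.property_table[[key]],
           list(class_id = as.integer(class_id), porosity = porosity,
                fluid = fluid))
  structure(out, class = "thermal_properties")
}

#' Freeze temperature-dependent properties at a reference temperature
#'
#' Returns a copy of `props` whose conductivity and specific-heat polynomials
#' are constants evaluated at `T_ref`.  Used when comparing the transient
#' solver against constant-property closed forms.
#'
#' @param props A [thermal_properties()] object.
#' @param T_ref Reference temperature, degrees C.
#' @export
constant_properties <- function(props, T_ref) {
  stopifnot(inherits(props, "thermal_properties"))
  props$k_coeffs <- c(conductivity(T_ref, props$class_id), 0)
  props$cp_coeffs <- c(specific_heat(T_ref, props$class_id), 0, 0)
  props
}

#' Thermal conductivity of the solid matrix
#'
#' Linear model k(T) = a + b T with per-class coefficients.
#'
#' @param T Temperature, degrees C (vectorised).
#' @param class_id Size class 1..3.
#' @return Conductivity, W/m K.
#' @export
conductivity <- function(T, class_id) {
  cf <- .property_table[[.check_class_id(class_id)]]$k_coeffs
  cf[1] + cf[2] * T
}

#' Specific heat of the solid matrix
#'
#' Quadratic model Cp(T) = a + b T + c T^2 with per-class coefficients.
#'
#' @inheritParams conductivity
#' @return Specific heat, J/kg K.
#' @export
specific_heat <- function(T, class_id) {
  cf <- .property_table[[.check_class_id(class_id)]]$cp_coeffs
  cf[1] + cf[2] * T + cf[3] * T^2
}

#' Porosity from vacuum-impregnation weight gain
#'
#' The pore volume is the water mass taken up under vacuum divided by the
#' water density, and porosity is pore volume over initial sample volume:
#' phi = (W_saturated - W_i) / (rho_w * V_i).
#'
#' @param W_saturated Weight after vacuum impregnation, kg.
#' @param W_i Initial weight, kg.
#' @param rho_w Water density, kg/m^3.
#' @param V_i Initial sample volume, m^3.
#' @return Porosity (dimensionless).  Values above 0.6 trigger a
#'   plausibility warning: leafy heads do not reach such void fractions.
#' @export
porosity <- function(W_saturated, W_i, rho_w = 1000, V_i) {
  if (any(V_i <= 0)) stop("`V_i` must be positive", call. = FALSE)
  if (any(W_saturated < W_i))
    stop("saturated weight below initial weight: negative uptake", call. = FALSE)
  phi <- (W_saturated - W_i) / (rho_w * V_i)
  if (any(phi > 0.6))
    warning("porosity above 0.6 is physically implausible for whole heads")
  phi
}

#' Effective conductivity of the porous medium
#'
#' Volume-weighted combination of solid and fluid conductivities.  The
#' default arithmetic (parallel) rule is k_eff = (1 - phi) k_s + phi k_f;
#' harmonic (series) and geometric rules are available since the mixing
#' construction is not fixed by measurement.
#'
#' @param phi Porosity in \[0, 1\].
#' @param k_s,k_f Solid and fluid conductivities, W/m K.
#' @param rule Mixing rule.
#' @return Effective conductivity, W/m K, bounded by `range(k_s, k_f)`.
#' @export
effective_conductivity <- function(phi, k_s, k_f,
                                   rule = c("arithmetic", "harmonic", "geometric")) {
  rule <- match.arg(rule)
  if (any(phi < 0 | phi > 1)) stop("`phi` must lie in [0, 1]", call. = FALSE)
  switch(rule,
    arithmetic = (1 - phi) * k_s + phi * k_f,
    harmonic   = 1 / ((1 - phi) / k_s + phi / k_f),
    geometric  = k_s^(1 - phi) * k_f^phi
  )
}

#' Darcy-Forchheimer flow resistance parameters
#'
#' Nominal defaults (permeability 1e-7 m^2, Forchheimer coefficient 0.55)
#' are order-of-magnitude values for loose leafy produce beds; they are not
#' measured cabbage values and should be replaced where measurements exist.
#'
#' @param K Permeability, m^2.
#' @param C_F Forchheimer (inertial) coefficient, dimensionless.
#' @export
porous_flow_params <- function(K = 1e-7, C_F = 0.55) {
  if (K <= 0) stop("permeability `K` must be positive", call. = FALSE)
  if (C_F < 0) stop("`C_F` must be nonnegative", call. = FALSE)
  structure(list(K = K, C_F = C_F), class = "porous_flow_params")
}

#' Darcy-Forchheimer pressure-gradient magnitude
#'
#' |grad P| = (mu / K) u + (rho C_F / sqrt(K)) u^2: a viscous (Darcy) term
#' linear in velocity and an inertial (Forchheimer) term quadratic in it.
#'
#' @param u Superficial velocity magnitude, m/s (vectorised, nonnegative).
#' @param flow A [porous_flow_params()] object.
#' @param mu Fluid dynamic viscosity, Pa s.
#' @param rho_wv Fluid (water vapour) density, kg/m^3.
#' @return Pressure-gradient magnitude, Pa/m.
#' @export
darcy_forchheimer_gradient <- function(u, flow = porous_flow_params(),
                                       mu = water_vapour_properties()$viscosity,
                                       rho_wv = water_vapour_properties()$density) {
  stopifnot(inherits(flow, "porous_flow_params"))
  if (any(u < 0)) stop("`u` must be nonnegative", call. = FALSE)
  (mu / flow$K) * u + (rho_wv * flow$C_F / sqrt(flow$K)) * u^2
}
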