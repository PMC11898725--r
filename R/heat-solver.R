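#' Equivalent-sphere geometry of a cabbage head
#'
#' A head is modelled as a prolate spheroid with semi-axes derived from the
#' two measured circumferences, a = length_circumference / 2 pi and
#' b = width_circumference / 2 pi, and replaced by the sphere of equal
#' volume, R = (a b^2)^(1/3).
#'
#' @param length_circumference_cm Circumference along the long axis, cm.
#' @param width_circumference_cm Circumference around the waist, cm.
#' @param class_id Optional size class the geometry belongs to.
#' @return Object of class `sphere_geometry` with radius `R` in metres and
#'   semi-axes `a`, `b` (m).
#' @export
sphere_geometry <- function(length_circumference_cm, width_circumference_cm,
                            class_id = NA_integer_) {
  a <- length_circumference_cm / (2 * pi) / 100
  b <- width_circumference_cm / (2 * pi) / 100
  if (a < b) stop("length circumference must be at least the width", call. = FALSE)
  structure(list(R = (a * b^2)^(1 / 3), a = a, b = b,
                 class_id = as.integer(class_id)),
            class = "sphere_geometry")
}

#' Equivalent sphere of a size class
#'
#' Builds the [sphere_geometry()] from a class's mean circumferences.
#'
#' @param class_id Size class 1..3.
#' @param specs Per-class trait specifications, see [cabbage_class_specs()].
#' @export
class_sphere <- function(class_id, specs = cabbage_class_specs()) {
  sp <- specs[[class_id]]
  sphere_geometry(sp$length_mean, sp$width_mean, class_id)
}

#' Convective boundary and initial conditions
#'
#' @param h Surface heat-transfer coefficient, W/m^2 K (positive).
#' @param T_inf Ambient (coolant air) temperature, degrees C.
#' @param T0 Initial produce temperature, degrees C.
#' @export
boundary_conditions <- function(h, T_inf, T0) {
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  structure(list(h = h, T_inf = T_inf, T0 = T0), class = "boundary_conditions")
}

#' Heat-source models for the transient solver
#'
#' `heat_source_none()` disables generation; `heat_source_constant()` applies
#' a fixed volumetric source; `heat_source_respiration()` couples the
#' temperature-dependent respiration heat [respiration_heat()] times the
#' produce density to the local temperature, re-evaluated each step.
#'
#' @param qdot Constant source strength, W/m^3.
#' @param params A [respiration_params()].
#' @param density Mass of respiring produce per unit model volume, kg/m^3.
#'   For a single head this is the solid density of its class; for a basket
#'   treated as a block it is the bulk density (mass over basket volume).
#' @param literal_9T See [respiration_heat()].
#' @return Object of class `heat_source`.
#' @export
heat_source_none <- function() {
  structure(list(type = "none"), class = "heat_source")
}

#' @rdname heat_source_none
#' @export
heat_source_constant <- function(qdot) {
  stopifnot(is.finite(qdot))
  structure(list(type = "constant", qdot = qdot), class = "heat_source")
}

#' @rdname heat_source_none
#' @export
heat_source_respiration <- function(params = respiration_params(), density,
                                    literal_9T = FALSE) {
  stopifnot(inherits(params, "respiration_params"), density > 0)
  structure(list(type = "respiration", params = params, density = density,
                 literal_9T = literal_9T), class = "heat_source")
}

.source_args <- function(source) {
  if (is.null(source)) source <- heat_source_none()
  if (is.numeric(source)) source <- heat_source_constant(source)
  stopifnot(inherits(source, "heat_source"))
  switch(source$type,
    none = list(type = 0L, qdot = 0, c = 0, g = 1, literal = FALSE, density = 0),
    constant = list(type = 1L, qdot = source$qdot, c = 0, g = 1,
                    literal = FALSE, density = 0),
    respiration = list(type = 2L, qdot = 0,
                       c = 10.7 * source$params$f / 3600, g = source$params$g,
                       literal = isTRUE(source$literal_9T),
                       density = source$density))
}

#' Transient conduction in the porous equivalent sphere
#'
#' Solves the volume-averaged energy equation of the porous head under
#' local thermal equilibrium (one temperature for matrix and pore fluid,
#' combined capacity (1 - phi) rho_s Cp_s + phi rho_f Cp_f) in spherical
#' symmetry:
#' C(T) dT/dt = (1/r^2) d/dr (r^2 k_eff(T) dT/dr) + q(T),
#' with zero gradient at the centre and Robin exchange
#' -k_eff dT/dr = h (T_s - T_inf) at the surface.  The march is backward
#' Euler on a uniform finite-volume grid with properties and source lagged
#' one step, giving one tridiagonal solve per step (unconditionally stable).
#'
#' @param geom A [sphere_geometry()].
#' @param props A [thermal_properties()].
#' @param bc A [boundary_conditions()].
#' @param source A `heat_source` object, a plain number (constant q, W/m^3),
#'   or NULL for no generation.
#' @param t_end Simulated time, s.
#' @param dt Time step, s.
#' @param n_nodes Number of radial cells.
#' @param output_dt Output sampling interval, s.
#' @param mixing Effective-conductivity mixing rule.
#' @return Object of class `temperature_field`: `node_radii` (m), `times`
#'   (s), `temperatures` (cells x times, degrees C), `volume_average`,
#'   `surface`, `center` (per-time, degrees C) and an `energy` audit with
#'   cumulative stored and supplied energy (J).
#' @export
solve_transient <- function(geom, props, bc, source = NULL,
                            t_end, dt = 5, n_nodes = 100, output_dt = 60,
                            mixing = c("arithmetic", "harmonic", "geometric")) {
  stopifnot(inherits(geom, "sphere_geometry"),
            inherits(props, "thermal_properties"),
            inherits(bc, "boundary_conditions"))
  if (dt <= 0 || n_nodes < 10)
    stop("`dt` must be positive and `n_nodes` at least 10", call. = FALSE)
  mixing <- match.arg(mixing)
  rule <- match(mixing, c("arithmetic", "harmonic", "geometric")) - 1L
  s <- .source_args(source)
  out <- .radial_solve_cpp(geom$R, as.integer(n_nodes), dt, t_end,
                           max(output_dt, dt),
                           props$k_coeffs, props$cp_coeffs, props$density,
                           props$porosity, props$fluid$density,
                           props$fluid$specific_heat, props$fluid$conductivity,
                           rule, bc$h, bc$T_inf, bc$T0,
                           s$type, s$qdot, s$c, s$g, s$literal, s$density)
  structure(list(node_radii = out$node_radii, times = out$times,
                 temperatures = out$temperatures,
                 volume_average = out$volume_average,
                 surface = out$surface, center = out$center,
                 energy = list(stored = out$energy_stored,
                               supplied = out$energy_supplied),
                 geom = geom, bc = bc),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  nt <- length(x$times)
  cat("Temperature field:", length(x$node_radii), "cells x", nt, "times\n")
  cat(sprintf("  t = 0 .. %.0f s;  volume average %.3f -> %.3f degC\n",
              x$times[nt], x$volume_average[1], x$volume_average[nt]))
  invisible(x)
}

#' @export
as.data.frame.temperature_field <- function(x, ...) {
  data.frame(time_s = x$times, volume_avg_C = x$volume_average,
             surface_C = x$surface, center_C = x$center)
}

# positive roots of 1 - lambda cot(lambda) = Bi, bracketed in (n pi, (n+1) pi)
.sphere_eigenvalues <- function(Bi, n_terms) {
  if (Bi <= 0) stop("Biot number must be positive", call. = FALSE)
  f <- function(l) 1 - l / tan(l) - Bi
  vapply(seq_len(n_terms), function(k) {
    uniroot(f, c((k - 1) * pi + 1e-10, k * pi - 1e-10), tol = 1e-12)$root
  }, numeric(1))
}

#' Analytic series for convective cooling of a solid sphere
#'
#' Constant-property, source-free benchmark: with Bi = h R / k and
#' Fo = alpha t / R^2, theta / theta0 = sum C_n sin(lambda_n r / R) /
#' (lambda_n r / R) exp(-lambda_n^2 Fo), where lambda_n are the roots of
#' 1 - lambda cot(lambda) = Bi and C_n = 4 (sin l - l cos l) /
#' (2 l - sin 2 l).  Serves as the independent oracle for the transient
#' solver.
#'
#' @param R Sphere radius, m.
#' @param k Conductivity, W/m K.
#' @param rho_cp Volumetric heat capacity, J/m^3 K.
#' @param h Surface coefficient, W/m^2 K.
#' @param T0,T_inf Initial and ambient temperatures, degrees C.
#' @param r Radial positions, m (scalar or vector; 0 allowed).
#' @param t Times, s (vector).
#' @param n_terms Number of series terms (>= 20).
#' @return Matrix of temperatures, length(r) x length(t) (dropped to a
#'   vector when r is scalar).
#' @export
analytic_sphere_cooling <- function(R, k, rho_cp, h, T0, T_inf, r, t,
                                    n_terms = 50) {
  stopifnot(n_terms >= 20, all(r >= 0), all(r <= R + 1e-12))
  lam <- .sphere_eigenvalues(h * R / k, n_terms)
  Cn <- 4 * (sin(lam) - lam * cos(lam)) / (2 * lam - sin(2 * lam))
  Fo <- (k / rho_cp) * t / R^2
  shape <- vapply(r, function(ri) {
    x <- lam * ri / R
    ifelse(x == 0, 1, sin(x) / x)
  }, numeric(length(lam)))                       # n_terms x length(r)
  decay <- exp(-outer(lam^2, Fo))                # n_terms x length(t)
  theta <- t(shape * Cn) %*% decay               # r x t
  out <- T_inf + (T0 - T_inf) * theta
  if (length(r) == 1L) drop(out) else out
}

#' Volume-averaged analytic sphere cooling
#'
#' Same series as [analytic_sphere_cooling()] integrated over the sphere:
#' mean theta / theta0 = sum B_n exp(-lambda_n^2 Fo) with
#' B_n = 3 C_n (sin l - l cos l) / l^3.
#'
#' @inheritParams analytic_sphere_cooling
#' @return Vector of volume-average temperatures at `t`.
#' @export
analytic_sphere_cooling_vavg <- function(R, k, rho_cp, h, T0, T_inf, t,
                                         n_terms = 50) {
  lam <- .sphere_eigenvalues(h * R / k, n_terms)
  Cn <- 4 * (sin(lam) - lam * cos(lam)) / (2 * lam - sin(2 * lam))
  Bn <- 3 * Cn * (sin(lam) - lam * cos(lam)) / lam^3
  Fo <- (k / rho_cp) * t / R^2
  T_inf + (T0 - T_inf) * colSums(Bn * exp(-outer(lam^2, Fo)))
}

#' Steady conduction profile with uniform generation
#'
#' Closed form for a sphere with constant source q and surface convection:
#' T(r) = T_inf + q R / (3 h) + q (R^2 - r^2) / (6 k_eff).
#'
#' @param R Radius, m.
#' @param k_eff Effective conductivity, W/m K.
#' @param h Surface coefficient, W/m^2 K (positive).
#' @param T_inf Ambient temperature, degrees C.
#' @param q_dot Volumetric source, W/m^3.
#' @param r Radial positions, m; defaults to 101 points on \[0, R\].
#' @return Data frame with columns `r` and `temperature`.
#' @export
steady_state_generation <- function(R, k_eff, h, T_inf, q_dot, r = NULL) {
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  if (is.null(r)) r <- seq(0, R, length.out = 101)
  data.frame(r = r,
             temperature = T_inf + q_dot * R / (3 * h) +
               q_dot * (R^2 - r^2) / (6 * k_eff))
}

# first crossing time of a series, linear interpolation between samples
.cross_time <- function(times, values, target) {
  if (values[1] <= target) return(0)
  below <- which(values <= target)
  if (length(below) == 0)
    stop("target temperature never reached within the simulated horizon",
         call. = FALSE)
  j <- below[1]
  t0 <- times[j - 1]; t1 <- times[j]
  v0 <- values[j - 1]; v1 <- values[j]
  t0 + (v0 - target) / (v0 - v1) * (t1 - t0)
}

#' Time for the volume-average temperature to reach a target
#'
#' Linear interpolation between the bracketing output times of the field's
#' volume-average series; 0 when the series starts at or below the target,
#' an error when the target is never crossed.
#'
#' @param field A [solve_transient()] result.
#' @param T_target Target temperature, degrees C.
#' @return Crossing time in the field's time unit (seconds).
#' @export
time_to_threshold <- function(field, T_target) {
  stopifnot(inherits(field, "temperature_field"))
  .cross_time(field$times, field$volume_average, T_target)
}
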