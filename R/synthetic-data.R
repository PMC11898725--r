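#' Per-class morphological trait specification
#'
#' Mean, SD and observed range of the three measured traits for one size
#' class.  The defaults in [cabbage_class_specs()] reproduce the summary
#' statistics of the classified heads.
#'
#' @param class_id Size class 1..3.
#' @param length_mean,length_sd,length_min,length_max Length circumference, cm.
#' @param width_mean,width_sd,width_min,width_max Width circumference, cm.
#' @param weight_mean,weight_sd,weight_min,weight_max Head weight, g.
#' @return Object of class `class_spec`.
#' @export
class_spec <- function(class_id,
                       length_mean, length_sd, length_min, length_max,
                       width_mean, width_sd, width_min, width_max,
                       weight_mean, weight_sd, weight_min, weight_max) {
  spec <- list(class_id = as.integer(class_id),
               length_mean = length_mean, length_sd = length_sd,
               length_min = length_min, length_max = length_max,
               width_mean = width_mean, width_sd = width_sd,
               width_min = width_min, width_max = width_max,
               weight_mean = weight_mean, weight_sd = weight_sd,
               weight_min = weight_min, weight_max = weight_max)
  for (tr in c("length", "width", "weight")) {
    m <- spec[[paste0(tr, "_mean")]]; s <- spec[[paste0(tr, "_sd")]]
    lo <- spec[[paste0(tr, "_min")]]; hi <- spec[[paste0(tr, "_max")]]
    if (s <= 0) stop(tr, " sd must be positive", call. = FALSE)
    if (!(lo <= m && m <= hi))
      stop(tr, " mean must lie inside [min, max]", call. = FALSE)
  }
  structure(spec, class = "class_spec")
}

#' Default morphological specifications of the three size classes
#'
#' Measured per-class summary statistics of 162 classified heads:
#' class 1 (small) 73.32 +- 3.34 cm length, 46.73 +- 2.24 cm width,
#' 1503.20 +- 118.39 g; class 2 (medium) 82.67 +- 1.17, 51.89 +- 2.37,
#' 2132.48 +- 127.16; class 3 (large) 89.17 +- 2.45, 58.67 +- 2.77,
#' 2826.37 +- 121.25 — each with its observed min/max range.
#'
#' @return List of three [class_spec()] objects.
#' @export
cabbage_class_specs <- function() {
  list(
    class_spec(1, 73.32, 3.34, 68, 79,   46.73, 2.24, 44, 48,
               1503.20, 118.39, 1306.39, 1783.26),
    class_spec(2, 82.67, 1.17, 80, 84,   51.89, 2.37, 49, 54,
               2132.48, 127.16, 1795.23, 2483.57),
    class_spec(3, 89.17, 2.45, 85, 93,   58.67, 2.77, 55, 61,
               2826.37, 121.25, 2484.77, 3112.85)
  )
}

#' Storage-environment summary specification
#'
#' Means and spreads of the monitored cold-room environment: mid-height CO2
#' 921 +- 8 ppm, relative humidity 59-68 %, and air velocities
#' 0.45 +- 0.19 (low), 0.23 +- 0.11 (mid) and 0.53 +- 0.18 m/s (high
#' position).
#'
#' @param co2_mid_mean,co2_mid_sd Mid-height CO2, ppm.
#' @param rh_range Relative-humidity range, percent (length-2).
#' @param velocity_low,velocity_mid,velocity_high Mean and SD pairs, m/s.
#' @export
env_spec <- function(co2_mid_mean = 921, co2_mid_sd = 8,
                     rh_range = c(59, 68),
                     velocity_low = c(0.45, 0.19),
                     velocity_mid = c(0.23, 0.11),
                     velocity_high = c(0.53, 0.18)) {
  vals <- c(co2_mid_mean, co2_mid_sd, rh_range, velocity_low, velocity_mid,
            velocity_high)
  if (any(vals < 0)) stop("environment values must be nonnegative", call. = FALSE)
  structure(list(co2_mid_mean = co2_mid_mean, co2_mid_sd = co2_mid_sd,
                 rh_range = rh_range, velocity_low = velocity_low,
                 velocity_mid = velocity_mid, velocity_high = velocity_high),
            class = "env_spec")
}

# storage basket: 52 x 30 x 30 cm
.basket_volume <- 0.52 * 0.30 * 0.30       # m^3
.basket_area <- 2 * (0.52 * 0.30 * 2 + 0.30 * 0.30)  # m^2

# truncated-Gaussian sampler by rejection (bounds sit within ~2 sd, so the
# acceptance rate is high)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(max(2L * n, 10L), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate synthetic morphology records
#'
#' Draws per-class traits from independent truncated Gaussians (truncation
#' at each trait's observed \[min, max\]).  The returned table carries no
#' class column — classification is the downstream task — but the ground
#' truth is attached as attribute `true_class`.
#'
#' @param n_per_class Heads per class (>= 2).
#' @param specs List of [class_spec()] objects.
#' @param seed RNG seed.
#' @return Data frame with columns `id`, `length_circumference_cm`,
#'   `width_circumference_cm`, `weight_g`; attribute `true_class` holds the
#'   generating class of each row.
#' @export
gen_morphology <- function(n_per_class = 54, specs = cabbage_class_specs(),
                           seed = 1) {
  if (n_per_class < 2) stop("`n_per_class` must be at least 2", call. = FALSE)
  stopifnot(all(vapply(specs, inherits, logical(1), "class_spec")))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  rows <- lapply(specs, function(sp) {
    data.frame(
      length_circumference_cm = .rtruncnorm(n_per_class, sp$length_mean,
                                            sp$length_sd, sp$length_min,
                                            sp$length_max),
      width_circumference_cm = .rtruncnorm(n_per_class, sp$width_mean,
                                           sp$width_sd, sp$width_min,
                                           sp$width_max),
      weight_g = .rtruncnorm(n_per_class, sp$weight_mean, sp$weight_sd,
                             sp$weight_min, sp$weight_max))
  })
  out <- do.call(rbind, rows)
  out <- cbind(id = seq_len(nrow(out)), out)
  attr(out, "true_class") <- rep(vapply(specs, `[[`, integer(1), "class_id"),
                                 each = n_per_class)
  out
}

#' Generate a sealed-chamber CO2 trace
#'
#' Forward model of the respiration measurement: three heads of the class's
#' mean weight sealed in a standard basket at constant temperature.  The
#' generating molar rate is the respiration heat at the chamber temperature
#' converted by the oxidative stoichiometry ([heat_to_molar_rate()]); the
#' CO2 concentration then rises linearly at the ideal-gas slope implied by
#' that rate, plus i.i.d. Gaussian sensor noise.
#'
#' @param class_id Size class 1..3.
#' @param duration Trace length, h.
#' @param dt Sampling interval, h.
#' @param T_chamber Chamber temperature, degrees C.
#' @param noise_sd CO2 sensor noise SD, ppm (>= 0).
#' @param seed RNG seed.
#' @param specs Class specifications (for the mean weight).
#' @param params Respiration coefficients.
#' @param co2_ambient Starting concentration, ppm.
#' @return A [sealed_chamber_trace()] with attributes `generating_rate`
#'   (mol CO2/kg h) and `generating_slope` (ppm/h).
#' @export
gen_sealed_trace <- function(class_id, duration = 12, dt = 0.5, T_chamber = 5,
                             noise_sd = 5, seed = 1,
                             specs = cabbage_class_specs(),
                             params = respiration_params(),
                             co2_ambient = 400) {
  if (duration <= 0 || dt <= 0) stop("`duration` and `dt` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  sp <- specs[[class_id]]
  mass <- 3 * sp$weight_mean / 1000                     # kg, three mean heads
  rate <- heat_to_molar_rate(respiration_heat(T_chamber, params))
  P <- 101325
  slope <- rate * mass * params$gas_constant * (T_chamber + 273.15) /
    (P * .basket_volume) * 1e6                          # ppm / h
  times <- seq(0, duration, by = dt)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  co2 <- co2_ambient + slope * times +
    if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0
  out <- sealed_chamber_trace(times, co2, T_chamber, .basket_volume, mass, P)
  attr(out, "generating_rate") <- rate
  attr(out, "generating_slope") <- slope
  out
}

#' Generate a synthetic cooling experiment
#'
#' Runs the forward radial solver for the class's equivalent sphere with the
#' respiration source enabled, samples the volume-average temperature at
#' regular intervals, and adds independent Gaussian noise per monitoring
#' position.  Stands in for logged cooling curves at the top, middle and
#' bottom baskets.
#'
#' @param h_true True surface coefficient, W/m^2 K.
#' @param T0 Initial produce temperature, degrees C.
#' @param T_inf Storage air temperature, degrees C.
#' @param positions Character labels of monitored positions.
#' @param noise_sd Thermocouple noise SD, degrees C.
#' @param duration Experiment length, h.
#' @param seed RNG seed.
#' @param class_id Size class of the monitored heads.
#' @param sample_dt_min Sampling interval, minutes.
#' @param respiration Include the metabolic source.
#' @param dt,n_nodes Solver discretization (s, cells).
#' @return A `cooling_experiment`: list with `times` (h), `temperatures`
#'   (samples x positions matrix, degrees C), `positions` and `meta`
#'   (class, T0, T_inf, h_true, noise_sd).
#' @export
gen_cooling_experiment <- function(h_true, T0 = 20, T_inf = 4.1,
                                   positions = c("top", "middle", "bottom"),
                                   noise_sd = 0.2, duration = 20, seed = 1,
                                   class_id = 2, sample_dt_min = 10,
                                   respiration = TRUE, dt = 30, n_nodes = 100) {
  if (h_true <= 0 || duration <= 0)
    stop("`h_true` and `duration` must be positive", call. = FALSE)
  props <- thermal_properties(class_id)
  geom <- class_sphere(class_id)
  src <- if (respiration) heat_source_respiration(density = props$density)
         else heat_source_none()
  out_dt <- sample_dt_min * 60
  field <- solve_transient(geom, props, boundary_conditions(h_true, T_inf, T0),
                           src, t_end = duration * 3600, dt = dt,
                           n_nodes = n_nodes, output_dt = out_dt)
  keep <- field$times > 0
  times_h <- field$times[keep] / 3600
  base <- field$volume_average[keep]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  temps <- vapply(positions, function(p)
    base + if (noise_sd > 0) rnorm(length(base), 0, noise_sd) else 0,
    numeric(length(base)))
  structure(list(times = times_h, temperatures = temps, positions = positions,
                 meta = list(class_id = class_id, T0 = T0, T_inf = T_inf,
                             h_true = h_true, noise_sd = noise_sd)),
            class = "cooling_experiment")
}

#' Generate an environment log for the storage room
#'
#' Simple stationary emulation of the monitored room: Gaussian CO2 around
#' the mid-height mean, relative humidity uniform in the observed range, and
#' Gaussian air velocity at the three probe heights (negative draws clipped
#' to zero).
#'
#' @param duration Log length, h.
#' @param dt Sampling interval, h.
#' @param spec An [env_spec()].
#' @param seed RNG seed.
#' @return Data frame with columns `time_h`, `co2_ppm`, `rh_pct`,
#'   `velocity_low_ms`, `velocity_mid_ms`, `velocity_high_ms`.
#' @export
gen_environment_trace <- function(duration = 72, dt = 0.5,
                                  spec = env_spec(), seed = 1) {
  stopifnot(inherits(spec, "env_spec"), duration > 0, dt > 0)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  times <- seq(0, duration, by = dt)
  n <- length(times)
  vel <- function(p) pmax(0, rnorm(n, p[1], p[2]))
  data.frame(time_h = times,
             co2_ppm = rnorm(n, spec$co2_mid_mean, spec$co2_mid_sd),
             rh_pct = runif(n, spec$rh_range[1], spec$rh_range[2]),
             velocity_low_ms = vel(spec$velocity_low),
             velocity_mid_ms = vel(spec$velocity_mid),
             velocity_high_ms = vel(spec$velocity_high))
}
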