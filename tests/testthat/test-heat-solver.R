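test_that("equivalent-sphere radius follows the spheroid volume rule", {
  g <- sphere_geometry(82.67, 51.89, 2)
  a <- 82.67 / (2 * pi) / 100
  b <- 51.89 / (2 * pi) / 100
  expect_equal(g$R, (a * b^2)^(1 / 3))
  expect_equal(class_sphere(2)$R, g$R)
  expect_equal(g$R, 0.0965, tolerance = 1e-3)
  expect_error(sphere_geometry(40, 50), "length circumference")
})

test_that("uniform equilibrium is preserved exactly", {
  fld <- solve_transient(class_sphere(2), thermal_properties(2),
                         boundary_conditions(270, 4.1, 4.1), NULL,
                         t_end = 3600, dt = 30, n_nodes = 50)
  expect_equal(max(abs(fld$temperatures - 4.1)), 0, tolerance = 1e-10)
})

test_that("solver matches the analytic series oracle for convective cooling", {
  props <- constant_properties(thermal_properties(2), 4.1)
  geom <- class_sphere(2)
  fld <- solve_transient(geom, props, boundary_conditions(270, 4.1, 20),
                         NULL, t_end = 20 * 3600, dt = 5, n_nodes = 200,
                         output_dt = 600)
  ora <- analytic_sphere_cooling_vavg(geom$R, class2_keff(), class2_rhocp(),
                                      270, 20, 4.1, fld$times[-1],
                                      n_terms = 80)
  expect_lt(max(abs(fld$volume_average[-1] - ora)), 0.05)
  # maximum principle with no source
  expect_true(all(fld$temperatures >= 4.1 - 1e-9 &
                    fld$temperatures <= 20 + 1e-9))
})

test_that("discrete energy balance closes to round-off", {
  props <- constant_properties(thermal_properties(2), 4.1)
  fld <- solve_transient(class_sphere(2), props,
                         boundary_conditions(270, 4.1, 20),
                         heat_source_constant(15),
                         t_end = 6 * 3600, dt = 10, n_nodes = 100)
  imb <- abs(fld$energy$stored - fld$energy$supplied)
  expect_lt(max(imb) / max(abs(fld$energy$stored)), 1e-6)
})

test_that("long-time solution converges to the closed-form generation profile", {
  props <- constant_properties(thermal_properties(2), 4.1)
  geom <- class_sphere(2)
  fld <- solve_transient(geom, props, boundary_conditions(270, 4.1, 4.1),
                         heat_source_constant(10), t_end = 250 * 3600,
                         dt = 600, n_nodes = 200, output_dt = 50 * 3600)
  ss <- steady_state_generation(geom$R, class2_keff(), 270, 4.1, 10,
                                r = fld$node_radii)
  final <- fld$temperatures[, ncol(fld$temperatures)]
  expect_lt(max(abs(final - ss$temperature)), 1e-3)
})

test_that("observed convergence orders are first in dt and second in dr", {
  props <- constant_properties(thermal_properties(2), 4.1)
  geom <- class_sphere(2)
  bc <- boundary_conditions(270, 4.1, 20)
  vavg_at <- function(dt, n) {
    fld <- solve_transient(geom, props, bc, NULL, t_end = 7200, dt = dt,
                           n_nodes = n, output_dt = 7200)
    fld$volume_average[length(fld$volume_average)]
  }
  # temporal order by self-convergence at fixed fine grid
  s <- vapply(c(160, 80, 40), vavg_at, numeric(1), n = 300)
  p_t <- log2(abs(s[1] - s[2]) / abs(s[2] - s[3]))
  expect_lt(abs(p_t - 1), 0.3)
  # spatial order at fixed small dt
  s <- vapply(c(24, 48, 96), function(n) vavg_at(2, n), numeric(1))
  p_x <- log2(abs(s[1] - s[2]) / abs(s[2] - s[3]))
  expect_lt(abs(p_x - 2), 0.3)
})

test_that("metabolic heat raises early-storage temperatures", {
  props <- thermal_properties(2)
  geom <- class_sphere(2)
  bc <- boundary_conditions(270, 4.1, 20)
  src <- heat_source_respiration(density = props$density)
  on_ <- solve_transient(geom, props, bc, src, 10 * 3600, dt = 60,
                         output_dt = 600)
  off <- solve_transient(geom, props, bc, NULL, 10 * 3600, dt = 60,
                         output_dt = 600)
  d <- on_$volume_average[-1] - off$volume_average[-1]
  expect_true(all(d > 0))
})

test_that("series oracle honours its own limits", {
  # initial condition recovered at r = R/2 (Bi = 4)
  R <- 0.1
  expect_lt(abs(analytic_sphere_cooling(R, 0.02, 8e5, 0.8, 20, 4, R / 2, 0,
                                        n_terms = 50) - 20), 1e-3)
  # Bi -> infinity pushes the first eigenvalue to pi
  lam <- napacool:::.sphere_eigenvalues(1e8, 1)
  expect_equal(lam, pi, tolerance = 1e-4)
  # Bi = 1 gives lambda_1 = pi/2
  expect_equal(napacool:::.sphere_eigenvalues(1, 1), pi / 2, tolerance = 1e-10)
  expect_error(analytic_sphere_cooling_vavg(R, 0.02, 8e5, -1, 20, 4, 1),
               "Biot")
})

test_that("steady generation profile satisfies the surface energy balance", {
  prof0 <- steady_state_generation(0.1, 0.02, 100, 4, 0)
  expect_equal(unique(prof0$temperature), 4)
  prof <- steady_state_generation(0.0965, 0.0211, 270, 4.1, 10)
  expect_equal(prof$temperature[nrow(prof)], 4.1 + 10 * 0.0965 / (3 * 270))
  centre_excess <- 10 * 0.0965 / (3 * 270) + 10 * 0.0965^2 / (6 * 0.0211)
  expect_equal(prof$temperature[1] - 4.1, centre_excess, tolerance = 1e-6)
  expect_equal(centre_excess, 0.737, tolerance = 1e-3)
  expect_error(steady_state_generation(0.1, 0.02, 0, 4, 1), "positive")
})

test_that("threshold times interpolate linearly between samples", {
  fake <- structure(list(times = c(0, 100), volume_average = c(5, 4)),
                    class = "temperature_field")
  expect_equal(time_to_threshold(fake, 4.25), 75)
  below <- structure(list(times = c(0, 100), volume_average = c(4, 3.5)),
                     class = "temperature_field")
  expect_equal(time_to_threshold(below, 4.25), 0)
  expect_error(time_to_threshold(fake, 3.9), "never reached")
})
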