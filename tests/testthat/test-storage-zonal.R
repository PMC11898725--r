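test_that("scenario construction encodes the three loading layouts", {
  fp <- build_scenario("fully_packed")
  bt <- build_scenario("batch_50_50")
  rp <- build_scenario("repositioned_batch")
  expect_true(all(fp$insertion_time == 0))
  expect_equal(sum(bt$insertion_time == 0), bt$n_blocks / 2)
  expect_equal(max(bt$insertion_time), 5)
  expect_gt(min(rp$airflow_fraction), min(fp$airflow_fraction))
  for (s in list(fp, bt, rp)) expect_equal(sum(s$airflow_fraction), 1)
  expect_error(build_scenario("stacked"), "arg")
  bad <- zonal_config(fractions = list(fully_packed = c(0.5, 0.2),
                                       batch_50_50 = 1,
                                       repositioned_batch = 1))
  expect_error(build_scenario("fully_packed", bad), "n_blocks")
})

test_that("blocks at the setpoint with no source stay put", {
  cfg <- zonal_config(T0 = 4.1, delay = 0)
  st <- simulate_storage(build_scenario("fully_packed", cfg), source = "none",
                         t_end = 5)
  expect_equal(max(abs(st$block_temperature - 4.1)), 0, tolerance = 1e-12)
})

test_that("a lone block follows the exponential lumped-cooling law", {
  cfg <- zonal_config(n_blocks = 2, delay = 0,
                      fractions = list(fully_packed = c(0.5, 0.5),
                                       batch_50_50 = c(0.5, 0.5),
                                       repositioned_batch = c(0.5, 0.5)))
  scn <- build_scenario("fully_packed", cfg)
  st <- simulate_storage(scn, source = "none", t_end = 2, output_dt = 0.1,
                         substep_factor = 2e-4)
  cp <- specific_heat(4.1, 2)
  tau <- cfg$block_mass * cp / (scn$h_eff[1] * cfg$block_area)   # s
  exact <- 4.1 + (20 - 4.1) * exp(-st$times * 3600 / tau)
  expect_lt(max(abs(st$block_temperature[1, ] - exact)), 1e-3)
})

test_that("respiring blocks settle at the flux-balance excess", {
  cfg <- zonal_config(n_blocks = 2, delay = 0,
                      fractions = list(fully_packed = c(0.6, 0.4),
                                       batch_50_50 = c(0.6, 0.4),
                                       repositioned_batch = c(0.6, 0.4)))
  scn <- build_scenario("fully_packed", cfg)
  st <- simulate_storage(scn, source = "respiration", t_end = 6)
  Tend <- st$block_temperature[, ncol(st$block_temperature)]
  for (b in 1:2) {
    conv <- scn$h_eff[b] * cfg$block_area * (Tend[b] - cfg$setpoint)
    resp <- respiration_heat(Tend[b]) * cfg$block_mass
    expect_equal(conv, resp, tolerance = 1e-3)
  }
})

test_that("block energy bookkeeping closes", {
  scn <- build_scenario("batch_50_50")
  st <- simulate_storage(scn, source = "respiration", t_end = 10)
  cp <- specific_heat(scn$setpoint, scn$class_id)
  for (b in seq_len(scn$n_blocks)) {
    dH <- scn$block_mass * cp *
      (st$block_temperature[b, ncol(st$block_temperature)] - scn$T0)
    supplied <- st$energy$convective[b] + st$energy$respiration[b]
    expect_lt(abs(supplied - dH) / abs(dH), 1e-4)
  }
})

test_that("zero staging delay collapses batch filling onto full packing", {
  f <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  cfg <- zonal_config(delay = 0,
                      fractions = list(fully_packed = f, batch_50_50 = f,
                                       repositioned_batch = f))
  st_f <- simulate_storage(build_scenario("fully_packed", cfg), t_end = 10)
  st_b <- simulate_storage(build_scenario("batch_50_50", cfg), t_end = 10)
  expect_equal(st_f$block_temperature, st_b$block_temperature)
})

test_that("more airflow everywhere cools every block faster", {
  scn <- build_scenario("batch_50_50")
  boosted <- scn
  boosted$airflow_fraction <- scn$airflow_fraction * 1.3
  boosted$h_eff <- scn$h_ref * boosted$airflow_fraction^scn$exponent
  t_slow <- compare_scenarios(list(scn))
  t_fast <- compare_scenarios(list(boosted))
  expect_lt(t_fast$gradient_time_h, t_slow$gradient_time_h)
  expect_lt(t_fast$equilibrium_time_h, t_slow$equilibrium_time_h)
})

test_that("identical scenarios report identical times", {
  out <- compare_scenarios(list(build_scenario("batch_50_50"),
                                build_scenario("batch_50_50")))
  expect_equal(out$gradient_time_h[1], out$gradient_time_h[2])
  expect_equal(out$equilibrium_time_h[1], out$equilibrium_time_h[2])
})

test_that("unreachable equilibrium is reported, not silently truncated", {
  scn <- build_scenario("fully_packed")
  expect_error(compare_scenarios(list(scn), t_end = 6), "never reached")
})
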