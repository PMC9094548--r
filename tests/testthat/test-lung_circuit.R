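test_that("lung_flow evaluates the linear R/C law", {
  lp <- lung_params(compliance = 20, resistance = 20)
  # equilibrium: applied pressure equals elastic recoil
  st <- lung_state(volume_above_residual = 20 * 5)  # V/C = 5
  expect_equal(lung_flow(5, st, lp), 0)
  # empty lung, 30 cmH2O applied: Q = 30/20 = 1.5 L/s
  st0 <- lung_state(0)
  expect_equal(lung_flow(30, st0, lp), 1.5)
  # pediatric numbers: V/C = 15, (20-15)/25 = 0.2 L/s
  ped <- lung_params(compliance = 10, resistance = 25)
  stp <- lung_state(150)
  expect_equal(lung_flow(20, stp, ped), 0.2)
  expect_error(lung_flow(Inf, st0, lp))
})

test_that("step_lung matches the closed-form exponential solution", {
  # C = 20 mL/cmH2O, R = 20 -> tau = 0.4 s; step 5 -> 30 held:
  # V(t) = C*30 - C*25*exp(-t/tau); at t = tau, dV = 500*(1-1/e) =~ 316 mL
  lp <- lung_params(20, 20)
  st <- lung_state(20 * 5)
  v0 <- st$volume
  for (i in 1:400) st <- step_lung(st, 30, 0.001, lp)
  dv_exact <- 0.5 * (1 - exp(-1))
  expect_lt(abs((st$volume - v0) - dv_exact), 0.01 * 0.5)  # <=1% of C*dP
  expect_equal((st$volume - v0) * 1000, 316, tolerance = 0.01)

  # pediatric: C = 10, R = 25 (tau = 0.25), step 5 -> 20 for 0.6 s
  ped <- lung_params(10, 25)
  stp <- lung_state(10 * 5)
  v0 <- stp$volume
  for (i in 1:600) stp <- step_lung(stp, 20, 0.001, ped)
  dv_exact <- 0.15 * (1 - exp(-0.6 / 0.25))
  expect_lt(abs((stp$volume - v0) - dv_exact), 0.01 * 0.15)
  expect_equal((stp$volume - v0) * 1000, 136, tolerance = 0.01)

  # exact integrator reproduces the closed form to numerical precision
  ste <- lung_state(20 * 5)
  for (i in 1:400) ste <- step_lung(ste, 30, 0.001, lp, method = "exact")
  expect_equal(ste$volume - 0.1, 0.5 * (1 - exp(-1)), tolerance = 1e-12)
})

test_that("step_lung keeps equilibrium, clamps volume, validates dt", {
  lp <- lung_params(20, 20)
  st <- lung_state(20 * 5)
  st2 <- step_lung(st, 5, 0.001, lp)
  expect_equal(st2$volume, st$volume)
  expect_equal(st2$time, st$time + 0.001)
  # strong negative applied pressure cannot push volume below zero
  st3 <- lung_state(1)
  for (i in 1:200) st3 <- step_lung(st3, -50, 0.01, lp)
  expect_gte(st3$volume, 0)
  expect_error(step_lung(st, 30, 0.02, lp), "dt")
  expect_error(step_lung(st, 30, 0, lp), "dt")
})

test_that("expiratory valve is one-way and thresholded at the PEEP setting", {
  cp <- circuit_params(expiratory_resistance = 10)
  expect_equal(expiratory_flow(30, 5, FALSE, cp), 0)
  expect_equal(expiratory_flow(5, 5, TRUE, cp), 0)
  expect_equal(expiratory_flow(30, 5, TRUE, cp), 2.5)
  expect_equal(expiratory_flow(3, 5, TRUE, cp), 0)  # below PEEP: no reverse flow
})

test_that("passive exhalation decays monotonically to PEEP without undershoot", {
  lp <- lung_params(20, 20)
  cp <- circuit_params(expiratory_resistance = 10)
  v <- 0.02 * 30  # inflated to 30 cmH2O recoil
  peep <- 5
  paws <- numeric(6000)
  for (i in seq_len(6000)) {
    paw <- airway_node_pressure(0, v / 0.02, TRUE, peep, lp, cp)
    q <- (paw - v / 0.02) / lp$resistance          # into lung (negative)
    v <- v + q * 0.001
    paws[i] <- paw
  }
  expect_true(all(diff(paws) <= 1e-12))
  expect_true(all(paws >= peep - 1e-9))
  expect_equal(paws[6000], peep, tolerance = 1e-3)
})

test_that("sensor frames apply gain/offset/noise and are seed-reproducible", {
  st <- lung_state(0, airway_pressure = 30, flow_out = 1, time = 2)
  ideal <- sensor_model(pressure_noise_sd = 0, flow_noise_sd = 0)
  f <- read_sensors(st, ideal)
  expect_equal(f$pressure_reading, 30)
  expect_equal(f$flow_reading, 60)  # 1 L/s on the expiratory side
  miscal <- sensor_model(pressure_noise_sd = 0, flow_noise_sd = 0,
                         pressure_gain = 1, pressure_offset = 2)
  expect_equal(read_sensors(st, miscal)$pressure_reading, 32)
  insp <- sensor_model(pressure_noise_sd = 0, flow_noise_sd = 0,
                       flow_sensor_side = "inspiratory")
  expect_equal(read_sensors(st, insp)$flow_reading, 0)
  noisy <- sensor_model()
  set.seed(42); a <- read_sensors(st, noisy)
  set.seed(42); b <- read_sensors(st, noisy)
  expect_identical(a, b)
})

test_that("pressure-sensor calibration recovers the affine map", {
  expect_equal(calibrate_pressure_sensor(rbind(c(0.5, 0), c(4.5, 100))),
               c(gain = 25, offset = -12.5))
  expect_equal(calibrate_pressure_sensor(rbind(c(0, 0), c(1, 1))),
               c(gain = 1, offset = 0))
  # noisy points on y = 10x + 3: least squares recovers within 2%
  set.seed(7)
  raw <- seq(0, 5, length.out = 40)
  known <- 10 * raw + 3 + rnorm(40, 0, 0.2)
  fit <- calibrate_pressure_sensor(cbind(raw, known))
  expect_equal(unname(fit["gain"]), 10, tolerance = 0.02)
  expect_equal(unname(fit["offset"]), 3, tolerance = 0.06)
  expect_error(calibrate_pressure_sensor(rbind(c(1, 0), c(1, 5))),
               "degenerate")
  expect_error(calibrate_pressure_sensor(rbind(c(1, 0))), "two")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(lung_params(compliance = 0))
  expect_error(lung_params(resistance = -1))
  expect_error(circuit_params(valve_max_flow = 120))
  expect_error(circuit_params(valve_max_flow = 0))
  expect_error(sensor_model(pressure_noise_sd = -1))
  expect_error(lung_state(-5))
})
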