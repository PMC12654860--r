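test_that("axis force follows m g cos(theta - phase) in nN", {
  m <- 3.27e-5
  mg <- mg_oracle(m)
  expect_equal(expected_axis_force(m, angle = 0), mg, tolerance = 1e-12)
  expect_equal(mg, 320.6775, tolerance = 1e-4)   # direct multiplication
  expect_lt(abs(expected_axis_force(m, angle = 90)), 1e-9)
  expect_equal(expected_axis_force(m, angle = 180),
               -expected_axis_force(m, angle = 0))
  expect_equal(expected_axis_force(m, angle = 120, phase = 30),
               expected_axis_force(m, angle = 90))
  expect_error(expected_axis_force(-1, 0), "must be > 0")
})

test_that("noise-free sweeps recover the sensor exactly", {
  sensor <- sensor_params(true_coefficient = 2, phase_offset = 30,
                          adc_baseline = 100, adc_noise_sd = 0)
  sw <- simulate_calibration_sweep(sensor, seed = 1)
  expect_equal(length(sw$angles), 50)
  expect_equal(diff(sw$angles)[1], 7.2)
  r <- fit_calibration(sw)
  expect_equal(r$coefficient, 2, tolerance = 1e-12)
  expect_equal(r$phase, 30, tolerance = 1e-9)
  expect_equal(r$baseline, 100, tolerance = 1e-9)
  expect_lt(r$rmse, 1e-9)
  expect_gte(r$max_error, r$rmse)
  expect_lt(r$resolution, 1e-9)
  # at 90 degrees past the phase the axis force is zero
  adc_at <- approx(sw$angles, sw$adc_values, xout = 120)$y
  expect_equal(adc_at, 100, tolerance = 1e-2)
})

test_that("coefficient recovery is unbiased under ADC noise (Monte Carlo)", {
  sensor <- sensor_params(true_coefficient = 2, phase_offset = 30,
                          adc_baseline = 100, adc_noise_sd = 1)
  ks <- vapply(1:200, function(s) {
    fit_calibration(simulate_calibration_sweep(sensor, seed = s))$coefficient
  }, numeric(1))
  expect_lt(abs(mean(ks) - 2) / 2, 0.01)
})

test_that("resolution tracks the force-equivalent ADC noise and scales linearly", {
  sensor <- sensor_params(true_coefficient = 2, adc_noise_sd = 1)
  res <- vapply(1:200, function(s) {
    sw <- simulate_calibration_sweep(sensor, seed = s)
    fit_calibration(sw)$resolution
  }, numeric(1))
  expect_equal(mean(res), 2, tolerance = 0.1)    # noise_sd * coefficient

  noise_grid <- c(0.5, 1, 2, 4)
  mean_res <- vapply(noise_grid, function(ns) {
    s2 <- sensor_params(true_coefficient = 2, adc_noise_sd = ns)
    mean(vapply(1:50, function(s) {
      fit_calibration(simulate_calibration_sweep(s2, seed = s))$resolution
    }, numeric(1)))
  }, numeric(1))
  fit <- lm(mean_res ~ noise_grid)
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 0.05)
  expect_lt(abs(coef(fit)[1]), 0.1)
})

test_that("rotating the sweep shifts the phase and nothing else", {
  sensor <- sensor_params(true_coefficient = 1.9, phase_offset = 10,
                          adc_noise_sd = 0.5)
  sw <- simulate_calibration_sweep(sensor, seed = 7)
  r0 <- fit_calibration(sw)
  for (delta in c(10, 33.3, 90)) {
    sw2 <- calibration_sweep(sw$angles + delta, sw$adc_values,
                             ball_mass = sw$ball_mass, gravity = sw$gravity)
    r2 <- fit_calibration(sw2)
    expect_equal(r2$phase, r0$phase + delta, tolerance = 1e-9)
    expect_equal(r2$coefficient, r0$coefficient, tolerance = 1e-12)
    expect_equal(r2$rmse, r0$rmse, tolerance = 1e-9)
    expect_equal(r2$resolution, r0$resolution, tolerance = 1e-9)
  }
})

test_that("denser angular sampling does not worsen coefficient recovery", {
  sensor <- sensor_params(true_coefficient = 2, adc_noise_sd = 2)
  err <- function(n_steps) {
    mean(vapply(1:100, function(s) {
      sw <- simulate_calibration_sweep(sensor, n_steps = n_steps, seed = s)
      abs(fit_calibration(sw)$coefficient - 2)
    }, numeric(1)))
  }
  expect_lt(err(50), err(10))
})

test_that("convert_trace applies the linear map and inverts simulation", {
  sensor <- sensor_params(true_coefficient = 2, phase_offset = 15,
                          adc_baseline = 50, adc_noise_sd = 0)
  sw <- simulate_calibration_sweep(sensor, seed = 1)
  r <- fit_calibration(sw)
  expect_equal(convert_trace(r$baseline + c(1, 2, 3), r), c(2, 4, 6),
               tolerance = 1e-9)
  expect_equal(convert_trace(rep(r$baseline, 5), r), rep(0, 5))
  truth <- expected_axis_force(sw$ball_mass, sw$angles, 15)
  expect_lt(max(abs(convert_trace(sw$adc_values, r) - truth)), 1e-9)
})

test_that("degenerate sweeps are rejected", {
  expect_error(calibration_sweep(c(0, 0, 0, 0), 1:4), "strictly increasing")
  expect_error(calibration_sweep(c(0, 120, 240), c(1, 2, 3)), "at least 4")
  expect_error(simulate_calibration_sweep(sensor_params(), ball_mass = -1),
               "must be > 0")
  expect_error(simulate_calibration_sweep(sensor_params(), n_steps = 3),
               "must lie in")
  sw <- simulate_calibration_sweep(sensor_params(adc_noise_sd = 0), seed = 1)
  r <- fit_calibration(sw)
  short <- calibration_sweep(sw$angles[1:4], sw$adc_values[1:4])
  expect_error(estimate_resolution(short, fit_calibration(short)),
               "at least 5")
})

test_that("calibration files round-trip through CSV + JSON sidecar", {
  sw <- simulate_calibration_sweep(sensor_params(), ball_mass = 2e-5,
                                   seed = 3, gravity = 9.81)
  p <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, p, header = "config deadbeef")
  sw2 <- read_sweep_csv(p)
  expect_equal(sw2$angles, sw$angles)
  expect_equal(sw2$adc_values, sw$adc_values)
  expect_equal(sw2$ball_mass, 2e-5)
  expect_equal(sw2$gravity, 9.81)
  rp <- tempfile(fileext = ".json")
  write_calibration_json(fit_calibration(sw), rp)
  j <- jsonlite::read_json(rp)
  expect_equal(j$coefficient_nN_per_ADU, fit_calibration(sw)$coefficient,
               tolerance = 1e-9)
})
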