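test_that("shipped tables hold 22 available pairs and 6 unavailable entries", {
  models <- sensor_models()
  expect_named(models, c("TGS-2611E00", "TGS-2611C00", "TGS-2610C00",
                         "TGS-2620"))
  avail <- sapply(models, function(m)
    sapply(m$calibrations, `[[`, "available"))
  expect_equal(dim(avail), c(7L, 4L))
  expect_equal(sum(avail), 22L)
  expect_equal(sum(!avail), 6L)
  # the datasheets publish no propane curve for TGS-2611E00/C00 and TGS-2620,
  # and no CO curve for any model but TGS-2620
  expect_false(models[["TGS-2611E00"]]$calibrations$propane$available)
  expect_false(models[["TGS-2611E00"]]$calibrations$CO$available)
  expect_false(models[["TGS-2611C00"]]$calibrations$propane$available)
  expect_false(models[["TGS-2611C00"]]$calibrations$CO$available)
  expect_false(models[["TGS-2610C00"]]$calibrations$CO$available)
  expect_false(models[["TGS-2620"]]$calibrations$propane$available)
  # every model covers all seven gases
  for (m in models) expect_named(m$calibrations, enose_gases())
})

test_that("forward power law at C = 1 ppm returns the table's A constant", {
  for (m in sensor_models()) {
    for (cal in m$calibrations) {
      if (!cal$available) next
      expect_equal(resistivity_from_concentration(cal, 1), cal$A,
                   tolerance = 1e-12)
    }
  }
})

test_that("forward power law matches direct arithmetic spot checks", {
  models <- sensor_models()
  methane <- models[["TGS-2611E00"]]$calibrations$methane
  expect_equal(resistivity_from_concentration(methane, 1), 29.37996766,
               tolerance = 1e-12)
  air <- models[["TGS-2611E00"]]$calibrations$air
  for (c in c(0.5, 1, 100, 1e4)) {
    expect_equal(resistivity_from_concentration(air, c), 8.584894051,
                 tolerance = 1e-12)
  }
  co <- models[["TGS-2620"]]$calibrations$CO
  expect_equal(resistivity_from_concentration(co, 10),
               47.99739024 * 10^(-0.6086910204), tolerance = 1e-12)
})

test_that("forward model is monotone in concentration with the sign of alpha", {
  grid <- c(0.1, 1, 10, 100, 1e4)
  for (cal in invertible_calibrations()) {
    rs <- resistivity_from_concentration(cal, grid)
    expect_true(all(sign(diff(rs)) == sign(cal$alpha)),
                label = paste("monotone", cal$gas_name))
  }
})

test_that("forward/inverse round trip holds to 1e-9 relative", {
  grid <- c(0.1, 1, 7, 100, 1234, 1e4)
  for (cal in invertible_calibrations()) {
    back <- concentration_from_resistivity(
      cal, resistivity_from_concentration(cal, grid))
    expect_equal(back, grid, tolerance = 1e-9)
  }
})

test_that("inversion at Rs = A gives exactly 1 ppm", {
  cal <- sensor_models()[["TGS-2611C00"]]$calibrations$methane
  expect_equal(concentration_from_resistivity(cal, cal$A), 1.0,
               tolerance = 1e-12)
})

test_that("unavailable, alpha = 0 and out-of-domain inputs raise typed failures", {
  models <- sensor_models()
  propane <- models[["TGS-2611E00"]]$calibrations$propane
  expect_error(resistivity_from_concentration(propane, 10), "no-calibration")
  expect_error(concentration_from_resistivity(propane, 10), "no-calibration")
  air <- models[["TGS-2611E00"]]$calibrations$air
  expect_error(concentration_from_resistivity(air, 10), "non-invertible")
  methane <- models[["TGS-2611E00"]]$calibrations$methane
  expect_error(resistivity_from_concentration(methane, 0), "positive")
  expect_error(resistivity_from_concentration(methane, -5), "positive")
  expect_error(concentration_from_resistivity(methane, 0), "positive")
})

test_that("log-log regression recovers noiseless generating constants exactly", {
  c_grid <- c(1, 10, 100, 1000)
  fit <- fit_power_law(c_grid, 50 * c_grid^-0.4)
  expect_equal(fit$A, 50, tolerance = 1e-9)
  expect_equal(fit$alpha, -0.4, tolerance = 1e-9)
  # every stored invertible calibration is recoverable from its own samples
  for (cal in invertible_calibrations()) {
    rs <- resistivity_from_concentration(cal, c_grid)
    refit <- fit_power_law(c_grid, rs, gas_name = cal$gas_name)
    expect_equal(refit$A, cal$A, tolerance = 1e-9)
    expect_equal(refit$alpha, cal$alpha, tolerance = 1e-9)
  }
})

test_that("two points give the exact interpolating power law", {
  fit <- fit_power_law(c(2, 20), c(30, 12))
  expect_equal(resistivity_from_concentration(fit, 2), 30, tolerance = 1e-9)
  expect_equal(resistivity_from_concentration(fit, 20), 12, tolerance = 1e-9)
})

test_that("fit tolerates multiplicative log-normal noise within 2 percent", {
  set.seed(404)
  c_grid <- 10^seq(0, 3, length.out = 50)
  rs <- 50 * c_grid^-0.4 * exp(rnorm(50, 0, 0.01))
  fit <- fit_power_law(c_grid, rs)
  expect_equal(fit$A, 50, tolerance = 0.02)
  expect_equal(fit$alpha, -0.4, tolerance = 0.02)
})

test_that("fit rejects degenerate input", {
  expect_error(fit_power_law(1, 10), "at least 2")
  expect_error(fit_power_law(c(1, -2), c(10, 20)), "positive")
  expect_error(fit_power_law(c(1, 2), c(0, 20)), "positive")
  expect_error(fit_power_law(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("load-divider inversion follows Rs = RL (Vcc - V)/V", {
  circ <- divider_circuit(supply_voltage = 5, load_resistance = 10000)
  expect_equal(resistance_from_voltage(2.5, circ), 10000)
  expect_equal(resistance_from_voltage(1.0, circ), 40000)
  v <- seq(0.1, 4.9, by = 0.1)
  expect_true(all(diff(resistance_from_voltage(v, circ)) < 0))
  expect_error(resistance_from_voltage(0, circ), "v_out")
  expect_error(resistance_from_voltage(5, circ), "v_out")
  expect_error(resistance_from_voltage(5.5, circ), "v_out")
})
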