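test_that("preprocessing removes a constant curve entirely", {
  cur <- curve_from_fun(function(t) rep(3.3, length(t)))
  out <- preprocess(cur)
  expect_equal(length(out$samples), 15000L)
  expect_true(max(abs(out$samples)) < 1e-12)
})

test_that("the median stage damps a single-sample spike", {
  x <- rep(1, 15000)
  x[7000] <- 4
  cur <- response_curve(x)
  out <- preprocess(cur)
  expect_lt(max(out$samples) + 1, max(x))   # offset-corrected scale
})

test_that("a smooth peak survives filtering to within 1 percent", {
  b <- 0.7; p <- 2.2
  f <- function(t) b + (p - b) * exp(-((t - 70) / 15)^2)
  out <- preprocess(curve_from_fun(f))
  expect_equal(max(out$samples), p - b, tolerance = 0.01)
})

test_that("oversized filter windows are rejected", {
  cur <- response_curve(rnorm(100))
  expect_error(preprocess(cur, median_window = 101L), "window")
  expect_error(preprocess(cur, mean_window = 150L), "window")
  expect_error(preprocess(cur, median_window = 4L), "odd")
})

test_that("characteristic points are read at the fixed times and the maximum", {
  tri <- curve_from_fun(function(t) 2 - abs(t - 80) / 40)
  pts <- extract_points(tri)
  expect_equal(pts$VB, 2.0)
  expect_equal(pts$tB, 80)
  inc <- curve_from_fun(function(t) t / 120)
  pts <- extract_points(inc)
  expect_equal(pts$VB, pts$VC)          # maximum at the right edge
  expect_equal(pts$tB, 14999 / 125)     # final sample carries t = 120 s
})

test_that("characteristic points of a sine match the closed form", {
  pts <- extract_points(curve_from_fun(function(t) sin(pi * t / 120)))
  expect_equal(pts$VA, sin(pi / 3), tolerance = 1e-6)
  expect_equal(pts$VB, 1, tolerance = 1e-6)
  expect_equal(pts$tB, 60, tolerance = 1e-6)
  expect_equal(pts$VD, sin(pi / 2), tolerance = 1e-6)
})

test_that("curves shorter than 120 s are rejected", {
  expect_error(extract_points(response_curve(rnorm(1000), sample_rate = 125)),
               "120 s")
})

test_that("slope features equal their defining finite differences", {
  pts <- characteristic_points(VA = 1.0, VB = 2.0, VC = 1.1, VD = 1.2,
                               VE = 1.8, tB = 80)
  s <- compute_slopes(pts)
  expect_equal(unname(s["slope_AB"]), 0.025)
  expect_equal(unname(s["slope_DE"]), 0.015)
  expect_equal(unname(s["slope_DB"]), 0.04)
  expect_equal(unname(s["slope_BE"]), -0.01)
  # property: all seven quotients against independent arithmetic
  set.seed(11)
  for (i in 1:25) {
    v <- runif(5, 0, 3)
    tb <- runif(1, 41, 119)
    p <- characteristic_points(v[1], v[2], v[3], v[4], v[5], tB = tb)
    s <- compute_slopes(p)
    expect_equal(unname(s), c((v[2] - v[1]) / (tb - 40),
                              (v[3] - v[2]) / (120 - tb),
                              (v[4] - v[1]) / 20,
                              (v[5] - v[4]) / 40,
                              (v[3] - v[5]) / 20,
                              (v[5] - v[2]) / (100 - tb),
                              (v[2] - v[4]) / (tb - 60)),
                 tolerance = 1e-12)
  }
})

test_that("flat points give zero slopes and a degenerate gap is guarded", {
  flat <- characteristic_points(1, 1, 1, 1, 1, tB = 80)
  expect_true(all(compute_slopes(flat) == 0))
  deg <- characteristic_points(1, 2, 1, 1, 1, tB = 40)   # tB == tA
  expect_warning(s <- compute_slopes(deg), "degenerate")
  expect_equal(unname(s["slope_AB"]), 0)
})

test_that("difference features are VB minus each fixed point, nonnegative at a true maximum", {
  pts <- characteristic_points(VA = 1.0, VB = 2.0, VC = 1.1, VD = 1.2,
                               VE = 1.8, tB = 80)
  d <- compute_differences(pts)
  expect_equal(unname(d), c(1.0, 0.9, 0.8, 0.2))
  expect_true(all(compute_differences(
    characteristic_points(1, 1, 1, 1, 1, tB = 80)) == 0))
  set.seed(12)
  for (i in 1:25) {
    v <- runif(5, 0, 3)
    v[2] <- max(v) + runif(1)           # force VB to be the global maximum
    d <- compute_differences(
      characteristic_points(v[1], v[2], v[3], v[4], v[5], tB = 80))
    expect_true(all(d >= 0))
  }
})

test_that("sine characteristic points give dif_BC = 1 within 1e-6", {
  # 15001 samples put t = 120 s exactly on the grid, so VC = sin(pi) = 0
  pts <- extract_points(curve_from_fun(function(t) sin(pi * t / 120),
                                       n = 15001L))
  d <- compute_differences(pts)
  expect_equal(unname(d["dif_BC"]), 1.0, tolerance = 1e-6)
})

test_that("distribution statistics match hand-checked values", {
  s <- compute_statistics(c(1, 2, 3, 4, 5))
  expect_equal(unname(s["stat_mean"]), 3)
  expect_equal(unname(s["stat_median"]), 3)
  expect_equal(unname(s["stat_p75"]), 4)    # linear-interpolation quantile
  expect_equal(unname(s["stat_iqr"]), 2)
  expect_equal(unname(s["stat_sd"]), sd(1:5))
})

test_that("a constant signal has degenerate statistics equal to its value", {
  s <- compute_statistics(rep(2.5, 100))
  expect_equal(unname(s["stat_sd"]), 0)
  expect_equal(unname(s["stat_iqr"]), 0)
  expect_equal(unname(s["stat_cv"]), 0)
  expect_equal(unname(s["stat_skew"]), 0)
  expect_equal(unname(s["stat_mean"]), 2.5)
  expect_equal(unname(s["stat_median"]), 2.5)
  expect_equal(unname(s["stat_mode"]), 2.5)
})

test_that("a symmetric signal has zero skewness and the mode finds the heavy bin", {
  x <- c(seq(-1, 1, length.out = 1001))
  expect_equal(unname(compute_statistics(x)["stat_skew"]), 0,
               tolerance = 1e-9)
  set.seed(5)
  y <- c(runif(200, 0, 1), rep(0.555, 60))
  expect_equal(unname(compute_statistics(y)["stat_mode"]), 0.555,
               tolerance = 0.011)
})

test_that("ppm features invert the calibration and sentinel the rest", {
  models <- sensor_models()
  circ <- divider_circuit()
  m <- models[["TGS-2611E00"]]
  # VB chosen so the scaled resistance equals A for methane -> exactly 1 ppm
  A <- m$calibrations$methane$A
  vb <- circ$supply_voltage * circ$load_resistance /
    (circ$load_resistance + A * circ$reference_resistance)
  pts <- characteristic_points(0.1, vb, 0.1, 0.1, 0.1, tB = 80)
  ppm <- estimate_ppm_features(pts, m, circ)
  expect_equal(unname(ppm["ppm_methane"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(ppm["ppm_air"]), 0)       # alpha = 0, non-invertible
  expect_equal(unname(ppm["ppm_propane"]), 0)   # no published calibration
  expect_equal(unname(ppm["ppm_CO"]), 0)
  # out-of-range peak voltage sentinels everything
  bad <- characteristic_points(0, 0, 0, 0, 0, tB = 80)
  expect_true(all(estimate_ppm_features(bad, m, circ) == 0))
})

test_that("identifier codes are the documented formula and injective", {
  models <- enose_sensor_models()
  expect_equal(encode_identifier(models[1], 0), 0L)
  expect_equal(encode_identifier(models[4], 31), 331L)
  codes <- as.vector(outer(models, 0:31, Vectorize(encode_identifier)))
  expect_equal(length(unique(codes)), 128L)
  expect_error(encode_identifier("TGS-9999", 0), "unknown")
})

test_that("featurize returns the frozen 32-feature vector deterministically", {
  set.seed(21)
  cur <- curve_from_fun(function(t)
    0.5 + 1.2 * exp(-((t - 80) / 20)^2) + rnorm(length(t), 0, 0.005),
    model_id = "TGS-2620", socket_index = 5L)
  v1 <- featurize(cur)
  expect_length(v1, 32L)
  expect_named(v1, feature_names())
  expect_true(all(is.finite(v1)))
  expect_identical(v1, featurize(cur))
  expect_equal(unname(v1["id_code"]), 305)
})

test_that("a flat nonzero curve featurizes to zeros under the sentinel policy", {
  cur <- curve_from_fun(function(t) rep(1.5, length(t)))
  v <- featurize(cur)
  expect_true(all(v[c("slope_BC", "slope_AD", "slope_DE", "slope_EC",
                      "slope_BE", "slope_DB")] == 0))
  expect_true(all(v[paste0("dif_", c("BA", "BC", "BD", "BE"))] == 0))
  expect_equal(unname(v["stat_sd"]), 0)
  expect_true(all(v[paste0("ppm_", enose_gases())] == 0))
})
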