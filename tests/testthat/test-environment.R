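test_that("PPFD converts to irradiance by the source constant", {
  expect_equal(ppfd_to_irradiance(0), 0)
  expect_equal(ppfd_to_irradiance(120, 4.6), 120 / 4.6)
  expect_equal(ppfd_to_irradiance(120, 4.6) * 4.6, 120)
  expect_error(ppfd_to_irradiance(120, 0), "> 0")
})

test_that("VPD follows the Tetens curve", {
  expect_equal(vpd_from_temp_rh(23, 100), 0)
  expect_equal(vpd_from_temp_rh(10, 100), 0)
  expect_equal(vpd_from_temp_rh(23, 60),
               0.6108 * exp(17.27 * 23 / (23 + 237.3)) * 0.4, tolerance = 1e-12)
  expect_equal(vpd_from_temp_rh(23, 60), 1.124, tolerance = 1e-3)
  expect_equal(vpd_from_temp_rh(20, 73), 0.631, tolerance = 1e-3)
  expect_error(vpd_from_temp_rh(23, 120), "\\[0, 100\\]")
})

test_that("solar elevation follows declination + hour-angle geometry", {
  # equator near equinox, solar noon: sun nearly overhead
  expect_gt(solar_elevation(12, 0, 81), 88)
  # midnight: below the horizon
  expect_lt(solar_elevation(0, 37.8, 172), 0)
  # mid-latitude summer solstice noon
  expect_equal(solar_elevation(12, 37.8, 172), 90 - (37.8 - 23.44),
               tolerance = 0.5)
})

test_that("cloud attenuation follows the clear-sky okta model", {
  expect_equal(irradiance_under_cloud(-5, 0, 1), 0)
  expect_equal(irradiance_under_cloud(0, 0, 1), 0)
  expect_equal(irradiance_under_cloud(90, 0, scale = 1), 880)   # 910 - 30
  expect_equal(irradiance_under_cloud(90, 8, scale = 1), 880 * 0.25)
  expect_error(irradiance_under_cloud(45, 9, 1), "\\[0, 8\\]")
})

test_that("random walks are seeded, bounded and degenerate to constants", {
  c1 <- random_walk_cloud(1296, 0.5, seed = 5)
  c2 <- random_walk_cloud(1296, 0.5, seed = 5)
  expect_identical(c1, c2)
  expect_true(all(c1 >= 0 & c1 <= 8))
  expect_equal(random_walk_cloud(100, 1, step = 0, start = 3, seed = 1),
               rep(3, 101))
  v0 <- random_walk_vpd(100, 1, step = 0, start = 1.0, seed = 1)
  expect_equal(v0, rep(1.0, 101))
})

test_that("reflection keeps every stochastic series inside its bounds", {
  for (s in 1:200) {
    v <- random_walk_vpd(200, 1, step = 0.3, seed = s)   # large steps
    expect_true(all(v >= 0.5 & v <= 2.0))
    cl <- random_walk_cloud(200, 1, step = 2, seed = s)
    expect_true(all(cl >= 0 & cl <= 8))
  }
})

test_that("controlled-room trajectory is a 14 h / 10 h square wave", {
  w <- controlled_trajectory(controlled_schedule(), 48, 0.5)
  day1 <- w$time_h < 24
  expect_equal(sum(w$k_plus_w_m2[day1 & w$time_h < 23.75] > 0), 28)  # 14 h at 0.5 h
  expect_equal(max(w$k_plus_w_m2), 120 / 4.6)
  expect_equal(unique(w$vpd_kpa[w$time_h %% 24 < 14]),
               vpd_from_temp_rh(23, 60))
  expect_equal(unique(w$vpd_kpa[w$time_h %% 24 >= 14 & day1]),
               vpd_from_temp_rh(20, 73))
  expect_true(all(w$k_plus_w_m2[w$time_h %% 24 >= 14] == 0))
})

test_that("identical seeds reproduce the full weather trajectory bit for bit", {
  w1 <- stochastic_trajectory(336, 0.5, seed = 9)
  w2 <- stochastic_trajectory(336, 0.5, seed = 9)
  expect_identical(w1, w2)
  w3 <- stochastic_trajectory(336, 0.5, seed = 10)
  expect_false(identical(w1$k_plus_w_m2, w3$k_plus_w_m2))
  expect_true(all(w1$k_plus_w_m2 >= 0))
  expect_true(all(w1$vpd_kpa >= 0.5 & w1$vpd_kpa <= 2.0))
})

test_that("the calibrated irradiance scale brackets controlled-room transpiration", {
  p <- pakchoi
  sc <- calibrate_irradiance_scale(p, horizon = 1296, dt = 1, n_seeds = 3)
  expect_gt(sc, 0); expect_lte(sc, 1)
  ctrl <- controlled_trajectory(controlled_schedule(), 1296, 1)
  lai <- leaf_area_index(ctrl$time_h, p)
  qc <- transpiration_rate(ctrl$k_plus_w_m2, ctrl$vpd_kpa, lai, p)
  daily_ctrl <- tapply(qc, floor(ctrl$time_h / 24), mean)
  meds <- vapply(1:5, function(s) {
    w <- stochastic_trajectory(1296, 1, scale = sc, seed = s)
    lw <- leaf_area_index(w$time_h, p)
    qw <- transpiration_rate(w$k_plus_w_m2, w$vpd_kpa, lw, p)
    median(tapply(qw, floor(w$time_h / 24), mean))
  }, 0)
  expect_true(all(meds >= min(daily_ctrl) & meds <= max(daily_ctrl)))
})

test_that("weather CSV round-trips", {
  w <- stochastic_trajectory(48, 0.5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(w, path)
  w2 <- read_weather_csv(path)
  expect_equal(w2$k_plus_w_m2, w$k_plus_w_m2)
  expect_equal(w2$vpd_kpa, w$vpd_kpa)
})
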