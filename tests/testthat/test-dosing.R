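test_that("volume-based dosing tops up to the volume setpoint with feed solution", {
  pol <- dosing_policy("volume", feed = standard_composition(), v0 = 0.3)
  full <- volume_based_dose(standard_state(), pol)
  expect_equal(full$water, 0)
  expect_equal(unname(full$nutrients), rep(0, 6))
  st <- tank_state(0.27, conc = standard_composition())
  d <- volume_based_dose(st, pol)
  expect_equal(d$water, 0.03)
  expect_equal(d$nutrients[["NO3"]], 0.03 * 7.5)   # 0.225 mol
  # linear in the deficit
  st2 <- tank_state(0.24, conc = standard_composition())
  d2 <- volume_based_dose(st2, pol)
  expect_equal(d2$nutrients, 2 * d$nutrients)
  expect_warning(volume_based_dose(tank_state(0.31, conc = standard_composition()), pol),
                 "above setpoint")
})

test_that("time-based dosing is identical at every event", {
  pol <- dosing_policy("time", fixed_water = 0.01,
                       fixed_nutrients = nutrient_vector(0.1))
  d1 <- time_based_dose(pol); d2 <- time_based_dose(pol)
  expect_identical(d1, d2)
  # cumulative nutrients after k events = k * fixed dose
  st <- standard_state()
  for (i in 1:3) st <- apply_dose(st, time_based_dose(pol))
  expect_equal(st$mass, standard_state()$mass + 3 * nutrient_vector(0.1))
  # zero fixed dose leaves a trajectory untouched
  w <- controlled_trajectory(controlled_schedule(), 72, 0.5)
  pol0 <- dosing_policy("time", fixed_water = 0, fixed_nutrients = nutrient_vector(0))
  s_ref <- simulate_tank(standard_state(), pakchoi, w, 72, 0.5)
  s_dos <- simulate_tank(standard_state(), pakchoi, w, 72, 0.5, policy = pol0)
  expect_equal(s_dos$conc_mol_m3, s_ref$conc_mol_m3)
})

test_that("EC+volume dosing restores the equivalent and volume setpoints exactly", {
  pol <- dosing_policy("ec_volume", feed = standard_composition(), v0 = 0.3,
                       ec0 = 26.1)
  # untouched initial state: nothing to add
  d0 <- ec_volume_based_dose(standard_state(), pol)
  expect_equal(d0$water, 0)
  expect_equal(unname(d0$nutrients), rep(0, 6))
  # worked deficit: V = 0.25, EC = 24 -> D = 7.83 - 6.0 = 1.83 eq
  conc24 <- standard_composition() * (24 / 26.1)
  st <- tank_state(0.25, conc = conc24)
  d <- ec_volume_based_dose(st, pol)
  expect_equal(d$water, 0.05)
  expect_equal(sum(ion_valences() * d$nutrients), 1.83, tolerance = 1e-12)
  post <- apply_dose(st, d)
  expect_equal(post$volume, 0.3)
  expect_equal(total_equivalents(concentrations(post)) * post$volume,
               0.3 * 26.1, tolerance = 1e-12)
})

test_that("doses apply additively and never remove anything", {
  st <- standard_state()
  d1 <- list(water = 0.01, nutrients = nutrient_vector(0.2))
  d2 <- list(water = 0.02, nutrients = nutrient_vector(0.1))
  both <- apply_dose(apply_dose(st, d1), d2)
  once <- apply_dose(st, list(water = 0.03, nutrients = nutrient_vector(0.3)))
  expect_equal(both$volume, once$volume)
  expect_equal(both$mass, once$mass)
  id <- apply_dose(st, list(water = 0, nutrients = nutrient_vector(0)))
  expect_equal(id$mass, st$mass)
  expect_equal(concentrations(both), (st$mass + 0.3) / (st$volume + 0.03))
  expect_error(apply_dose(st, list(water = -0.1, nutrients = nutrient_vector(0))))
})

test_that("all controller dose logs are non-negative along stochastic runs", {
  w <- stochastic_trajectory(336, 0.5, seed = 21)
  st <- standard_state()
  pol_ec <- dosing_policy("ec_volume", feed = standard_composition(),
                          v0 = 0.3, ec0 = 26.1)
  pols <- list(
    dosing_policy("volume", feed = standard_composition(), v0 = 0.3),
    calibrate_time_policy(st, pakchoi, w, 336, 0.5, ec_policy = pol_ec),
    pol_ec)
  for (pol in pols) {
    sim <- simulate_tank(st, pakchoi, w, 336, 0.5, policy = pol)
    expect_true(all(sim$doses$water_m3 >= 0))
    expect_true(all(as.matrix(sim$doses[, paste0(ion_set(), "_mol")]) >= 0))
    expect_equal(emission_accounting(sim)$waste_m3, 0)
  }
})

test_that("the calibrated time policy matches the reference cumulative supply", {
  w <- stochastic_trajectory(336, 0.5, seed = 3)
  st <- standard_state()
  pol_ec <- dosing_policy("ec_volume", feed = standard_composition(),
                          v0 = 0.3, ec0 = 26.1)
  pol_tm <- calibrate_time_policy(st, pakchoi, w, 336, 0.5, ec_policy = pol_ec)
  ref <- simulate_tank(st, pakchoi, w, 336, 0.5, policy = pol_ec)
  tm <- simulate_tank(st, pakchoi, w, 336, 0.5, policy = pol_tm)
  expect_equal(tm$dosed_mol, ref$dosed_mol, tolerance = 1e-9)
  expect_equal(tm$dosed_water_m3, ref$dosed_water_m3, tolerance = 1e-9)
})
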