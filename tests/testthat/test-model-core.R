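test_that("root length follows the logistic curve", {
  p <- pakchoi
  p$rmax <- 1; p$K1 <- 9; p$k1 <- 0.01
  expect_equal(root_length(0, p), 1 / (1 + 9))
  expect_equal(root_length(log(9) / 0.01, p), 0.5)   # K1 e^{-k1 t} = 1
  expect_lt(root_length(2000, p), 1)
  expect_equal(root_length(1e6, p), 1, tolerance = 1e-9)
  tt <- seq(0, 2000, by = 50)
  expect_true(all(diff(root_length(tt, pakchoi)) > 0))
  expect_error(root_length(-1, p), ">= 0")
})

test_that("root surface area is a cylinder lateral surface", {
  expect_equal(root_surface_area(0, 5e-4), 0)
  expect_equal(root_surface_area(10, 5e-4), 2 * pi * 5e-4 * 10)
  expect_equal(root_surface_area(20, 5e-4), 2 * root_surface_area(10, 5e-4))
  expect_error(root_surface_area(-1, 5e-4), ">= 0")
})

test_that("LAI follows the Boltzmann sigmoid", {
  p <- pakchoi
  p$a_lai <- 3; p$x0 <- 600; p$b_lai <- 120
  expect_equal(leaf_area_index(600, p), 1.5)             # midpoint
  expect_equal(leaf_area_index(720, p), 3 / (1 + exp(-1)))  # = 2.193182...
  expect_equal(leaf_area_index(1e6, p), 3, tolerance = 1e-9)
  tt <- seq(0, 2000, by = 50)
  expect_true(all(diff(leaf_area_index(tt, pakchoi)) > 0))
})

test_that("uptake is Michaelis-Menten: zero at C=0, half-saturating at Km, bounded", {
  p <- pakchoi
  expect_equal(unname(uptake_rate(nutrient_vector(0), 0.1, p)), rep(0, 6))
  half <- uptake_rate(p$km, 0.1, p)
  expect_equal(unname(half), unname(0.1 * p$jmax / 2))
  # hand evaluation on one ion
  p1 <- p; p1$jmax[] <- 2e-5; p1$km[] <- 0.5
  expect_equal(uptake_rate(nutrient_vector(1), 0.01, p1)[["NO3"]],
               0.01 * 2e-5 * 1 / 1.5, tolerance = 1e-12)
  # saturation bound and monotonicity in C
  for (C in c(0.01, 0.1, 1, 10, 100)) {
    r <- uptake_rate(nutrient_vector(C), 0.1, p)
    expect_true(all(r < 0.1 * p$jmax))
  }
  r1 <- uptake_rate(nutrient_vector(1), 0.1, p)
  r2 <- uptake_rate(nutrient_vector(2), 0.1, p)
  expect_true(all(r2 > r1))
  # concavity: halfway value above the chord
  mid <- uptake_rate(nutrient_vector(1.5), 0.1, p)
  expect_true(all(mid > (r1 + r2) / 2))
})

test_that("transpiration has radiative and aerodynamic components", {
  p <- pakchoi
  expect_equal(transpiration_rate(100, 1.2, 0, p), 0)
  p$b_trs <- 5e-6
  expect_equal(transpiration_rate(0, 1, 2, p), 1e-5)   # night: aerodynamic only
  p$a_trs <- 1e-7; p$k_ext <- 0.7
  expect_equal(transpiration_rate(100, 1.2, 2, p),
               1e-7 * (1 - exp(-1.4)) * 100 + 5e-6 * 2 * 1.2, tolerance = 1e-12)
  # the alternative reading moves VPD into the exponent
  alt <- transpiration_rate(100, 1.2, 2, p, vpd_in_exponent = TRUE)
  expect_equal(alt, 1e-7 * (1 - exp(-0.7 * 2 * 1.2)) * 100 + 5e-6 * 2 * 1.2,
               tolerance = 1e-12)
  expect_error(transpiration_rate(-1, 1, 1, p), ">= 0")
})

test_that("system derivatives have the mass-balance structure", {
  st <- standard_state()
  p <- pakchoi
  # closed system: no light, no VPD, no uptake capacity
  p0 <- p; p0$jmax[] <- 0; p0$a_trs <- 1e-30; p0$b_trs <- 1e-30
  d <- system_derivatives(st, p0, k_plus = 0, vpd = 0)
  expect_equal(d$dV, 0, tolerance = 1e-32)
  expect_equal(unname(d$dM), rep(0, 6))
  # transpiring, absorbing tank: V falls, M falls, and dM = -J exactly
  d2 <- system_derivatives(st, p, k_plus = 26, vpd = 1.1)
  expect_lt(d2$dV, 0)
  expect_true(all(d2$dM < 0))
  expect_equal(unname(d2$dM), unname(-d2$J))
  expect_error(system_derivatives(tank_state(0, mass = nutrient_vector(1)), p, 0, 0),
               "volume > 0")
})

test_that("water balance: constant transpiration drains the tank linearly", {
  q <- 1e-5
  p <- constant_transpiration_params(q)          # 84 plants
  w <- constant_weather(101, k = 0, v = 1)
  # start at t = 1 h, past the (numerically instantaneous) LAI ramp
  st <- tank_state(0.3, conc = standard_composition(), t = 1)
  sim <- simulate_tank(st, p, w, horizon = 100, dt = 0.5)
  expect_equal(sim$volume_m3, 0.3 - 84 * q * (sim$time_h - 1), tolerance = 1e-6)
})

test_that("a closed tank with no fluxes stays exactly constant", {
  p0 <- pakchoi; p0$jmax[] <- 0; p0$a_trs <- 1e-30; p0$b_trs <- 1e-30
  w <- constant_weather(200, k = 30, v = 1.5)
  sim <- simulate_tank(standard_state(), p0, w, horizon = 200, dt = 1)
  expect_equal(sim$volume_m3, rep(0.3, length(sim$time_h)), tolerance = 1e-12)
  expect_equal(max(abs(sweep(sim$conc_mol_m3, 2, standard_composition()))), 0,
               tolerance = 1e-12)
})

test_that("mass is conserved along seeded stochastic runs with dosing", {
  w <- stochastic_trajectory(336, 0.5, seed = 11)
  pol <- dosing_policy("ec_volume", feed = standard_composition(), v0 = 0.3,
                       ec0 = 26.1)
  sim <- simulate_tank(standard_state(), pakchoi, w, horizon = 336, dt = 0.5,
                       policy = pol)
  expect_lt(max(mass_balance_residual(sim)), 1e-6)
})

test_that("the literal concentration form drops the dilution term", {
  # with transpiration but no uptake, mass form concentrates the solution,
  # the literal form leaves concentration unchanged
  p0 <- constant_transpiration_params(1e-5)
  p0$jmax[] <- 0
  w <- constant_weather(168, k = 0, v = 1)
  sm <- simulate_tank(standard_state(), p0, w, 168, dt = 0.5, ode_form = "mass")
  sc <- simulate_tank(standard_state(), p0, w, 168, dt = 0.5,
                      ode_form = "concentration")
  n <- length(sm$time_h)
  expect_gt(sm$conc_mol_m3[n, "NO3"], 7.5)
  expect_equal(unname(sc$conc_mol_m3[n, "NO3"]), 7.5, tolerance = 1e-9)
})

test_that("weekly replacement resets the tank and logs the waste", {
  st <- standard_state()
  same <- weekly_replacement(st, standard_composition(), 0.3)
  expect_equal(same$volume, st$volume)
  expect_equal(same$mass, st$mass)
  expect_equal(attr(same, "waste")$volume, 0.3)
  st2 <- tank_state(0.25, conc = standard_composition() * 0.6)
  fresh <- weekly_replacement(st2, standard_composition(), 0.3)
  expect_equal(fresh$mass[["NO3"]], 7.5 * 0.3)   # = 2.25 mol
  expect_equal(total_equivalents(concentrations(fresh)), 26.1)
})

test_that("weekly replacement produces the sawtooth volume pattern", {
  w <- controlled_trajectory(controlled_schedule(), 1296, 0.5)
  sim <- simulate_tank(standard_state(), pakchoi, w, horizon = 1296, dt = 0.5,
                       replacement = list(interval_h = 168, volume = 0.3,
                                          composition = standard_composition()))
  idx_repl <- which(sim$time_h %in% seq(168, 1176, by = 168))
  expect_true(all(sim$volume_m3[idx_repl - 1] < 0.3))    # drawn down in-week
  expect_equal(sim$volume_m3[idx_repl], rep(0.3, length(idx_repl)))  # reset
  expect_true(all(diff(sim$cum_transpiration_m3) >= 0))
  expect_gt(sim$replacement_waste_m3, 0)
})

test_that("constant sub-capacity influx converges to the Michaelis-Menten steady state", {
  # U_max = n * RSA * Jmax = 2e-3 mol/h, F = 1e-3 -> C* = Km F/(U_max - F) = 0.5
  km <- 0.5
  p <- species_preset("pakchoi")
  p$jmax[] <- 2e-3 / 84; p$km[] <- km
  p$a_trs <- 1e-30; p$b_trs <- 1e-30
  w <- constant_weather(6000, k = 0, v = 1, dt = 2)
  sim <- simulate_tank(tank_state(0.3, conc = nutrient_vector(2)), p, w,
                       horizon = 6000, dt = 1,
                       inflow = list(water = 0, nutrients = nutrient_vector(1e-3)),
                       rsa_override = 1)
  cstar <- km * 1e-3 / (2e-3 - 1e-3)
  cfin <- sim$conc_mol_m3[nrow(sim$conc_mol_m3), ]
  expect_equal(unname(cfin), rep(cstar, 6), tolerance = 1e-3)
})

test_that("the fixed-step integrator matches an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  p <- pakchoi
  w <- controlled_trajectory(controlled_schedule(), 168, 0.1)
  sim <- simulate_tank(standard_state(), p, w, 168, dt = 0.1)
  kf <- approxfun(w$time_h, w$k_plus_w_m2, rule = 2)
  vf <- approxfun(w$time_h, w$vpd_kpa, rule = 2)
  rhs <- function(t, y, parms) {
    d <- system_derivatives(tank_state(y[1], mass = y[2:7], t = t), p, kf(t), vf(t))
    list(c(d$dV, d$dM))
  }
  ref <- deSolve::ode(c(0.3, standard_composition() * 0.3), c(0, 168), rhs,
                      NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10)
  fin <- ref[nrow(ref), -1]
  n <- length(sim$time_h)
  expect_equal(sim$volume_m3[n], unname(fin[1]), tolerance = 1e-4)
  expect_equal(unname(sim$conc_mol_m3[n, ]), unname(fin[2:7] / fin[1]),
               tolerance = 1e-4)
})

test_that("a drying tank aborts with a diagnostic", {
  p <- constant_transpiration_params(5e-5)   # 84 * 5e-5 = 4.2e-3 m3/h
  w <- constant_weather(200, k = 0, v = 1)
  expect_error(simulate_tank(tank_state(0.2, conc = standard_composition()), p,
                             w, horizon = 200, dt = 0.5),
               "ran dry")
})

test_that("trajectory CSV round-trips the recorded series", {
  w <- controlled_trajectory(controlled_schedule(), 48, 0.5)
  sim <- simulate_tank(standard_state(), pakchoi, w, 48, dt = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(sim, path)
  df <- read.csv(path)
  expect_equal(df$volume_m3, sim$volume_m3)
  expect_equal(df$conc_NO3_mol_m3, unname(sim$conc_mol_m3[, "NO3"]))
})
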