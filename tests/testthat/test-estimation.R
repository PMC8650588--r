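test_that("the N/W method computes per-plant absorption from bookend measurements", {
  same <- nw_absorption(standard_composition(), 0.3,
                        standard_composition(), 0.3, 84)
  expect_equal(unname(same$uptake_mol_plant), rep(0, 6))
  expect_equal(same$transpiration_m3_plant, 0)
  ci <- standard_composition(); cf <- standard_composition()
  ci["NO3"] <- 7.5; cf["NO3"] <- 5.0
  rec <- nw_absorption(ci, 0.3, cf, 0.25, 84)
  expect_equal(rec$uptake_mol_plant[["NO3"]], (2.25 - 1.25) / 84)  # 0.011905
  expect_equal(rec$transpiration_m3_plant, 0.05 / 84)              # 5.952e-4
  # apparent efflux is flagged, not an error
  neg <- nw_absorption(nutrient_vector(1), 0.3, nutrient_vector(2), 0.3, 84)
  expect_true(all(neg$negative_flag))
})

test_that("rmse matches the closed form and is permutation invariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 5)), sqrt(4 / 3))
  perm <- c(3, 1, 2)
  expect_equal(rmse(c(1, 2, 3)[perm], c(1, 2, 5)[perm]), sqrt(4 / 3))
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("campaign records validate their physical invariants", {
  wk <- data.frame(t_start_h = c(0, 168), t_end_h = c(168, 336),
                   v_init_m3 = 0.3, v_final_m3 = 0.28)
  cm <- matrix(1, 2, 6)
  expect_s3_class(measurement_campaign("x", 84, 0.3, wk, cm, cm),
                  "measurement_campaign")
  bad <- wk; bad$v_final_m3 <- 0.31
  expect_error(measurement_campaign("x", 84, 0.3, bad, cm, cm), "v_final")
  expect_error(measurement_campaign("x", 84, 0.3, wk[1, ], cm[1, , drop = FALSE],
                                    cm[1, , drop = FALSE]))
})

test_that("simulated campaigns decouple uptake from transpiration", {
  spec <- synthetic_spec(species = "pakchoi", conc_noise_sd = 0, vol_noise_sd = 0,
                         weeks = 3, horizon_h = 504)
  truth <- sample_ground_truth(spec, seed = 2)[[1]]
  camp <- generate_campaign(truth, spec, seed = 3)
  p0 <- truth; p0$jmax[] <- 0
  sim0 <- simulate_campaign(p0, camp, dt = 1)
  expect_equal(max(abs(sim0$cum_uptake_mol_plant)), 0)
  sim1 <- simulate_campaign(truth, camp, dt = 1)
  expect_equal(sim0$cum_transpiration_m3_plant, sim1$cum_transpiration_m3_plant,
               tolerance = 1e-9)
  expect_true(all(diff(sim1$cum_transpiration_m3_plant) > 0))
})

test_that("N/W on noiseless synthetic weeks equals the integrator's uptake integral", {
  spec <- synthetic_spec(species = "pakchoi", conc_noise_sd = 0, vol_noise_sd = 0,
                         weeks = 3, horizon_h = 504)
  truth <- sample_ground_truth(spec, seed = 5)[[1]]
  camp <- generate_campaign(truth, spec, seed = 6, dt = 0.5)
  meas <- campaign_accumulations(camp)
  sim <- simulate_campaign(truth, camp, dt = 0.5)
  expect_equal(meas$cum_uptake_mol_plant, sim$cum_uptake_mol_plant,
               tolerance = 1e-6)
  expect_equal(meas$cum_transpiration_m3_plant, sim$cum_transpiration_m3_plant,
               tolerance = 1e-6)
})

test_that("progress-curve fitting recovers the truth from a noiseless campaign", {
  spec <- synthetic_spec(species = "pakchoi", conc_noise_sd = 0, vol_noise_sd = 0)
  truth <- sample_ground_truth(spec, seed = 7)[[1]]
  camp <- generate_campaign(truth, spec, seed = 8)
  fit <- fit_params(camp, base_params = species_preset("pakchoi"),
                    n_starts = 3, seed = 1, dt = 2)
  rel <- abs(fit$params$jmax - truth$jmax) / truth$jmax
  expect_true(all(rel < 0.05))
  # uptake RMSE under 1% of the final accumulated uptake, per ion
  final_up <- campaign_accumulations(camp)$cum_uptake_mol_plant[spec$weeks, ]
  expect_true(all(fit$rmse_uptake_mol_plant < 0.01 * final_up))
  expect_true(all(fit$params$jmax >= 1e-7 & fit$params$jmax <= 5e-3))
})

test_that("fitting is reproducible for a fixed seed", {
  spec <- synthetic_spec(species = "pakchoi", weeks = 4, horizon_h = 672)
  truth <- sample_ground_truth(spec, seed = 12)[[1]]
  camp <- generate_campaign(truth, spec, seed = 13)
  f1 <- fit_params(camp, species_preset("pakchoi"), n_starts = 2, seed = 4, dt = 4)
  f2 <- fit_params(camp, species_preset("pakchoi"), n_starts = 2, seed = 4, dt = 4)
  expect_identical(f1$params$jmax, f2$params$jmax)
  expect_identical(f1$params$a_trs, f2$params$a_trs)
})

test_that("excluding the truth from the bounds worsens the achieved fit", {
  spec <- synthetic_spec(species = "pakchoi", conc_noise_sd = 0, vol_noise_sd = 0,
                         weeks = 4, horizon_h = 672)
  truth <- sample_ground_truth(spec, seed = 21)[[1]]
  camp <- generate_campaign(truth, spec, seed = 22)
  free_fit <- fit_params(camp, species_preset("pakchoi"), n_starts = 2, seed = 1,
                         dt = 4)
  # cap jmax far below the truth
  capped <- fit_params(camp, species_preset("pakchoi"), n_starts = 2, seed = 1,
                       dt = 4, bounds = list(jmax = c(1e-7, 1e-4)))
  expect_gt(capped$rmse_uptake_mol_plant[["NO3"]],
            free_fit$rmse_uptake_mol_plant[["NO3"]])
})

test_that("campaign CSV round-trips the full record", {
  spec <- synthetic_spec(species = "pakchoi", weeks = 3, horizon_h = 504)
  camp <- generate_campaign(sample_ground_truth(spec, seed = 1)[[1]], spec, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_campaign_csv(camp, path)
  back <- read_campaign_csv(path)
  expect_equal(back$weeks$v_final_m3, camp$weeks$v_final_m3)
  expect_equal(unname(back$c_init), unname(camp$c_init))
  expect_equal(back$n_plants, camp$n_plants)
})
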