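#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline uses, overridable via
#' [read_config()]. Sizes default to a desk-scale run; the full study
#' conditions (54-day horizon, 84 plants, 0.3 m3 tank) are the generator
#' defaults.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    tank = list(v0 = 0.3),
    synthetic = list(species = c("pakchoi", "lacinato_kale", "curly_kale"),
                     n_plants = 84L, weeks = 8L, horizon_h = 1296,
                     conc_noise_sd = 0.03, vol_noise_sd = 0.01),
    estimation = list(n_starts = 4L, dt = 2, maxit = 300),
    dosing = list(interval_h = 24, n_replicates = 20L, horizon = 1296,
                  dt = 0.5, scale = 0.05),
    optimization = list(seeds = 1:3, horizon = 672, dt = 0.5,
                        n_starts = 2L, maxit = 80, feed_ec = 26.1),
    integrator = list(dt = 0.5, ode_form = "mass")
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]; keys not in
#' the file keep their defaults.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the four stages end to end with one seed: (1) generate
#' synthetic ground truth and noisy weekly campaigns, (2) fit transpiration
#' and uptake parameters per species by progress-curve analysis, (3)
#' compare the three dosing controllers over a stochastic weather ensemble,
#' (4) optimize the dosing composition under EC+volume dosing. All
#' artifacts (campaign CSVs, parameter JSON, %CV tables, dose logs,
#' optimization result, run report) are written under `out_dir`.
#'
#' @param config configuration list (see [default_config()]) or the path
#'   to a YAML file.
#' @param out_dir output directory (created if missing).
#' @param seed overrides `config$seed` when given.
#' @return the report list, invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, config = config)

  ## stage 1: synthetic data ------------------------------------------------
  spec <- synthetic_spec(species = config$synthetic$species,
                         n_plants = config$synthetic$n_plants,
                         v0 = config$tank$v0,
                         weeks = config$synthetic$weeks,
                         horizon_h = config$synthetic$horizon_h,
                         conc_noise_sd = config$synthetic$conc_noise_sd,
                         vol_noise_sd = config$synthetic$vol_noise_sd)
  truth <- tryCatch(sample_ground_truth(spec, seed = config$seed),
                    error = function(e) stop("stage generate-data: ", conditionMessage(e)))
  campaigns <- list()
  for (sp in spec$species) {
    campaigns[[sp]] <- tryCatch(
      generate_campaign(truth[[sp]], spec,
                        seed = config$seed + match(sp, spec$species),
                        dt = config$integrator$dt),
      error = function(e) stop("stage generate-data: ", conditionMessage(e)))
    write_campaign_csv(campaigns[[sp]], file.path(out_dir, paste0("campaign_", sp, ".csv")))
  }
  jsonlite::write_json(lapply(truth, unclass),
                       file.path(out_dir, "ground_truth_params.json"),
                       auto_unbox = TRUE, digits = NA)

  ## stage 2: estimation ----------------------------------------------------
  fits <- list()
  for (sp in spec$species) {
    fits[[sp]] <- tryCatch(
      fit_params(campaigns[[sp]], base_params = species_preset(sp, spec$n_plants),
                 n_starts = config$estimation$n_starts,
                 seed = config$seed, dt = config$estimation$dt,
                 maxit = config$estimation$maxit),
      error = function(e) stop("stage fit: ", conditionMessage(e)))
  }
  jsonlite::write_json(
    lapply(fits, function(f) list(params = unclass(f$params),
                                  rmse_transpiration = f$rmse_transpiration_m3_plant,
                                  rmse_uptake = as.list(f$rmse_uptake_mol_plant),
                                  km_flat = as.list(f$km_flat))),
    file.path(out_dir, "fitted_params.json"), auto_unbox = TRUE, digits = NA)
  report$fit <- lapply(fits, function(f) list(
    rmse_transpiration_m3_plant = f$rmse_transpiration_m3_plant,
    rmse_uptake_mol_plant = as.list(f$rmse_uptake_mol_plant)))

  ## stage 3: dosing comparison (highest-capacity species) -------------------
  rep_params <- fits[[spec$species[1]]]$params
  cmp <- tryCatch(
    compare_dosing(rep_params, n_replicates = config$dosing$n_replicates,
                   v0 = config$tank$v0, interval_h = config$dosing$interval_h,
                   horizon = config$dosing$horizon, dt = config$dosing$dt,
                   seed = config$seed, scale = config$dosing$scale),
    error = function(e) stop("stage compare-dosing: ", conditionMessage(e)))
  utils::write.csv(as.data.frame(cmp$cv_pct),
                   file.path(out_dir, "dosing_cv_pct.csv"))
  utils::write.csv(cmp$dose_rates, file.path(out_dir, "dose_rates.csv"),
                   row.names = FALSE)
  report$dosing_cv_pct <- apply(cmp$cv_pct, 1, mean)

  ## stage 4: composition optimization ---------------------------------------
  standard <- composition_to_ratio(standard_composition())
  scen <- dosing_scenario(rep_params, v0 = config$tank$v0,
                          ec0 = total_equivalents(standard_composition()),
                          feed_ec = config$optimization$feed_ec,
                          interval_h = config$dosing$interval_h,
                          horizon = config$optimization$horizon,
                          dt = config$optimization$dt,
                          seeds = config$optimization$seeds,
                          scale = config$dosing$scale)
  opt <- tryCatch(
    optimize_dosing_composition(standard, scen, seed = config$seed,
                                n_starts = config$optimization$n_starts,
                                maxit = config$optimization$maxit),
    error = function(e) stop("stage optimize: ", conditionMessage(e)))
  jsonlite::write_json(list(ratio = list(anions = as.list(opt$ratio$anions),
                                         cations = as.list(opt$ratio$cations)),
                            feed_mol_m3 = as.list(opt$feed),
                            objective = opt$objective,
                            objective_standard = opt$objective_standard),
                       file.path(out_dir, "optimization.json"),
                       auto_unbox = TRUE, digits = NA)
  # ternary coordinates for plotting (anion and cation simplices)
  utils::write.csv(data.frame(
    group = c("anions", "cations"),
    a = c(opt$ratio$anions[1], opt$ratio$cations[1]),
    b = c(opt$ratio$anions[2], opt$ratio$cations[2]),
    c = c(opt$ratio$anions[3], opt$ratio$cations[3])),
    file.path(out_dir, "optimized_ternary.csv"), row.names = FALSE)
  report$optimization <- list(objective = opt$objective,
                              objective_standard = opt$objective_standard)

  ## Jmax ratio variability across species ----------------------------------
  jr <- jmax_ratio_cv(lapply(fits, function(f) f$params))
  report$jmax_cv <- list(mean_cv_jmax_pct = jr$mean_cv_jmax_pct,
                         mean_cv_ratio_pct = jr$mean_cv_ratio_pct)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
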