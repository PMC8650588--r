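#' Specification of a synthetic depletion experiment
#'
#' Describes the synthetic ground truth and measurement process used to
#' emulate a 54-day, weekly-replacement, three-species depletion campaign:
#' which species presets to draw, how much the true parameters are
#' jittered around the presets, how the fresh weekly solutions scatter
#' around the standard composition, and the measurement noise of the
#' recorded concentrations and volumes.
#'
#' @param species character vector of [species_preset()] names.
#' @param n_plants plants per species tank.
#' @param v0 tank volume (m3).
#' @param weeks number of measurement periods (>= 2). With the default
#'   54-day horizon the last period is the 120 h remainder after seven full
#'   weeks.
#' @param horizon_h campaign length (h); default 1296 (54 days).
#' @param param_jitter_sd relative log-normal jitter of the true uptake and
#'   transpiration parameters around the preset values.
#' @param conc_noise_sd relative Gaussian measurement noise on
#'   concentrations (default 0.03, analytical-chemistry grade).
#' @param vol_noise_sd relative Gaussian measurement noise on volumes
#'   (default 0.01).
#' @param comp_mean,comp_sd mean and SD (mol m-3) of the sampled weekly
#'   initial compositions; default the standard composition and its stated
#'   scatter.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(species = c("pakchoi", "lacinato_kale", "curly_kale"),
                           n_plants = 84L, v0 = 0.3, weeks = 8L,
                           horizon_h = 1296,
                           param_jitter_sd = 0.05,
                           conc_noise_sd = 0.03, vol_noise_sd = 0.01,
                           comp_mean = standard_composition(),
                           comp_sd = standard_composition_sd()) {
  stopifnot(weeks >= 2, conc_noise_sd >= 0, vol_noise_sd >= 0,
            param_jitter_sd >= 0, v0 > 0, horizon_h > 0)
  out <- list(species = species, n_plants = as.integer(n_plants), v0 = v0,
              weeks = as.integer(weeks), horizon_h = horizon_h,
              param_jitter_sd = param_jitter_sd,
              conc_noise_sd = conc_noise_sd, vol_noise_sd = vol_noise_sd,
              comp_mean = nutrient_vector(comp_mean),
              comp_sd = nutrient_vector(comp_sd))
  class(out) <- "synthetic_spec"
  out
}

# week boundaries: full 168 h weeks with the remainder folded into the last
week_boundaries <- function(weeks, horizon_h) {
  b <- seq(0, by = 168, length.out = weeks)
  b <- c(b, horizon_h)
  if (b[weeks + 1] <= b[weeks]) stop("horizon too short for that many weeks")
  data.frame(t_start_h = b[-(weeks + 1)], t_end_h = b[-1])
}

#' Sample ground-truth parameter sets
#'
#' Draws one true [plant_params()] per species by applying mild
#' multiplicative log-normal jitter to the species presets. The preset
#' ordering of uptake and transpiration capacity (pakchoi > lacinato kale >
#' curly kale) is preserved by construction because the jitter is small
#' relative to the preset spacing.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; identical seeds give identical draws.
#' @return named list of [plant_params()], one per species.
#' @export
sample_ground_truth <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  out <- lapply(spec$species, function(sp) {
    p <- species_preset(sp, n_plants = spec$n_plants)
    jit <- function(x) x * exp(stats::rnorm(length(x), sd = spec$param_jitter_sd))
    p$jmax <- jit(p$jmax)
    p$km <- jit(p$km)
    p$a_trs <- jit(p$a_trs); p$b_trs <- jit(p$b_trs)
    p$a_lai <- jit(p$a_lai); p$x0 <- jit(p$x0)
    p
  })
  stats::setNames(out, spec$species)
}

#' Sample a fresh initial composition
#'
#' Per-ion Gaussian draw around the standard composition, truncated at a
#' small positive floor, emulating the week-to-week scatter of freshly
#' prepared solutions around Steiner-proximal ratios.
#'
#' @param spec a [synthetic_spec()].
#' @return nutrient vector of concentrations (mol m-3). Uses the current
#'   RNG stream (seed managed by the caller).
#' @export
sample_initial_composition <- function(spec) {
  conc <- stats::rnorm(6, mean = spec$comp_mean, sd = spec$comp_sd)
  nutrient_vector(pmax(conc, 0.05 * spec$comp_mean))
}

#' Generate a noisy synthetic measurement campaign
#'
#' Simulates each week with the tank model under the controlled-room
#' schedule from a freshly sampled initial composition, then perturbs the
#' recorded initial/final concentrations and volumes with relative
#' Gaussian measurement noise. At zero noise the records are exactly the
#' simulated values, so the N/W method applied to a record reproduces the
#' integrator's own uptake integral.
#'
#' @param params true [plant_params()] for the species.
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (composition sampling and noise).
#' @param schedule the [controlled_schedule()] driving transpiration.
#' @param dt integration step (h).
#' @return a [measurement_campaign()].
#' @export
generate_campaign <- function(params, spec, seed = 1L,
                              schedule = controlled_schedule(), dt = 0.5) {
  stopifnot(inherits(params, "plant_params"), inherits(spec, "synthetic_spec"))
  wb <- week_boundaries(spec$weeks, spec$horizon_h)
  weather <- controlled_trajectory(schedule, spec$horizon_h, dt = dt)
  set.seed(seed)
  W <- spec$weeks
  v_init_true <- numeric(W); v_final_true <- numeric(W)
  c_init_true <- matrix(0, W, 6); c_final_true <- matrix(0, W, 6)
  for (w in seq_len(W)) {
    comp <- sample_initial_composition(spec)
    st0 <- tank_state(spec$v0, conc = comp, t = wb$t_start_h[w])
    sim <- simulate_tank(st0, params, weather,
                         horizon = wb$t_end_h[w] - wb$t_start_h[w], dt = dt)
    last <- length(sim$time_h)
    v_init_true[w] <- spec$v0
    v_final_true[w] <- sim$volume_m3[last]
    c_init_true[w, ] <- comp
    c_final_true[w, ] <- sim$conc_mol_m3[last, ]
  }
  noisy <- function(x, sd_rel) {
    if (sd_rel == 0) x else x * (1 + stats::rnorm(length(x), sd = sd_rel))
  }
  v_init <- noisy(v_init_true, spec$vol_noise_sd)
  v_final <- noisy(v_final_true, spec$vol_noise_sd)
  v_final <- pmin(v_final, v_init)   # water only leaves by transpiration
  c_init <- pmax(noisy(c_init_true, spec$conc_noise_sd), 0)
  c_final <- pmax(noisy(c_final_true, spec$conc_noise_sd), 0)
  measurement_campaign(params$species, spec$n_plants, spec$v0,
                       cbind(wb, v_init_m3 = v_init, v_final_m3 = v_final),
                       c_init, c_final)
}
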