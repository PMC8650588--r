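#' Percent coefficient of variation
#'
#' `100 * sd(x) / mean(x)` (sample standard deviation).
#'
#' @param x numeric vector of replicate values, length >= 2, non-zero mean.
#' @return %CV.
#' @export
percent_cv <- function(x) {
  if (length(x) < 2L) stop("need >= 2 replicates")
  m <- mean(x)
  if (m == 0) stop("zero mean")
  100 * stats::sd(x) / m
}

#' Compare dosing controllers over a stochastic weather ensemble
#'
#' Runs the volume-, time- and EC+volume-based controllers over the same
#' set of stochastic weather replicates and summarizes the reproducibility
#' of the root-zone nutrient concentrations as percent coefficients of
#' variation across replicates. The time-based dose is calibrated against
#' an EC+volume reference on the first weather replicate so all three
#' controllers supply comparable cumulative amounts.
#'
#' Two %CV variants are computed: the headline `cv_pct` takes the %CV
#' across replicates at each sampled time and averages over time; the
#' `cv_trajectory_pct` variant first averages each replicate's trajectory
#' over time and takes the %CV of those means.
#'
#' @param params a [plant_params()] or list of them.
#' @param n_replicates number of weather replicates (>= 2; 50 is a useful
#'   ensemble size).
#' @param v0 tank volume setpoint (m3).
#' @param feed feed solution (mol m-3); the EC setpoint is its total
#'   equivalents.
#' @param interval_h dosing interval (h).
#' @param horizon,dt simulation length and step (h).
#' @param seed base weather seed (replicate i uses `seed + i - 1`).
#' @param scale irradiance scaling factor for [stochastic_trajectory()].
#' @param sample_every_h spacing of concentration samples entering the
#'   %CV (h).
#' @param ... further arguments to [stochastic_trajectory()] (random-walk
#'   steps, bounds, site geometry).
#' @return object of class `ensemble_summary`: per-method-and-ion %CV
#'   matrices, per-method dose-rate series (total equivalents per event,
#'   averaged over replicates), waste accounting (zero for all three
#'   controllers) and the seeds used.
#' @export
compare_dosing <- function(params, n_replicates = 50, v0 = 0.3,
                           feed = standard_composition(), interval_h = 24,
                           horizon = 1296, dt = 0.5, seed = 1L, scale = 0.05,
                           sample_every_h = 6, ...) {
  stopifnot(n_replicates >= 2)
  seeds <- seed + seq_len(n_replicates) - 1L
  ec0 <- total_equivalents(feed)
  weather <- lapply(seeds, function(s) {
    stochastic_trajectory(horizon, dt, scale = scale, seed = s, ...)
  })
  state0 <- tank_state(v0, conc = feed)
  pol_vol <- dosing_policy("volume", interval_h, feed = feed, v0 = v0)
  pol_ec <- dosing_policy("ec_volume", interval_h, feed = feed, v0 = v0, ec0 = ec0)
  pol_time <- calibrate_time_policy(state0, params, weather[[1]], horizon, dt,
                                    ec_policy = pol_ec)
  policies <- list(volume = pol_vol, time = pol_time, ec_volume = pol_ec)

  step <- max(1L, round(sample_every_h / dt))
  z <- ion_valences()
  cv_pct <- matrix(NA_real_, 3, 6, dimnames = list(names(policies), ion_set()))
  cv_traj <- cv_pct
  dose_rates <- list()
  for (m in names(policies)) {
    conc_arr <- NULL
    eq_events <- NULL
    for (r in seq_len(n_replicates)) {
      sim <- simulate_tank(state0, params, weather[[r]], horizon, dt,
                           policy = policies[[m]])
      idx <- seq(1, length(sim$time_h), by = step)
      if (is.null(conc_arr)) {
        conc_arr <- array(NA_real_, c(n_replicates, length(idx), 6))
      }
      conc_arr[r, , ] <- sim$conc_mol_m3[idx, ]
      if (!is.null(sim$doses)) {
        eq <- as.numeric(as.matrix(sim$doses[, paste0(ion_set(), "_mol")]) %*% z)
        if (is.null(eq_events)) eq_events <- matrix(0, n_replicates, nrow(sim$doses))
        eq_events[r, ] <- eq
      }
    }
    cv_t <- apply(conc_arr, c(2, 3), function(x) 100 * stats::sd(x) / mean(x))
    cv_pct[m, ] <- colMeans(cv_t, na.rm = TRUE)
    traj_means <- apply(conc_arr, c(1, 3), mean)
    cv_traj[m, ] <- apply(traj_means, 2, percent_cv)
    if (!is.null(eq_events)) {
      dose_rates[[m]] <- data.frame(
        method = m, event = seq_len(ncol(eq_events)),
        time_h = interval_h * seq_len(ncol(eq_events)),
        eq_per_event = colMeans(eq_events),
        eq_per_event_rep1 = eq_events[1, ])
    }
  }
  out <- list(cv_pct = cv_pct, cv_trajectory_pct = cv_traj,
              dose_rates = do.call(rbind, dose_rates),
              policies = policies, seeds = seeds,
              waste_m3 = c(volume = 0, time = 0, ec_volume = 0))
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("ensemble_summary (% CV across replicates, time-averaged)\n")
  print(round(x$cv_pct, 2))
  cat("  mean per method:",
      paste(sprintf("%s %.2f", rownames(x$cv_pct), rowMeans(x$cv_pct)), collapse = ", "), "\n")
  invisible(x)
}

#' Trend statistics of a dose-rate series
#'
#' Classifies the qualitative dosing-rate signature of a controller from a
#' single-replicate dose-event log: overall coefficient of variation of
#' the event sizes, Kendall rank correlation with time (trend), and the
#' residual CV after removing a linear trend (irregularity around the
#' trend). A near-zero CV is `"constant"`; a clear monotone trend with a
#' smooth residual is `"increasing"`/`"decreasing"`; a large residual CV
#' marks the series `"irregular"`.
#'
#' @param eq_per_event numeric series of total equivalents per dosing
#'   event for one replicate.
#' @param irregular_cv_pct residual-CV threshold (percent) above which the
#'   series is classified irregular; default 10.
#' @return list with `cv_pct`, `kendall_tau`, `residual_cv_pct` and
#'   `classification` (`"constant"`, `"increasing"`, `"decreasing"` or
#'   `"irregular"`).
#' @export
dose_rate_signature <- function(eq_per_event, irregular_cv_pct = 10) {
  stopifnot(length(eq_per_event) >= 3)
  m <- mean(eq_per_event)
  cv <- if (m == 0) 0 else 100 * stats::sd(eq_per_event) / m
  tau <- if (stats::sd(eq_per_event) == 0) 0 else
    suppressWarnings(stats::cor(seq_along(eq_per_event), eq_per_event,
                                method = "kendall"))
  # roughness around a smooth trend: loess residuals (the trend itself may
  # be sigmoidal, so linear detrending would not do)
  idx <- seq_along(eq_per_event)
  resid <- stats::residuals(stats::loess(eq_per_event ~ idx, span = 0.5, degree = 2))
  residual_cv <- if (m == 0) 0 else 100 * stats::sd(resid) / m
  cls <- if (cv < 1) "constant"
  else if (residual_cv > irregular_cv_pct) "irregular"
  else if (tau > 0.5) "increasing"
  else if (tau < -0.5) "decreasing"
  else "irregular"
  list(cv_pct = cv, kendall_tau = tau, residual_cv_pct = residual_cv,
       classification = cls)
}

#' Emission accounting of a simulation
#'
#' Total water and nutrients discarded by a run. The three dosing
#' controllers never remove solution, so their waste is identically zero;
#' only the weekly full-replacement protocol emits waste.
#'
#' @param sim a `tank_simulation`.
#' @return list with `waste_m3` and `waste_mol` (nutrient vector).
#' @export
emission_accounting <- function(sim) {
  stopifnot(inherits(sim, "tank_simulation"))
  list(waste_m3 = sim$replacement_waste_m3,
       waste_mol = sim$replacement_waste_mol)
}
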