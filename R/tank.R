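#' Tank state
#'
#' State of the well-mixed nutrient tank at one time point: elapsed time,
#' water volume and per-ion nutrient mass. Concentration is the derived
#' view `mass / volume`.
#'
#' @param volume water volume (m3), > 0.
#' @param conc nutrient vector of concentrations (mol m-3); give either
#'   `conc` or `mass`.
#' @param mass nutrient vector of masses (mol).
#' @param t elapsed time (h).
#' @return object of class `tank_state` with fields `t`, `volume`, `mass`.
#' @examples
#' st <- tank_state(0.3, conc = standard_composition())
#' concentrations(st)
#' @export
tank_state <- function(volume, conc = NULL, mass = NULL, t = 0) {
  stopifnot(volume >= 0, t >= 0)
  if (is.null(mass) == is.null(conc)) stop("give exactly one of conc or mass")
  if (is.null(mass)) mass <- nutrient_vector(conc) * volume
  mass <- nutrient_vector(mass)
  out <- list(t = t, volume = volume, mass = mass)
  class(out) <- "tank_state"
  out
}

#' @rdname tank_state
#' @param state a `tank_state`.
#' @export
concentrations <- function(state) {
  stopifnot(inherits(state, "tank_state"))
  if (state$volume <= 0) stop("concentration undefined at zero volume")
  state$mass / state$volume
}

#' @export
print.tank_state <- function(x, ...) {
  cat(sprintf("tank_state at t = %.1f h: V = %.4f m3\n", x$t, x$volume))
  if (x$volume > 0) {
    cat("  conc (mol m-3):",
        paste(sprintf("%s %.3f", names(x$mass), x$mass / x$volume), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full replacement of the tank solution
#'
#' Discards the current tank contents and refills to volume `v0` with a
#' fresh solution of composition `new_composition`. The discarded water and
#' nutrient mass are attached as the `"waste"` attribute for emission
#' accounting (replacement is the only operation in the package that emits
#' waste).
#'
#' @param state a [tank_state()].
#' @param new_composition nutrient vector of the fresh solution (mol m-3).
#' @param v0 refill volume (m3), > 0.
#' @return the refreshed `tank_state`; `attr(, "waste")` holds
#'   `list(volume, mass)` of the discarded contents.
#' @export
weekly_replacement <- function(state, new_composition, v0) {
  stopifnot(inherits(state, "tank_state"), v0 > 0)
  new_composition <- nutrient_vector(new_composition)
  out <- tank_state(v0, conc = new_composition, t = state$t)
  attr(out, "waste") <- list(volume = state$volume, mass = state$mass)
  out
}

#' System mass-balance derivatives
#'
#' Right-hand side of the coupled tank balance at one instant:
#' \deqn{dV/dt = Q_{in} - n\,Q_{trs}, \qquad
#'       dM^I/dt = F_{in}^I - n\,J^I(C),}
#' with \eqn{C = M/V}, uptake from [uptake_rate()] at the current root
#' surface area, and transpiration carrying no nutrients. `F_in` is the
#' nutrient inflow in mol h-1 (equal to `Q_in * C_in` for a liquid feed).
#'
#' @param state a [tank_state()] with `volume > 0`.
#' @param params a [plant_params()] object (or list of them for a
#'   multi-species tank).
#' @param k_plus irradiance (W m-2).
#' @param vpd vapour pressure deficit (kPa).
#' @param q_in water inflow (m3 h-1).
#' @param f_in nutrient inflow (nutrient vector, mol h-1); default zero.
#' @param rsa_override optional fixed root surface area (m2), bypassing the
#'   root growth curve (used for steady-state experiments).
#' @return list with `dV` (m3 h-1), `dM` (mol h-1) and the total uptake
#'   flux `J` (mol h-1, all plants).
#' @export
system_derivatives <- function(state, params, k_plus, vpd, q_in = 0,
                               f_in = NULL, rsa_override = NULL) {
  stopifnot(inherits(state, "tank_state"))
  if (state$volume <= 0) stop("system_derivatives needs volume > 0")
  if (is.null(f_in)) f_in <- nutrient_vector(0)
  plist <- if (inherits(params, "plant_params")) list(params) else params
  conc <- pmax(state$mass, 0) / state$volume
  qt <- 0
  J <- nutrient_vector(0)
  for (p in plist) {
    rsa <- if (is.null(rsa_override)) {
      root_surface_area(root_length(state$t, p), p$r0)
    } else rsa_override
    lai <- leaf_area_index(state$t, p)
    qt <- qt + p$n_plants * transpiration_rate(k_plus, vpd, lai, p)
    J <- J + p$n_plants * uptake_rate(conc, rsa, p)
  }
  list(dV = q_in - qt, dM = f_in - J, J = J)
}

# linear interpolation of a weather trajectory onto an arbitrary grid
interp_weather <- function(weather, t_out) {
  list(
    k_plus = stats::approx(weather$time_h, weather$k_plus_w_m2, t_out, rule = 2)$y,
    vpd = stats::approx(weather$time_h, weather$vpd_kpa, t_out, rule = 2)$y
  )
}

#' Simulate the hydroponic tank
#'
#' Fixed-step classical Runge-Kutta (RK4) integration of the tank mass
#' balance under a weather trajectory, with dosing and replacement handled
#' as instantaneous events at grid times. By default the integrator evolves
#' nutrient MASS, which conserves mass exactly up to integration error;
#' `ode_form = "concentration"` instead integrates concentration with the
#' dilution term dropped (the literal single-equation tank balance), kept
#' for comparison.
#'
#' Transpiration and root growth are state-independent, so the per-plant
#' transpiration and uptake-capacity schedules are precomputed on the
#' half-step grid before the main loop.
#'
#' @param state0 initial [tank_state()].
#' @param params a [plant_params()] or list of them (multi-species tank).
#' @param weather a `weather_trajectory` covering `[0, horizon]`.
#' @param horizon simulation length (h).
#' @param dt step (h), > 0; the horizon is rounded to a whole number of steps.
#' @param policy optional [dosing_policy()]; doses are applied at multiples
#'   of the policy interval (excluding t = 0 and the final time).
#' @param inflow optional continuous feed: `list(water = m3/h, nutrients =
#'   nutrient vector mol/h)`.
#' @param replacement optional full-replacement protocol:
#'   `list(interval_h, volume, composition)` where `composition` is a
#'   nutrient vector or a function(week_index) returning one.
#' @param ode_form `"mass"` (default) or `"concentration"`.
#' @param vpd_in_exponent see [transpiration_rate()].
#' @param rsa_override optional fixed root surface area (m2).
#' @param clip_tol abort if clipped (negative) nutrient mass exceeds this
#'   fraction of the mass throughput; default 0.01.
#' @return object of class `tank_simulation`: a list with the time grid,
#'   volume and concentration trajectories, system transpiration rate and
#'   cumulative transpiration/uptake, dose and replacement (waste) logs,
#'   conservation accounting and the configuration snapshot.
#' @export
simulate_tank <- function(state0, params, weather, horizon, dt = 0.1,
                          policy = NULL, inflow = NULL, replacement = NULL,
                          ode_form = c("mass", "concentration"),
                          vpd_in_exponent = FALSE, rsa_override = NULL,
                          clip_tol = 0.01) {
  ode_form <- match.arg(ode_form)
  stopifnot(inherits(state0, "tank_state"), dt > 0, horizon > 0)
  plist <- if (inherits(params, "plant_params")) list(params) else params
  n_steps <- round(horizon / dt)
  t0 <- state0$t   # simulation runs over [t0, t0 + horizon] in absolute time
  t_grid <- t0 + seq(0, by = dt, length.out = n_steps + 1)
  t_half <- t0 + seq(0, by = dt / 2, length.out = 2 * n_steps + 1)

  env <- interp_weather(weather, t_half)
  # per-species schedules on the half grid
  QT <- numeric(length(t_half))          # system transpiration (m3 h-1)
  A <- vector("list", length(plist))     # 6 x K uptake capacity n*RSA*Jmax
  km <- vector("list", length(plist))
  for (s in seq_along(plist)) {
    p <- plist[[s]]
    lai <- leaf_area_index(t_half, p)
    rsa <- if (is.null(rsa_override)) {
      root_surface_area(root_length(t_half, p), p$r0)
    } else rep(rsa_override, length(t_half))
    QT <- QT + p$n_plants *
      transpiration_rate(env$k_plus, env$vpd, lai, p, vpd_in_exponent)
    A[[s]] <- outer(p$jmax, p$n_plants * rsa)
    km[[s]] <- p$km
  }

  w_in <- if (is.null(inflow)) 0 else inflow$water
  f_in <- if (is.null(inflow)) nutrient_vector(0) else nutrient_vector(inflow$nutrients)

  V <- state0$volume
  M <- state0$mass                        # mass form state
  Cs <- if (V > 0) M / V else nutrient_vector(0)  # concentration form state
  mass_form <- ode_form == "mass"

  # records
  vol_rec <- numeric(n_steps + 1); vol_rec[1] <- V
  conc_rec <- matrix(NA_real_, n_steps + 1, 6, dimnames = list(NULL, ion_set()))
  conc_rec[1, ] <- if (V > 0) (if (mass_form) M / V else Cs) else NA_real_
  qtrs_rec <- QT[seq(1, length(t_half), by = 2)]
  cum_T <- numeric(n_steps + 1)
  cum_U <- matrix(0, n_steps + 1, 6, dimnames = list(NULL, ion_set()))
  dosed_water <- 0; dosed_mol <- nutrient_vector(0)
  inflow_water <- 0; inflow_mol <- nutrient_vector(0)
  repl_added_mol <- nutrient_vector(0); repl_waste_mol <- nutrient_vector(0)
  repl_waste_m3 <- 0; repl_added_m3 <- 0
  clipped <- 0
  dose_log <- list(); repl_log <- list()

  uptake_flux <- function(Cvec, k) {
    Cc <- pmax(Cvec, 0)
    J <- 0
    for (s in seq_along(A)) J <- J + A[[s]][, k] * Cc / (km[[s]] + Cc)
    J
  }

  week_idx <- 0L
  for (i in seq_len(n_steps)) {
    t_i <- t_grid[i]
    ## --- events at the current grid time (never at the start time) ---
    if (!is.null(replacement) && t_i > t0 &&
        abs(t_i / replacement$interval_h - round(t_i / replacement$interval_h)) < 1e-9) {
      week_idx <- week_idx + 1L
      comp <- replacement$composition
      if (is.function(comp)) comp <- comp(week_idx)
      repl_log[[length(repl_log) + 1L]] <- c(time_h = t_i, waste_m3 = V,
        stats::setNames(if (mass_form) M else Cs * V, paste0("waste_", ion_set(), "_mol")))
      repl_waste_m3 <- repl_waste_m3 + V
      repl_waste_mol <- repl_waste_mol + (if (mass_form) M else Cs * V)
      V <- replacement$volume
      M <- nutrient_vector(comp) * V
      Cs <- nutrient_vector(comp)
      repl_added_m3 <- repl_added_m3 + V
      repl_added_mol <- repl_added_mol + M
      vol_rec[i] <- V
      conc_rec[i, ] <- if (mass_form) M / V else Cs
    }
    if (!is.null(policy) && t_i > t0 &&
        abs(t_i / policy$interval_h - round(t_i / policy$interval_h)) < 1e-9) {
      st <- tank_state(V, mass = if (mass_form) M else Cs * V, t = t_i)
      dose <- compute_dose(st, policy)
      if (dose$water > 0 || any(dose$nutrients > 0)) {
        if (mass_form) {
          M <- M + dose$nutrients
        } else {
          Cs <- (Cs * V + dose$nutrients) / (V + dose$water)
        }
        V <- V + dose$water
        dosed_water <- dosed_water + dose$water
        dosed_mol <- dosed_mol + dose$nutrients
        vol_rec[i] <- V
        conc_rec[i, ] <- if (mass_form) M / V else Cs
      }
      dose_log[[length(dose_log) + 1L]] <- c(time_h = t_i, water_m3 = dose$water,
        stats::setNames(dose$nutrients, paste0(ion_set(), "_mol")))
    }

    ## --- one RK4 step over [t_i, t_i + dt] ---
    k0 <- 2L * i - 1L; kh <- 2L * i; k2 <- 2L * i + 1L
    if (V <= 1e-9) stop("tank ran dry at t = ", t_i, " h")
    if (mass_form) {
      J1 <- uptake_flux(M / V, k0)
      V1 <- V + dt / 2 * (w_in - QT[k0])
      J2 <- uptake_flux((M + dt / 2 * (f_in - J1)) / V1, kh)
      J3 <- uptake_flux((M + dt / 2 * (f_in - J2)) / V1, kh)
      V3 <- V + dt * (w_in - QT[kh])
      J4 <- uptake_flux((M + dt * (f_in - J3)) / V3, k2)
      Jbar <- (J1 + 2 * J2 + 2 * J3 + J4) / 6
      M <- M + dt * (f_in - Jbar)
      V <- V + dt * (w_in - (QT[k0] + 4 * QT[kh] + QT[k2]) / 6)
      if (any(M < 0)) { clipped <- clipped + sum(-M[M < 0]); M[M < 0] <- 0 }
      cum_U[i + 1, ] <- cum_U[i, ] + dt * Jbar
    } else {
      J1 <- uptake_flux(Cs, k0)
      V1 <- V + dt / 2 * (w_in - QT[k0])
      C2 <- Cs + dt / 2 * (f_in - J1) / V
      J2 <- uptake_flux(C2, kh)
      C3 <- Cs + dt / 2 * ((f_in - J2) / V1)
      J3 <- uptake_flux(C3, kh)
      V3 <- V + dt * (w_in - QT[kh])
      C4 <- Cs + dt * ((f_in - J3) / V1)
      J4 <- uptake_flux(C4, k2)
      Jbar <- (J1 + 2 * J2 + 2 * J3 + J4) / 6
      # literal form: V dC/dt = F_in - J, dilution term dropped
      Cs <- Cs + dt * (f_in - Jbar) / V
      V <- V + dt * (w_in - (QT[k0] + 4 * QT[kh] + QT[k2]) / 6)
      if (any(Cs < 0)) { clipped <- clipped + sum(-Cs[Cs < 0]) * V; Cs[Cs < 0] <- 0 }
      cum_U[i + 1, ] <- cum_U[i, ] + dt * Jbar
    }
    if (V <= 0) stop("tank ran dry at t = ", t_grid[i + 1], " h")
    inflow_water <- inflow_water + dt * w_in
    inflow_mol <- inflow_mol + dt * f_in
    cum_T[i + 1] <- cum_T[i] + dt * (QT[k0] + 4 * QT[kh] + QT[k2]) / 6
    vol_rec[i + 1] <- V
    conc_rec[i + 1, ] <- if (mass_form) M / V else Cs
  }

  throughput <- max(sum(state0$mass), sum(dosed_mol + inflow_mol))
  if (clipped > clip_tol * throughput) {
    stop("clipped nutrient mass exceeds ", clip_tol * 100,
         "% of throughput; reduce dt")
  }
  if (clipped > 0) {
    warning(sprintf("clipped %.3g mol of negative nutrient mass at the zero bound", clipped))
  }

  out <- list(
    time_h = t_grid,
    volume_m3 = vol_rec,
    conc_mol_m3 = conc_rec,
    q_trs_m3_h = qtrs_rec,
    cum_transpiration_m3 = cum_T,
    cum_uptake_mol = cum_U,
    doses = if (length(dose_log)) as.data.frame(do.call(rbind, dose_log)) else NULL,
    replacements = if (length(repl_log)) as.data.frame(do.call(rbind, repl_log)) else NULL,
    initial_mass_mol = state0$mass,
    final_mass_mol = if (mass_form) M else Cs * V,
    dosed_water_m3 = dosed_water, dosed_mol = dosed_mol,
    inflow_water_m3 = inflow_water, inflow_mol = inflow_mol,
    replacement_added_mol = repl_added_mol, replacement_waste_mol = repl_waste_mol,
    replacement_added_m3 = repl_added_m3, replacement_waste_m3 = repl_waste_m3,
    clipped_mol = clipped,
    n_plants_total = sum(vapply(plist, function(p) p$n_plants, 0L)),
    dt = dt, ode_form = ode_form,
    weather_seed = attr(weather, "seed"),
    params = plist
  )
  class(out) <- "tank_simulation"
  out
}

#' @export
print.tank_simulation <- function(x, ...) {
  cat(sprintf("tank_simulation: %.0f h at dt = %.3g h (%s form), %d plants\n",
              max(x$time_h), x$dt, x$ode_form, x$n_plants_total))
  cat(sprintf("  final V = %.4f m3; cumulative transpiration %.4f m3; %d doses\n",
              x$volume_m3[length(x$volume_m3)],
              x$cum_transpiration_m3[length(x$cum_transpiration_m3)],
              if (is.null(x$doses)) 0L else nrow(x$doses)))
  invisible(x)
}

#' Per-ion mass-balance residual of a simulation
#'
#' Re-accumulates the fluxes stored in a `tank_simulation` and reports, per
#' ion, \eqn{|M_{final} - M_{initial} - dosed - inflow + absorbed| /
#' \max(M_{initial}, dosed + inflow)}. For the mass-form integrator this is
#' bounded by integration round-off; the literal concentration form does
#' not conserve mass and shows a real residual whenever the volume changes.
#'
#' @param sim a `tank_simulation`.
#' @return named numeric vector of relative residuals per ion.
#' @export
mass_balance_residual <- function(sim) {
  stopifnot(inherits(sim, "tank_simulation"))
  absorbed <- sim$cum_uptake_mol[nrow(sim$cum_uptake_mol), ]
  supplied <- sim$dosed_mol + sim$inflow_mol +
    sim$replacement_added_mol - sim$replacement_waste_mol
  resid <- abs(sim$final_mass_mol - sim$initial_mass_mol - supplied + absorbed)
  denom <- pmax(pmax(sim$initial_mass_mol, abs(supplied) + absorbed), 1e-12)
  resid / denom
}

#' Write a simulation trajectory as tidy CSV
#'
#' Columns: `time_h`, `volume_m3`, one `conc_<ion>_mol_m3` column per ion,
#' `q_trs_m3_h` (system transpiration) and a `dosed` flag at event times.
#'
#' @param sim a `tank_simulation`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(sim, path) {
  stopifnot(inherits(sim, "tank_simulation"))
  df <- data.frame(time_h = sim$time_h, volume_m3 = sim$volume_m3)
  conc <- sim$conc_mol_m3
  colnames(conc) <- paste0("conc_", ion_set(), "_mol_m3")
  df <- cbind(df, conc)
  df$q_trs_m3_h <- sim$q_trs_m3_h
  df$dosed <- sim$time_h %in% (if (is.null(sim$doses)) numeric(0) else sim$doses$time_h)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
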