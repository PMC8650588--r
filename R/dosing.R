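#' Nutrient dosing policy
#'
#' Configuration of one of the three fertigation controllers compared by
#' the package:
#' \describe{
#'   \item{`"volume"`}{tops the tank back up to its initial volume `v0`
#'     with the feed solution, so nutrient influx tracks the transpired
#'     water volume.}
#'   \item{`"time"`}{adds a fixed water volume and fixed nutrient amounts
#'     at every dosing time, regardless of tank state.}
#'   \item{`"ec_volume"`}{restores the tank's total ionic equivalents to
#'     `v0 * ec0` (the EC setpoint expressed as eq m-3) with nutrients in
#'     the feed's composition ratio, and separately tops water up to `v0`.}
#' }
#' None of the controllers ever removes solution: closed-system,
#' emission-free operation.
#'
#' @param kind `"volume"`, `"time"` or `"ec_volume"`.
#' @param interval_h hours between dosing times (> 0, default 24).
#' @param feed nutrient vector (mol m-3). For `"volume"` this is the feed
#'   solution concentration; for `"ec_volume"` only its composition ratio
#'   matters (it is renormalized on the equivalent scale).
#' @param v0 volume setpoint (m3).
#' @param ec0 total-equivalent setpoint (eq m-3); required for
#'   `"ec_volume"`.
#' @param fixed_water water per event (m3) for `"time"`.
#' @param fixed_nutrients nutrient vector (mol per event) for `"time"`.
#' @return object of class `dosing_policy`.
#' @export
dosing_policy <- function(kind = c("volume", "time", "ec_volume"),
                          interval_h = 24, feed = standard_composition(),
                          v0 = 0.3, ec0 = NULL,
                          fixed_water = 0, fixed_nutrients = nutrient_vector(0)) {
  kind <- match.arg(kind)
  stopifnot(interval_h > 0, v0 > 0, fixed_water >= 0)
  feed <- nutrient_vector(feed)
  fixed_nutrients <- nutrient_vector(fixed_nutrients)
  if (kind != "time" && all(feed == 0)) stop("feed composition must not be all zero")
  if (kind == "ec_volume") {
    if (is.null(ec0)) stop("ec_volume policy needs an ec0 setpoint")
    stopifnot(ec0 > 0)
  }
  out <- list(kind = kind, interval_h = interval_h, feed = feed, v0 = v0,
              ec0 = ec0, fixed_water = fixed_water,
              fixed_nutrients = fixed_nutrients)
  class(out) <- "dosing_policy"
  out
}

#' Controller dose computations
#'
#' Compute the dose a controller would apply to a given tank state.
#' `compute_dose()` dispatches on the policy kind; the three per-controller
#' functions are exported for direct use and testing.
#'
#' @param state a [tank_state()].
#' @param policy a [dosing_policy()].
#' @return a dose: `list(water = m3, nutrients = nutrient vector mol)`,
#'   both non-negative.
#' @export
compute_dose <- function(state, policy) {
  stopifnot(inherits(policy, "dosing_policy"))
  switch(policy$kind,
         volume = volume_based_dose(state, policy),
         time = time_based_dose(policy),
         ec_volume = ec_volume_based_dose(state, policy))
}

#' @rdname compute_dose
#' @export
volume_based_dose <- function(state, policy) {
  stopifnot(inherits(state, "tank_state"))
  deficit <- policy$v0 - state$volume
  if (deficit < 0) {
    warning("tank volume above setpoint; zero dose")
    deficit <- 0
  }
  list(water = deficit, nutrients = deficit * policy$feed)
}

#' @rdname compute_dose
#' @export
time_based_dose <- function(policy) {
  list(water = policy$fixed_water, nutrients = policy$fixed_nutrients)
}

#' @rdname compute_dose
#' @export
ec_volume_based_dose <- function(state, policy) {
  stopifnot(inherits(state, "tank_state"))
  z <- ion_valences()
  current_eq <- sum(z * state$mass)            # total equivalents in the tank (eq)
  deficit_eq <- policy$v0 * policy$ec0 - current_eq
  water <- max(0, policy$v0 - state$volume)
  if (deficit_eq <= 0) {
    return(list(water = water, nutrients = nutrient_vector(0)))
  }
  feed_per_eq <- policy$feed / sum(z * policy$feed)  # mol per equivalent
  list(water = water, nutrients = deficit_eq * feed_per_eq)
}

#' Apply a dose to a tank state
#'
#' Instantaneous, mass-additive application: volume and nutrient masses are
#' incremented; nothing is removed.
#'
#' @param state a [tank_state()].
#' @param dose a dose as returned by [compute_dose()].
#' @return the updated `tank_state`.
#' @export
apply_dose <- function(state, dose) {
  stopifnot(inherits(state, "tank_state"), dose$water >= 0,
            all(dose$nutrients >= 0))
  tank_state(state$volume + dose$water,
             mass = state$mass + nutrient_vector(dose$nutrients),
             t = state$t)
}

#' Calibrate the time-based controller against an EC+volume reference run
#'
#' The time-based controller has no feedback; a fair comparison supplies
#' the same cumulative water and nutrients as an EC+volume-based reference
#' simulation, spread uniformly over the dosing events. This helper runs
#' the reference and returns the matching `"time"` policy.
#'
#' @param state0,params,weather,horizon,dt as in [simulate_tank()].
#' @param ec_policy the reference [dosing_policy()] of kind `"ec_volume"`.
#' @return a [dosing_policy()] of kind `"time"`.
#' @export
calibrate_time_policy <- function(state0, params, weather, horizon, dt = 0.5,
                                  ec_policy) {
  stopifnot(ec_policy$kind == "ec_volume")
  ref <- simulate_tank(state0, params, weather, horizon, dt, policy = ec_policy)
  n_events <- if (is.null(ref$doses)) 1L else nrow(ref$doses)
  dosing_policy("time", interval_h = ec_policy$interval_h,
                feed = ec_policy$feed, v0 = ec_policy$v0,
                fixed_water = ref$dosed_water_m3 / n_events,
                fixed_nutrients = ref$dosed_mol / n_events)
}
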