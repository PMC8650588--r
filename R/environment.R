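#' Convert PPFD to shortwave irradiance
#'
#' @param ppfd photosynthetic photon flux density (umol m-2 s-1), >= 0.
#' @param k_conv conversion constant of the light source (umol J-1);
#'   default 4.6 for a warm-white-class source.
#' @return irradiance (W m-2).
#' @export
ppfd_to_irradiance <- function(ppfd, k_conv = 4.6) {
  if (k_conv <= 0) stop("k_conv must be > 0")
  if (any(ppfd < 0)) stop("ppfd must be >= 0")
  ppfd / k_conv
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' Tetens saturation curve
#' \eqn{e_s(T) = 0.6108\, e^{17.27 T / (T + 237.3)}} kPa, so
#' \eqn{VPD = e_s(T)(1 - RH/100)}.
#'
#' @param temp_c air temperature (deg C).
#' @param rh relative humidity (percent, 0-100).
#' @return VPD (kPa), >= 0.
#' @examples
#' vpd_from_temp_rh(23, 60) # daytime growing-room setpoint, ~1.124 kPa
#' @export
vpd_from_temp_rh <- function(temp_c, rh) {
  if (any(rh < 0 | rh > 100)) stop("rh must be in [0, 100]")
  es <- 0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
  es * (1 - rh / 100)
}

#' Solar elevation angle
#'
#' Standard declination + hour-angle solar geometry. Solar time is taken as
#' `t_h` modulo 24 with solar noon at 12 h.
#'
#' @param t_h elapsed time (h); day-of-year advances every 24 h.
#' @param latitude latitude (degrees).
#' @param day_of_year day of year at `t_h = 0`.
#' @return elevation (degrees); negative at night.
#' @export
solar_elevation <- function(t_h, latitude, day_of_year) {
  doy <- day_of_year + floor(t_h / 24)
  decl <- 23.44 * sin(2 * pi * (284 + doy) / 365)
  hour_angle <- 15 * ((t_h %% 24) - 12)
  rad <- pi / 180
  sin_h <- sin(latitude * rad) * sin(decl * rad) +
    cos(latitude * rad) * cos(decl * rad) * cos(hour_angle * rad)
  asin(pmin(1, pmax(-1, sin_h))) / rad
}

#' Ground-level irradiance under cloud cover
#'
#' Kasten-Czeplak-type clear-sky model attenuated by total cloud cover:
#' \deqn{K^+ = s \cdot \max(0, A \sin h - B)(1 - 0.75 (N/8)^{3.4}),}
#' with elevation h, cloud cover N in oktas and an overall scaling factor s
#' used to bring the open-sky irradiance onto the scale of a low-light
#' growing room.
#'
#' @param elevation solar elevation (degrees).
#' @param cloud_okta total cloud cover (okta, 0-8).
#' @param scale irradiance scaling factor in (0, 1].
#' @param A,B clear-sky constants (W m-2); defaults 910 and 30.
#' @return irradiance (W m-2), 0 at or below the horizon.
#' @export
irradiance_under_cloud <- function(elevation, cloud_okta, scale = 0.05,
                                   A = 910, B = 30) {
  if (any(cloud_okta < 0 | cloud_okta > 8)) stop("cloud_okta must be in [0, 8]")
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  clear <- pmax(0, A * sin(pmin(90, pmax(0, elevation)) * pi / 180) - B)
  clear[elevation <= 0] <- 0
  scale * clear * (1 - 0.75 * (cloud_okta / 8)^3.4)
}

# reflect a series into [lo, hi] (billiard reflection, avoids boundary
# sticking that clamping would cause)
reflect_into <- function(x, lo, hi) {
  period <- 2 * (hi - lo)
  y <- (x - lo) %% period
  lo + ifelse(y > (hi - lo), period - y, y)
}

#' Random-walk cloud cover series
#'
#' Gaussian random walk with increment sd `step * sqrt(dt)`, reflected into
#' the okta range \[0, 8\].
#'
#' @param horizon length of the series (h).
#' @param dt time step (h), > 0.
#' @param step random-walk step scale (okta per sqrt hour).
#' @param start initial cloud cover (okta).
#' @param seed integer seed; the series is reproducible given the seed.
#' @return numeric series of length `horizon/dt + 1` on the grid
#'   `seq(0, horizon, by = dt)`.
#' @export
random_walk_cloud <- function(horizon, dt, step = 0.5, start = 4, seed = 1L) {
  stopifnot(dt > 0, start >= 0, start <= 8)
  n <- round(horizon / dt)
  set.seed(seed)
  inc <- c(0, stats::rnorm(n, sd = step * sqrt(dt)))
  reflect_into(start + cumsum(inc), 0, 8)
}

#' Random-walk vapour pressure deficit series
#'
#' Gaussian random walk reflected into `bounds` (default 0.5-2.0 kPa).
#'
#' @inheritParams random_walk_cloud
#' @param step random-walk step scale (kPa per sqrt hour).
#' @param bounds lower/upper VPD bounds (kPa), ordered and positive.
#' @param start initial VPD (kPa); defaults to the midpoint of `bounds`.
#' @return numeric series on the grid `seq(0, horizon, by = dt)`.
#' @export
random_walk_vpd <- function(horizon, dt, step = 0.05, bounds = c(0.5, 2.0),
                            start = mean(bounds), seed = 1L) {
  stopifnot(dt > 0, length(bounds) == 2, bounds[1] > 0, bounds[2] > bounds[1],
            start >= bounds[1], start <= bounds[2])
  n <- round(horizon / dt)
  set.seed(seed)
  inc <- c(0, stats::rnorm(n, sd = step * sqrt(dt)))
  reflect_into(start + cumsum(inc), bounds[1], bounds[2])
}

#' Controlled growing-room environment schedule
#'
#' Day/night square-wave setpoints of a controlled room: PPFD during the
#' photoperiod, temperature and relative humidity by day and night. The
#' defaults mirror a low-light leafy-greens room: 120 umol m-2 s-1 for 14 h,
#' 23 C / 60 % RH by day and 20 C / 73 % RH by night.
#'
#' @param photoperiod_h lit hours per 24 h day.
#' @param ppfd daytime PPFD (umol m-2 s-1).
#' @param k_conv PPFD-to-irradiance conversion constant (umol J-1).
#' @param temp_day,temp_night air temperature setpoints (deg C).
#' @param rh_day,rh_night relative humidity setpoints (percent).
#' @return object of class `environment_schedule`.
#' @export
controlled_schedule <- function(photoperiod_h = 14, ppfd = 120, k_conv = 4.6,
                                temp_day = 23, temp_night = 20,
                                rh_day = 60, rh_night = 73) {
  stopifnot(photoperiod_h > 0, photoperiod_h < 24)
  out <- list(photoperiod_h = photoperiod_h, ppfd = ppfd, k_conv = k_conv,
              temp_day = temp_day, temp_night = temp_night,
              rh_day = rh_day, rh_night = rh_night)
  class(out) <- "environment_schedule"
  out
}

weather_trajectory <- function(time_h, k_plus, vpd, cloud_okta = NA_real_,
                               seed = NA_integer_) {
  stopifnot(all(diff(time_h) > 0), all(k_plus >= 0))
  out <- data.frame(time_h = time_h, k_plus_w_m2 = k_plus, vpd_kpa = vpd,
                    cloud_okta = cloud_okta)
  attr(out, "seed") <- seed
  class(out) <- c("weather_trajectory", "data.frame")
  out
}

#' Deterministic controlled-room weather trajectory
#'
#' Square-wave irradiance and VPD repeating every 24 h, built from a
#' [controlled_schedule()]. Lights are on for the first `photoperiod_h`
#' hours of each day.
#'
#' @param schedule an [controlled_schedule()] object.
#' @param horizon trajectory length (h).
#' @param dt grid spacing (h).
#' @return a `weather_trajectory` data frame with columns `time_h`,
#'   `k_plus_w_m2`, `vpd_kpa`, `cloud_okta` (NA for the controlled room).
#' @export
controlled_trajectory <- function(schedule, horizon, dt = 0.5) {
  stopifnot(inherits(schedule, "environment_schedule"), dt > 0)
  time_h <- seq(0, horizon, by = dt)
  is_day <- (time_h %% 24) < schedule$photoperiod_h
  k_plus <- ifelse(is_day, ppfd_to_irradiance(schedule$ppfd, schedule$k_conv), 0)
  vpd <- ifelse(is_day,
                vpd_from_temp_rh(schedule$temp_day, schedule$rh_day),
                vpd_from_temp_rh(schedule$temp_night, schedule$rh_night))
  weather_trajectory(time_h, k_plus, vpd)
}

#' Stochastic open-weather trajectory
#'
#' Solar irradiance from a clear-sky elevation model under random-walk
#' cloud cover, and a bounded random-walk VPD. Both walks are driven by a
#' single seed, so a trajectory is fully reproducible.
#'
#' @param horizon trajectory length (h).
#' @param dt grid spacing (h).
#' @param latitude site latitude (degrees); default 37.8.
#' @param day_of_year day of year at t = 0; default 91 (early April).
#' @param scale irradiance scaling factor, see [irradiance_under_cloud()].
#' @param cloud_step,vpd_step random-walk step scales.
#' @param vpd_bounds VPD reflection bounds (kPa).
#' @param seed integer seed.
#' @return a `weather_trajectory` data frame.
#' @export
stochastic_trajectory <- function(horizon, dt = 0.5, latitude = 37.8,
                                  day_of_year = 91, scale = 0.05,
                                  cloud_step = 0.5, vpd_step = 0.05,
                                  vpd_bounds = c(0.5, 2.0), seed = 1L) {
  time_h <- seq(0, horizon, by = dt)
  cloud <- random_walk_cloud(horizon, dt, step = cloud_step, seed = seed)
  vpd <- random_walk_vpd(horizon, dt, step = vpd_step, bounds = vpd_bounds,
                         seed = seed + 1000000L)
  elev <- solar_elevation(time_h, latitude, day_of_year)
  k_plus <- irradiance_under_cloud(elev, cloud, scale = scale)
  weather_trajectory(time_h, k_plus, vpd, cloud_okta = cloud, seed = seed)
}

#' Calibrate the irradiance scaling factor against a reference climate
#'
#' Chooses the open-weather irradiance scaling factor so that the
#' time-mean simulated per-plant transpiration rate under stochastic
#' weather matches the mean rate under the controlled-room trajectory for
#' the same plants. Because the transpiration model is linear in
#' irradiance, the matching scale has a closed form and no optimization is
#' needed.
#'
#' @param params a [plant_params()] object.
#' @param schedule a [controlled_schedule()]; the calibration target.
#' @param horizon,dt grid for the comparison (h).
#' @param n_seeds number of stochastic weather draws averaged over.
#' @param seed base seed for the draws.
#' @param ... further arguments passed to [stochastic_trajectory()]
#'   (latitude, steps, bounds...).
#' @return scaling factor in (0, 1].
#' @export
calibrate_irradiance_scale <- function(params, schedule = controlled_schedule(),
                                       horizon = 1296, dt = 0.5,
                                       n_seeds = 5, seed = 1L, ...) {
  ctrl <- controlled_trajectory(schedule, horizon, dt)
  lai <- leaf_area_index(ctrl$time_h, params)
  q_ctrl <- mean(transpiration_rate(ctrl$k_plus_w_m2, ctrl$vpd_kpa, lai, params))
  rad_unit <- 0; aero <- 0
  for (i in seq_len(n_seeds)) {
    w <- stochastic_trajectory(horizon, dt, scale = 1, seed = seed + i - 1L, ...)
    lai_w <- leaf_area_index(w$time_h, params)
    rad_unit <- rad_unit +
      mean(params$a_trs * (1 - exp(-params$k_ext * lai_w)) * w$k_plus_w_m2)
    aero <- aero + mean(params$b_trs * lai_w * w$vpd_kpa)
  }
  rad_unit <- rad_unit / n_seeds
  aero <- aero / n_seeds
  scale <- (q_ctrl - aero) / rad_unit
  min(1, max(1e-4, scale))
}

#' Read or write weather trajectories as CSV
#'
#' @param weather a `weather_trajectory`.
#' @param path file path.
#' @return `read_weather_csv` returns a `weather_trajectory`.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(as.data.frame(weather), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path)
  weather_trajectory(df$time_h, df$k_plus_w_m2, df$vpd_kpa,
                     cloud_okta = if ("cloud_okta" %in% names(df)) df$cloud_okta else NA_real_)
}
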