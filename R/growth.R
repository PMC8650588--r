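#' Logistic root length
#'
#' Root length grows along a logistic curve
#' \deqn{P_{RL}(t) = R_{max} / (1 + K_1 e^{-k_1 t}).}
#'
#' @param t elapsed time since transplanting (h), >= 0.
#' @param params a [plant_params()] object.
#' @return root length (m), in (0, Rmax).
#' @export
root_length <- function(t, params) {
  stopifnot(inherits(params, "plant_params"))
  if (any(t < 0)) stop("t must be >= 0")
  params$rmax / (1 + params$K1 * exp(-params$k1 * t))
}

#' Cylindrical root surface area
#'
#' Roots are treated as smooth cylinders of constant mean radius, so the
#' absorbing surface is \eqn{P_{RSA} = 2\pi r_0 P_{RL}}.
#'
#' @param length root length (m), >= 0.
#' @param r0 mean root radius (m), >= 0.
#' @return root surface area (m2).
#' @export
root_surface_area <- function(length, r0) {
  if (any(length < 0) || any(r0 < 0)) stop("inputs must be >= 0")
  2 * pi * r0 * length
}

#' Boltzmann sigmoid leaf area index
#'
#' \deqn{P_{LAI}(t) = a_{LAI} / (1 + e^{(x_0 - t)/b_{LAI}}).}
#'
#' @inheritParams root_length
#' @return LAI (dimensionless), in (0, a_lai).
#' @export
leaf_area_index <- function(t, params) {
  stopifnot(inherits(params, "plant_params"))
  if (any(t < 0)) stop("t must be >= 0")
  if (params$b_lai == 0) stop("b_lai must be non-zero")
  params$a_lai / (1 + exp((params$x0 - t) / params$b_lai))
}

#' Michaelis-Menten nutrient uptake rate
#'
#' Per-plant uptake of each ion is transporter-limited:
#' \deqn{J^I = P_{RSA} J_{max}^I C^I / (K_m^I + C^I),}
#' saturating at \eqn{P_{RSA} J_{max}^I} for large concentrations.
#'
#' @param conc nutrient vector of tank concentrations (mol m-3), >= 0.
#' @param rsa root surface area per plant (m2), >= 0.
#' @param params a [plant_params()] object.
#' @return nutrient vector of per-plant uptake rates (mol h-1).
#' @export
uptake_rate <- function(conc, rsa, params) {
  stopifnot(inherits(params, "plant_params"))
  conc <- nutrient_vector(conc)
  if (rsa < 0) stop("rsa must be >= 0")
  rsa * params$jmax * conc / (params$km + conc)
}

#' Reduced Penman-Monteith transpiration rate
#'
#' Per-plant transpiration is the sum of a radiative term saturating with
#' canopy light interception and an aerodynamic term proportional to canopy
#' size and vapour pressure deficit:
#' \deqn{Q_{trs} = a_{trs}(1 - e^{-k_{ext} LAI}) K^+ + b_{trs} \, LAI \, VPD.}
#' With `vpd_in_exponent = TRUE` the VPD multiplies LAI inside the
#' exponent of the radiative term instead, an alternative reading of the
#' empirical formula kept for comparison.
#'
#' @param k_plus solar irradiance at canopy level (W m-2), >= 0.
#' @param vpd vapour pressure deficit (kPa), >= 0.
#' @param lai leaf area index (dimensionless), >= 0.
#' @param params a [plant_params()] object.
#' @param vpd_in_exponent place VPD inside the radiative exponent
#'   (default `FALSE`, the standard Baille-type form).
#' @return transpiration rate (m3 h-1 per plant).
#' @export
transpiration_rate <- function(k_plus, vpd, lai, params, vpd_in_exponent = FALSE) {
  stopifnot(inherits(params, "plant_params"))
  if (any(k_plus < 0) || any(vpd < 0) || any(lai < 0)) stop("inputs must be >= 0")
  expo <- if (vpd_in_exponent) params$k_ext * lai * vpd else params$k_ext * lai
  params$a_trs * (1 - exp(-expo)) * k_plus + params$b_trs * lai * vpd
}
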