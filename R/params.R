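#' Plant parameter set
#'
#' All species-level parameters of the hydroponic system model: per-ion
#' Michaelis-Menten uptake kinetics, logistic root growth, Boltzmann
#' leaf-area-index (LAI) curve and the reduced Penman-Monteith transpiration
#' coefficients, plus the number of plants sharing the tank.
#'
#' Time is measured in hours from transplanting.
#'
#' @param jmax named nutrient vector of maximal uptake rates (mol m-2 h-1,
#'   per unit root surface area).
#' @param km named nutrient vector of half-saturation constants (mol m-3).
#' @param rmax maximal root length (m).
#' @param K1,k1 logistic root-growth coefficients (dimensionless, h-1).
#' @param r0 mean root radius (m); roots are treated as smooth cylinders.
#' @param a_lai asymptotic LAI (dimensionless).
#' @param b_lai sigmoid width of the LAI curve (h).
#' @param x0 sigmoid midpoint of the LAI curve (h).
#' @param a_trs radiative transpiration coefficient (m3 h-1 per W m-2).
#' @param b_trs aerodynamic transpiration coefficient (m3 h-1 per kPa per
#'   unit LAI).
#' @param k_ext canopy extinction coefficient (dimensionless).
#' @param n_plants number of plants (>= 1).
#' @param species optional species label.
#' @return object of class `plant_params`.
#' @seealso [species_preset()] for ready-made synthetic parameter sets.
#' @export
plant_params <- function(jmax, km, rmax, K1, k1, r0,
                         a_lai, b_lai, x0, a_trs, b_trs, k_ext,
                         n_plants = 84L, species = "unnamed") {
  jmax <- nutrient_vector(jmax)
  km <- nutrient_vector(km)
  scalars <- c(rmax = rmax, K1 = K1, k1 = k1, r0 = r0, a_lai = a_lai,
               b_lai = b_lai, x0 = x0, a_trs = a_trs, b_trs = b_trs,
               k_ext = k_ext)
  if (any(!is.finite(scalars)) || any(scalars <= 0)) {
    stop("all scalar plant parameters must be positive and finite")
  }
  if (any(jmax < 0) || any(km <= 0)) stop("jmax must be >= 0 and km > 0")
  n_plants <- as.integer(n_plants)
  if (n_plants < 1L) stop("n_plants must be >= 1")
  out <- list(species = species, jmax = jmax, km = km,
              rmax = rmax, K1 = K1, k1 = k1, r0 = r0,
              a_lai = a_lai, b_lai = b_lai, x0 = x0,
              a_trs = a_trs, b_trs = b_trs, k_ext = k_ext,
              n_plants = n_plants)
  class(out) <- "plant_params"
  out
}

#' @export
print.plant_params <- function(x, ...) {
  cat("plant_params:", x$species, "(", x$n_plants, "plants )\n")
  cat("  jmax (mol m-2 h-1):", paste(sprintf("%s %.3g", names(x$jmax), x$jmax), collapse = ", "), "\n")
  cat("  km   (mol m-3)    :", paste(sprintf("%s %.3g", names(x$km), x$km), collapse = ", "), "\n")
  cat(sprintf("  root: rmax %.3g m, K1 %.3g, k1 %.3g h-1, r0 %.3g m\n",
              x$rmax, x$K1, x$k1, x$r0))
  cat(sprintf("  canopy: a_lai %.3g, b_lai %.3g h, x0 %.3g h, k_ext %.3g\n",
              x$a_lai, x$b_lai, x$x0, x$k_ext))
  cat(sprintf("  transpiration: a_trs %.3g, b_trs %.3g\n", x$a_trs, x$b_trs))
  invisible(x)
}

# base synthetic magnitudes shared by the presets (see vignette for the
# reasoning behind the scales)
.preset_base <- function() {
  list(
    jmax = c(NO3 = 6.0e-4, H2PO4 = 1.6e-4, SO4 = 1.3e-4,
             K = 2.8e-4, Ca = 1.1e-4, Mg = 7.5e-5),
    km = c(NO3 = 0.10, H2PO4 = 0.05, SO4 = 0.08,
           K = 0.06, Ca = 0.08, Mg = 0.06),
    rmax = 200, K1 = 50, k1 = 0.005, r0 = 2e-4,
    a_lai = 3.0, b_lai = 150, x0 = 648,
    a_trs = 2.0e-7, b_trs = 3.0e-7, k_ext = 0.7
  )
}

#' Synthetic species parameter presets
#'
#' Three leafy Brassica-like parameter sets ordered by uptake and
#' transpiration capacity: `"pakchoi"` > `"lacinato_kale"` > `"curly_kale"`.
#' NO3 carries the largest Jmax in every preset and the two kale presets
#' have elevated SO4 uptake relative to pakchoi. The magnitudes are
#' synthetic defaults (no measured parameter values are shipped): they are
#' chosen so that an 84-plant, 0.3 m3 tank shows weekly per-plant
#' transpiration of order 1e-4 to 1e-3 m3 and visible but incomplete weekly
#' depletion of the standard solution.
#'
#' @param species one of `"pakchoi"`, `"lacinato_kale"`, `"curly_kale"`.
#' @param n_plants number of plants (default 84).
#' @return a [plant_params()] object.
#' @export
species_preset <- function(species = c("pakchoi", "lacinato_kale", "curly_kale"),
                           n_plants = 84L) {
  species <- match.arg(species)
  b <- .preset_base()
  scal <- switch(species,
    pakchoi       = list(up = 1.00, so4 = 1.0, trs = 1.00, lai = 1.0),
    lacinato_kale = list(up = 0.80, so4 = 1.6, trs = 0.85, lai = 0.9),
    curly_kale    = list(up = 0.65, so4 = 1.8, trs = 0.70, lai = 0.8)
  )
  jmax <- b$jmax * scal$up
  jmax["SO4"] <- jmax["SO4"] * scal$so4
  plant_params(jmax = jmax, km = b$km,
               rmax = b$rmax, K1 = b$K1, k1 = b$k1, r0 = b$r0,
               a_lai = b$a_lai * scal$lai, b_lai = b$b_lai, x0 = b$x0,
               a_trs = b$a_trs * scal$trs, b_trs = b$b_trs * scal$trs,
               k_ext = b$k_ext, n_plants = n_plants, species = species)
}
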