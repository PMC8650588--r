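# shared small fixtures, built in code at load time

pakchoi <- species_preset("pakchoi")

# constant-environment weather: K+ = k, VPD = v over [0, horizon]
constant_weather <- function(horizon, k = 0, v = 1, dt = 1) {
  data.frame(time_h = seq(0, horizon, by = dt),
             k_plus_w_m2 = k, vpd_kpa = v, cloud_okta = NA_real_)
}

# params whose transpiration is (numerically) constant: LAI at its
# asymptote from t = 0, radiative term off
constant_transpiration_params <- function(q_per_plant, vpd = 1, a_lai = 3,
                                          n_plants = 84L) {
  p <- species_preset("pakchoi", n_plants = n_plants)
  p$a_lai <- a_lai
  p$x0 <- 1e-6; p$b_lai <- 1e-3          # sigmoid saturated immediately
  p$a_trs <- 1e-30
  p$b_trs <- q_per_plant / (a_lai * vpd)
  p
}

standard_state <- function(v0 = 0.3) tank_state(v0, conc = standard_composition())
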