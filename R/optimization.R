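#' Scenario for dosing-composition optimization
#'
#' Bundles everything [deviation_objective()] needs to score a dosing
#' composition: the species parameters, tank and controller setpoints, the
#' stochastic weather ensemble (generated once and cached, so the
#' objective is deterministic and cheap to re-evaluate) and the deviation
#' metric.
#'
#' @param params a [plant_params()] or list of them.
#' @param v0 tank volume setpoint (m3).
#' @param ec0 EC setpoint as total equivalents (eq m-3).
#' @param feed_ec total equivalents of the absolute feed built from a
#'   ratio (eq m-3); only the composition matters to the EC+volume
#'   controller, so this is a reporting scale.
#' @param interval_h dosing interval (h).
#' @param horizon,dt simulation length and step (h).
#' @param seeds integer vector of weather seeds averaged over.
#' @param metric `"rms"` (default), `"mean_abs"` or `"final"` - how ratio
#'   deviations are aggregated over time points and ions.
#' @param sample_every_h spacing of the trajectory samples entering the
#'   metric (h).
#' @param scale,... irradiance scaling factor and further arguments to
#'   [stochastic_trajectory()].
#' @return object of class `dosing_scenario`.
#' @export
dosing_scenario <- function(params, v0 = 0.3, ec0 = 26.1, feed_ec = 26.1,
                            interval_h = 24, horizon = 1296, dt = 0.5,
                            seeds = 1:5, metric = c("rms", "mean_abs", "final"),
                            sample_every_h = 1, scale = 0.05, ...) {
  metric <- match.arg(metric)
  weather <- lapply(seeds, function(s) {
    stochastic_trajectory(horizon, dt, scale = scale, seed = s, ...)
  })
  out <- list(params = params, v0 = v0, ec0 = ec0, feed_ec = feed_ec,
              interval_h = interval_h, horizon = horizon, dt = dt,
              seeds = seeds, metric = metric, sample_every_h = sample_every_h,
              weather = weather)
  class(out) <- "dosing_scenario"
  out
}

# percentage molar shares of a concentration trajectory, per charge group
.ratio_trajectory <- function(conc) {
  g <- ion_groups()
  out <- conc
  out[, g$anions] <- 100 * conc[, g$anions] / rowSums(conc[, g$anions])
  out[, g$cations] <- 100 * conc[, g$cations] / rowSums(conc[, g$cations])
  out
}

ratio_as_vector <- function(ratio) {
  stopifnot(inherits(ratio, "composition_ratio"))
  c(ratio$anions, ratio$cations)[ion_set()]
}

#' Root-zone deviation of a dosing composition from a standard
#'
#' Simulates EC+volume-based dosing with the candidate feed composition
#' over the scenario's stochastic weather ensemble, converts the root-zone
#' concentration trajectory to percentage molar ratios, and aggregates the
#' deviation from the standard ratio over time points, ions and seeds.
#'
#' @param ratio candidate dosing [composition_ratio()].
#' @param standard the standard (target) [composition_ratio()].
#' @param scenario a [dosing_scenario()].
#' @return scalar deviation (percentage-ratio units), >= 0; deterministic
#'   given the scenario.
#' @export
deviation_objective <- function(ratio, standard, scenario) {
  stopifnot(inherits(scenario, "dosing_scenario"))
  feed <- ratio_to_feed(ratio, scenario$feed_ec)
  policy <- dosing_policy("ec_volume", interval_h = scenario$interval_h,
                          feed = feed, v0 = scenario$v0, ec0 = scenario$ec0)
  target <- ratio_as_vector(standard)
  state0 <- tank_state(scenario$v0, conc = standard_feed_for(standard, scenario$ec0))
  step <- max(1L, round(scenario$sample_every_h / scenario$dt))
  vals <- vapply(scenario$weather, function(w) {
    sim <- simulate_tank(state0, scenario$params, w, horizon = scenario$horizon,
                         dt = scenario$dt, policy = policy)
    idx <- seq(1, length(sim$time_h), by = step)
    dev <- sweep(.ratio_trajectory(sim$conc_mol_m3[idx, , drop = FALSE]), 2, target)
    switch(scenario$metric,
           rms = sqrt(mean(dev^2)),
           mean_abs = mean(abs(dev)),
           final = sqrt(mean(dev[nrow(dev), ]^2)))
  }, 0)
  mean(vals)
}

# absolute initial/standard solution realizing the standard ratio at the
# scenario's EC setpoint
standard_feed_for <- function(standard, ec0) ratio_to_feed(standard, ec0)

# ratio <-> unconstrained softmax coordinates, with some ions held fixed
.ratio_codec <- function(standard, free) {
  g <- ion_groups()
  std <- ratio_as_vector(standard)
  chunks <- list()
  for (grp in names(g)) {
    fr <- intersect(g[[grp]], free[[grp]])
    chunks[[grp]] <- list(free = fr, fixed = setdiff(g[[grp]], fr),
                          rem = 100 - sum(std[setdiff(g[[grp]], fr)]))
  }
  n_par <- sum(vapply(chunks, function(ch) max(0L, length(ch$free) - 1L), 0L))
  encode <- function(ratio) {
    x <- ratio_as_vector(ratio)
    z <- numeric(0)
    for (ch in chunks) {
      if (length(ch$free) > 1) {
        sh <- pmax(x[ch$free], 1e-6)
        z <- c(z, log(sh[-1] / sh[1]))
      }
    }
    z
  }
  decode <- function(z) {
    x <- std
    pos <- 0L
    for (ch in chunks) {
      if (length(ch$free) == 1L) {
        x[ch$free] <- ch$rem
      } else if (length(ch$free) > 1L) {
        k <- length(ch$free) - 1L
        logits <- c(0, z[pos + seq_len(k)]); pos <- pos + k
        e <- exp(logits - max(logits))
        x[ch$free] <- ch$rem * e / sum(e)
      }
    }
    composition_ratio(x[g$anions], x[g$cations], basis = standard$basis)
  }
  list(encode = encode, decode = decode, n_par = n_par)
}

#' Optimize the dosing composition
#'
#' Searches the product of the anion and cation percentage simplices for
#' the dosing composition whose root-zone trajectory deviates least from
#' the standard composition under EC+volume-based dosing (softmax
#' reparameterization, multi-start Nelder-Mead, the standard ratio always
#' included as one start). Subsets of ions can be held at their standard
#' shares via `free`, which also enables low-dimensional brute-force
#' cross-checks.
#'
#' @param standard the standard [composition_ratio()].
#' @param scenario a [dosing_scenario()].
#' @param seed integer seed for the extra starts.
#' @param free named list with elements `anions` and `cations` giving the
#'   ions allowed to move; defaults to all six.
#' @param n_starts number of optimizer starts (>= 1; the first is the
#'   standard ratio).
#' @param maxit Nelder-Mead evaluation budget per start.
#' @return object of class `optimization_result`: optimal ratio and
#'   absolute feed, objective at optimum and at the standard-composition
#'   baseline, and diagnostics. The optimum's objective never exceeds the
#'   baseline because the standard is a start point.
#' @export
optimize_dosing_composition <- function(standard, scenario, seed = 1L,
                                        free = ion_groups(), n_starts = 3,
                                        maxit = 150) {
  stopifnot(inherits(standard, "composition_ratio"),
            inherits(scenario, "dosing_scenario"))
  codec <- .ratio_codec(standard, free)
  obj <- function(z) deviation_objective(codec$decode(z), standard, scenario)
  baseline <- deviation_objective(standard, standard, scenario)
  evals <- 0L
  if (codec$n_par == 0L) {
    best_z <- numeric(0); best_val <- obj(best_z)
  } else if (codec$n_par == 1L) {
    opt <- stats::optimize(function(z) obj(z), interval = c(-8, 8), tol = 1e-3)
    best_z <- opt$minimum; best_val <- opt$objective
    z0 <- codec$encode(standard)
    v0 <- obj(z0)
    if (v0 < best_val) { best_z <- z0; best_val <- v0 }
  } else {
    set.seed(seed)
    z0 <- codec$encode(standard)
    starts <- rbind(z0)
    if (n_starts > 1) {
      starts <- rbind(starts,
                      matrix(stats::rnorm((n_starts - 1) * codec$n_par, sd = 1.0),
                             ncol = codec$n_par) + rep(z0, each = n_starts - 1))
    }
    best_val <- Inf; best_z <- z0
    for (r in seq_len(nrow(starts))) {
      opt <- stats::optim(starts[r, ], obj, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-6))
      evals <- evals + opt$counts[["function"]]
      if (opt$value < best_val) { best_val <- opt$value; best_z <- opt$par }
    }
  }
  ratio_opt <- codec$decode(best_z)
  if (best_val > baseline) {  # argmin contract: the standard is a candidate
    ratio_opt <- standard; best_val <- baseline
  }
  out <- list(ratio = ratio_opt,
              feed = ratio_to_feed(ratio_opt, scenario$feed_ec),
              objective = best_val, objective_standard = baseline,
              seed = seed, n_par = codec$n_par, evals = evals)
  class(out) <- "optimization_result"
  out
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("optimization_result\n")
  cat(sprintf("  objective: %.4f (standard baseline %.4f)\n",
              x$objective, x$objective_standard))
  print(x$ratio)
  invisible(x)
}

#' Between-species variability of Jmax and of its molar ratios
#'
#' Percent coefficient of variation across species parameter sets, per
#' ion, computed on the raw Jmax values and on the within-group percentage
#' molar ratios of Jmax. Because the ratios are scale-invariant, species
#' differing mainly by an overall uptake-capacity factor show much lower
#' ratio CVs than raw CVs.
#'
#' @param params_list list of >= 2 [plant_params()].
#' @return list with `cv_jmax_pct`, `cv_ratio_pct` (named per-ion vectors)
#'   and their means `mean_cv_jmax_pct`, `mean_cv_ratio_pct`.
#' @export
jmax_ratio_cv <- function(params_list) {
  stopifnot(length(params_list) >= 2)
  jm <- t(vapply(params_list, function(p) p$jmax, numeric(6)))
  colnames(jm) <- ion_set()
  if (any(colMeans(jm) == 0)) stop("zero mean Jmax")
  cv <- function(x) 100 * stats::sd(x) / mean(x)
  cv_raw <- apply(jm, 2, cv)
  ratios <- t(apply(jm, 1, function(x) ratio_as_vector(composition_to_ratio(x))))
  cv_ratio <- apply(ratios, 2, cv)
  list(cv_jmax_pct = cv_raw, cv_ratio_pct = cv_ratio,
       mean_cv_jmax_pct = mean(cv_raw), mean_cv_ratio_pct = mean(cv_ratio))
}
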