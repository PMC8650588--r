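#' @keywords internal
"_PACKAGE"

#' Macronutrient ion set and valences
#'
#' The package tracks the six macronutrient ions of a standard hydroponic
#' solution in a fixed order. All nutrient vectors, matrices and CSV columns
#' use this order throughout the package.
#'
#' @return `ion_set()` returns the ordered character vector of ion labels;
#'   `ion_valences()` returns the named vector of absolute ionic charges.
#' @examples
#' ion_set()
#' ion_valences()
#' @export
ion_set <- function() c("NO3", "H2PO4", "SO4", "K", "Ca", "Mg")

#' @rdname ion_set
#' @export
ion_valences <- function() {
  c(NO3 = 1, H2PO4 = 1, SO4 = 2, K = 1, Ca = 2, Mg = 2)
}

# which ions belong to which charge group
ion_groups <- function() {
  list(anions = c("NO3", "H2PO4", "SO4"), cations = c("K", "Ca", "Mg"))
}

#' Construct a nutrient vector
#'
#' A nutrient vector holds one value per macronutrient ion, in the package's
#' fixed ion order. Depending on context the values are concentrations
#' (mol m-3), masses (mol) or rates (mol h-1).
#'
#' @param x numeric vector of length 6. If named, names are matched against
#'   [ion_set()] and reordered; if unnamed, values are taken to be in ion-set
#'   order. A single scalar is recycled.
#' @param allow_negative permit negative entries (e.g. for rate differences);
#'   default `FALSE`.
#' @return named numeric vector over `ion_set()`.
#' @examples
#' nutrient_vector(c(NO3 = 7.5, H2PO4 = 3, SO4 = 2.5, K = 4, Ca = 1.9, Mg = 1.4))
#' @export
nutrient_vector <- function(x, allow_negative = FALSE) {
  ions <- ion_set()
  if (length(x) == 1L && is.null(names(x))) x <- rep(x, 6L)
  if (!is.null(names(x))) {
    if (!setequal(names(x), ions)) {
      stop("nutrient vector names must be exactly {", paste(ions, collapse = ", "), "}")
    }
    x <- x[ions]
  } else {
    if (length(x) != 6L) stop("nutrient vector must have 6 entries")
    names(x) <- ions
  }
  x <- as.numeric(stats::setNames(x, ions))
  names(x) <- ions
  if (any(!is.finite(x))) stop("nutrient vector entries must be finite")
  if (!allow_negative && any(x < 0)) stop("nutrient vector entries must be >= 0")
  x
}

#' Standard nutrient composition
#'
#' Mean initial macronutrient composition of a Steiner-proximal standard
#' solution (mol m-3, i.e. mM): NO3 7.5, H2PO4 3.0, SO4 2.5, K 4.0, Ca 1.9,
#' Mg 1.4, totalling 26.1 meq L-1. Used as the default standard (target)
#' composition throughout.
#'
#' @return a nutrient vector of concentrations (mol m-3).
#' @seealso [steiner_ratio()], [total_equivalents()]
#' @export
standard_composition <- function() {
  nutrient_vector(c(NO3 = 7.5, H2PO4 = 3.0, SO4 = 2.5, K = 4.0, Ca = 1.9, Mg = 1.4))
}

#' Per-ion standard deviations of the sampled initial composition
#'
#' Week-to-week scatter (mol m-3) of the freshly prepared initial solutions
#' around [standard_composition()].
#' @return named numeric vector (mol m-3).
#' @export
standard_composition_sd <- function() {
  nutrient_vector(c(NO3 = 1.0, H2PO4 = 1.4, SO4 = 1.1, K = 0.4, Ca = 0.4, Mg = 0.2))
}

#' Steiner's universal-solution percentage equivalent ratios
#'
#' Classical Steiner anion/cation percentage equivalent ratios:
#' NO3 60, H2PO4 5, SO4 35 among anions; K 35, Ca 45, Mg 20 among cations.
#'
#' @return a [composition_ratio()] object on the equivalent basis.
#' @export
steiner_ratio <- function() {
  composition_ratio(anions = c(NO3 = 60, H2PO4 = 5, SO4 = 35),
                    cations = c(K = 35, Ca = 45, Mg = 20),
                    basis = "equivalent")
}

#' Total ionic equivalent concentration
#'
#' Sum over ions of |z| * C, the total ion equivalent concentration in
#' eq m-3 (numerically equal to meq L-1). This is the quantity an EC probe
#' is taken to measure: the package treats electrical conductivity as a
#' linear proxy for total ionic concentration.
#'
#' @param conc nutrient vector of concentrations (mol m-3).
#' @return total equivalents (eq m-3 == meq L-1).
#' @examples
#' total_equivalents(standard_composition()) # 26.1
#' @export
total_equivalents <- function(conc) {
  conc <- nutrient_vector(conc)
  sum(ion_valences() * conc)
}

#' Display conversion from equivalent concentration to conductivity
#'
#' Optional linear reporting conversion: 0.1 dS m-1 per meq L-1.
#' @param meq_l total equivalents (meq L-1).
#' @return electrical conductivity (dS m-1), for display only.
#' @export
equivalents_to_ds_m <- function(meq_l) 0.1 * meq_l

#' Percentage composition ratio within charge groups
#'
#' A composition ratio expresses a nutrient vector as percentage shares
#' within its two charge groups: anions (NO3, H2PO4, SO4) and cations
#' (K, Ca, Mg), each group summing to 100.
#'
#' @param anions named numeric of the three anion percentages.
#' @param cations named numeric of the three cation percentages.
#' @param basis `"molar"` (default) or `"equivalent"` - the scale on which
#'   the percentages were computed.
#' @return object of class `composition_ratio`: a list with `anions`,
#'   `cations` (each renormalized to sum exactly 100) and `basis`.
#' @export
composition_ratio <- function(anions, cations, basis = c("molar", "equivalent")) {
  basis <- match.arg(basis)
  g <- ion_groups()
  anions <- anions[g$anions]; cations <- cations[g$cations]
  if (any(!is.finite(c(anions, cations))) || any(c(anions, cations) < 0)) {
    stop("ratio entries must be finite and >= 0")
  }
  if (sum(anions) <= 0 || sum(cations) <= 0) stop("each charge group needs a positive sum")
  out <- list(anions = 100 * anions / sum(anions),
              cations = 100 * cations / sum(cations),
              basis = basis)
  class(out) <- "composition_ratio"
  out
}

#' @export
print.composition_ratio <- function(x, ...) {
  cat("composition ratio (", x$basis, " % within charge group)\n", sep = "")
  cat("  anions : ", paste(sprintf("%s %.1f", names(x$anions), x$anions), collapse = ", "), "\n")
  cat("  cations: ", paste(sprintf("%s %.1f", names(x$cations), x$cations), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a composition to percentage ratios
#'
#' @param conc nutrient vector (mol m-3 or any common scale; the ratio is
#'   scale-invariant within each group).
#' @param basis `"molar"` (percentages of molar concentration, the default)
#'   or `"equivalent"` (percentages of |z|*C).
#' @return a [composition_ratio()].
#' @examples
#' composition_to_ratio(standard_composition())
#' @export
composition_to_ratio <- function(conc, basis = c("molar", "equivalent")) {
  basis <- match.arg(basis)
  conc <- nutrient_vector(conc)
  x <- if (basis == "equivalent") ion_valences() * conc else conc
  g <- ion_groups()
  if (sum(x[g$anions]) <= 0 || sum(x[g$cations]) <= 0) {
    stop("cannot form ratios: a charge group is all zero")
  }
  composition_ratio(x[g$anions], x[g$cations], basis = basis)
}

#' Absolute feed composition realizing a ratio at a given strength
#'
#' Builds the electroneutral feed solution whose within-group percentage
#' ratios equal `ratio` and whose total ionic strength is `total_eq`
#' (eq m-3). Anion and cation groups each carry half the equivalents, so the
#' feed is charge-balanced by construction.
#'
#' @param ratio a [composition_ratio()].
#' @param total_eq total equivalent concentration of the feed (eq m-3).
#' @return nutrient vector of concentrations (mol m-3).
#' @export
ratio_to_feed <- function(ratio, total_eq) {
  stopifnot(inherits(ratio, "composition_ratio"), total_eq > 0)
  z <- ion_valences()
  g <- ion_groups()
  conc <- stats::setNames(numeric(6), ion_set())
  for (grp in names(g)) {
    sh <- ratio[[grp]] / 100
    ions <- g[[grp]]
    mol <- if (ratio$basis == "equivalent") sh / z[ions] else sh
    # scale group so its equivalents total total_eq / 2
    eqs <- sum(mol * z[ions])
    conc[ions] <- mol * (total_eq / 2) / eqs
  }
  nutrient_vector(conc)
}
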