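#' Solution composition
#'
#' A `solution_composition` records the mole fraction of every dissolved
#' species (plus the solvent). Mole fractions are the package's internal
#' concentration basis because every thermodynamic expression in the model is
#' written on it; mass fractions and grams per gram of water are derived views.
#'
#' @param mole_fractions Named numeric vector of mole fractions (names are
#'   species in the registry, case-insensitive). Must be in `[0, 1]` and sum to
#'   one; small rounding slack (1e-6) is renormalized away.
#' @param registry Species registry, see [species_registry()].
#'
#' @return A tibble of class `solution_composition` with columns `species`,
#'   `role`, `molar_mass` and `mole_fraction`.
#' @export
#' @examples
#' solution_composition(c(water = 0.99, "alpha-lactose" = 0.004,
#'                        "beta-lactose" = 0.006))
solution_composition <- function(mole_fractions, registry = species_registry()) {
  if (is.null(names(mole_fractions)) || any(names(mole_fractions) == "")) {
    abort_domain("`mole_fractions` must be a fully named numeric vector.")
  }
  x <- as.numeric(mole_fractions)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_domain("Mole fractions must be finite and in [0, 1].")
  }
  s <- sum(x)
  if (abs(s - 1) > 1e-6) {
    abort_domain(sprintf("Mole fractions must sum to 1 (got %.8f).", s))
  }
  x <- x / s
  nm <- tolower(names(mole_fractions))
  i <- match(nm, tolower(registry$name))
  if (anyNA(i)) {
    abort_domain(sprintf("Unknown species: %s.", toString(nm[is.na(i)])))
  }
  out <- tibble(
    species = registry$name[i],
    role = registry$role[i],
    molar_mass = registry$molar_mass[i],
    mole_fraction = x
  )
  if (!any(out$role == "solvent")) {
    abort_domain("Composition must contain the solvent.")
  }
  class(out) <- c("solution_composition", class(out))
  out
}

comp_from_moles <- function(moles, registry = species_registry()) {
  solution_composition(moles / sum(moles), registry)
}

#' @rdname solution_composition
#' @param comp A `solution_composition`.
#' @export
x_water <- function(comp) sum(comp$mole_fraction[comp$role == "solvent"])

#' @rdname solution_composition
#' @export
x_alpha <- function(comp) {
  sum(comp$mole_fraction[tolower(comp$species) == "alpha-lactose"])
}

#' @rdname solution_composition
#' @export
x_beta <- function(comp) {
  sum(comp$mole_fraction[tolower(comp$species) == "beta-lactose"])
}

#' @rdname solution_composition
#' @export
x_iso <- function(comp) sum(comp$mole_fraction[comp$role == "isomer"])

#' @rdname solution_composition
#' @export
x_foreign <- function(comp) sum(comp$mole_fraction[comp$role == "foreign_sugar"])

#' Build a composition from a powder loading
#'
#' Converts a dissolved-lactose loading (grams of anhydrous lactose per gram
#' of water), a beta-to-alpha mass ratio and optional foreign-sugar loadings
#' into mole fractions. Because the two anomers have the same molar mass, the
#' beta:alpha mole ratio equals the mass ratio.
#'
#' @param lactose_g_per_g_water Grams of dissolved (anhydrous) lactose per gram
#'   of water; must be non-negative.
#' @param beta_to_alpha Mass ratio of dissolved beta- to alpha-lactose
#'   (>= 0; e.g. the mutarotation equilibrium value).
#' @param foreign_loadings Named numeric vector of foreign-sugar loadings in
#'   grams per gram of water, e.g. `c(sucrose = 0.1)`.
#' @inheritParams solution_composition
#' @return A [solution_composition()].
#' @export
#' @examples
#' composition_from_loading(0.2191, beta_to_alpha = 1.6)
composition_from_loading <- function(lactose_g_per_g_water, beta_to_alpha,
                                     foreign_loadings = NULL,
                                     registry = species_registry()) {
  check_number(lactose_g_per_g_water, "lactose_g_per_g_water", lower = 0)
  check_number(beta_to_alpha, "beta_to_alpha", lower = 0)
  n_w <- 1 / molar_mass(registry, "water")
  n_l <- lactose_g_per_g_water / molar_mass(registry, "alpha-lactose")
  moles <- c(
    water = n_w,
    "alpha-lactose" = n_l / (1 + beta_to_alpha),
    "beta-lactose" = n_l * beta_to_alpha / (1 + beta_to_alpha)
  )
  if (length(foreign_loadings)) {
    if (any(foreign_loadings < 0)) abort_domain("Foreign loadings must be >= 0.")
    nf <- foreign_loadings / molar_mass(registry, names(foreign_loadings))
    moles <- c(moles, setNames(as.numeric(nf), tolower(names(foreign_loadings))))
  }
  comp_from_moles(moles, registry)
}

#' Mass fractions of a solution
#'
#' @param comp A [solution_composition()].
#' @return A tibble with columns `species` and `mass_fraction` (of total
#'   solution); fractions sum to one.
#' @export
mass_fractions <- function(comp) {
  m <- comp$mole_fraction * comp$molar_mass
  tibble(species = comp$species, mass_fraction = m / sum(m))
}

#' Convert a solute concentration between bases
#'
#' Supported bases are `"mole_fraction"`, `"mass_fraction_solution"` and
#' `"g_per_g_water"`. The conversion factors are evaluated at the composition
#' `comp` (which supplies the water mole and mass fractions), so chained
#' conversions commute exactly. `species` fixes the molar mass used for the
#' mole-fraction basis; `"lactose"` means the isomer group.
#'
#' @param value Numeric concentration(s) to convert.
#' @param from_basis,to_basis Concentration bases (see above).
#' @param comp The [solution_composition()] at which the conversion factors are
#'   evaluated.
#' @param species Species whose concentration `value` is, or `"lactose"` for
#'   the isomer group (default).
#' @return Numeric vector on the `to_basis` scale.
#' @export
convert_concentration <- function(value, from_basis, to_basis, comp,
                                  species = "lactose") {
  bases <- c("mole_fraction", "mass_fraction_solution", "g_per_g_water")
  from_basis <- rlang::arg_match(from_basis, bases)
  to_basis <- rlang::arg_match(to_basis, bases)
  if (identical(from_basis, to_basis)) {
    return(value)
  }
  M_s <- if (identical(tolower(species), "lactose")) {
    comp$molar_mass[match("isomer", comp$role)] %||% 342.30
  } else {
    comp$molar_mass[match(tolower(species), tolower(comp$species))]
  }
  if (is.na(M_s)) abort_domain(sprintf("Species '%s' not in composition.", species))
  xw <- x_water(comp)
  M_w <- comp$molar_mass[comp$role == "solvent"][1]
  w_w <- mass_fractions(comp)$mass_fraction[comp$role == "solvent"][1]
  # hub basis: grams of species per gram of water
  to_hub <- switch(from_basis,
    mole_fraction = value * M_s / (xw * M_w),
    mass_fraction_solution = value / w_w,
    g_per_g_water = value
  )
  switch(to_basis,
    mole_fraction = to_hub * xw * M_w / M_s,
    mass_fraction_solution = to_hub * w_w,
    g_per_g_water = to_hub
  )
}
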