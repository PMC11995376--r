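#' Species registry
#'
#' The registry is a tibble of the chemical species the package knows about:
#' the solvent (water), the two interconverting lactose anomers, the
#' crystallizing solid phase (alpha-lactose monohydrate) and common foreign
#' sugars. Molar masses are IUPAC values rounded to four significant figures.
#' Species names are matched case-insensitively throughout the package.
#'
#' @param overrides Optional data frame (or tibble) with columns `name`,
#'   `molar_mass` (g/mol) and `role` used to add species or replace defaults,
#'   e.g. a foreign sugar not shipped with the package.
#'
#' @return A tibble with columns `name`, `molar_mass` and `role`; `role` is one
#'   of `"solvent"`, `"isomer"`, `"foreign_sugar"`, `"crystal_hydrate"`.
#' @export
#' @examples
#' species_registry()
species_registry <- function(overrides = NULL) {
  reg <- tibble(
    name = c(
      "water", "alpha-lactose", "beta-lactose", "alpha-lactose-monohydrate",
      "glucose", "galactose", "sucrose"
    ),
    molar_mass = c(18.015, 342.30, 342.30, 360.31, 180.16, 180.16, 342.30),
    role = c(
      "solvent", "isomer", "isomer", "crystal_hydrate",
      "foreign_sugar", "foreign_sugar", "foreign_sugar"
    )
  )
  if (!is.null(overrides)) {
    overrides <- as_tibble(overrides)
    needed <- c("name", "molar_mass", "role")
    if (!all(needed %in% names(overrides))) {
      abort_domain("`overrides` needs columns name, molar_mass and role.")
    }
    overrides$name <- tolower(overrides$name)
    reg <- dplyr::bind_rows(
      dplyr::anti_join(reg, overrides, by = "name"),
      overrides[needed]
    )
  }
  validate_registry(reg)
}

validate_registry <- function(reg) {
  if (any(!is.finite(reg$molar_mass)) || any(reg$molar_mass <= 0)) {
    abort_domain("All molar masses must be positive.")
  }
  bad <- setdiff(reg$role, c("solvent", "isomer", "foreign_sugar", "crystal_hydrate"))
  if (length(bad)) {
    abort_domain(sprintf("Unknown species role(s): %s.", toString(bad)))
  }
  if (sum(reg$role == "solvent") != 1L) {
    abort_domain("Exactly one species must have role 'solvent'.")
  }
  if (anyDuplicated(tolower(reg$name))) {
    abort_domain("Species names must be unique (case-insensitive).")
  }
  reg
}

#' Look up a molar mass in a species registry
#'
#' @param registry A registry from [species_registry()].
#' @param name Species name (case-insensitive).
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(registry, name) {
  i <- match(tolower(name), tolower(registry$name))
  if (anyNA(i)) {
    abort_domain(sprintf(
      "Species %s not in registry.", toString(name[is.na(i)])
    ))
  }
  registry$molar_mass[i]
}

#' Stoichiometric release factor of the monohydrate
#'
#' Mass of anhydrous alpha-lactose released per unit mass of alpha-lactose
#' monohydrate crystal dissolved, computed from the molar masses in the
#' registry (the remaining fraction is released as water).
#'
#' @inheritParams molar_mass
#' @return A dimensionless number, 0.95 for the default registry.
#' @export
#' @examples
#' chi_stoichiometry()
chi_stoichiometry <- function(registry = species_registry()) {
  molar_mass(registry, "alpha-lactose") /
    molar_mass(registry, "alpha-lactose-monohydrate")
}
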