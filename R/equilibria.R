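#' Solid--liquid equilibrium model for alpha-lactose monohydrate
#'
#' Bundles the solubility product of the monohydrate with the activity models
#' needed to evaluate it. With the solid activity taken as unity, saturation
#' with respect to alpha-lactose monohydrate requires
#' \deqn{K_{sp} = a_w(x_w)\, \gamma^*_\alpha(x_w)\, x_\alpha,}
#' which, at mutarotation equilibrium
#' (\eqn{x_\alpha = (1 - x_w)/(1 + K_x(x_w))}), collapses to a function of
#' \eqn{x_w} alone in which the \eqn{(1 + K_x)} factors cancel exactly -- the
#' equilibrium solubility is therefore independent of the composition slope of
#' \eqn{K_x}.
#'
#' @param K_sp Solubility product (dimensionless, > 0). Default 0.00494 for
#'   alpha-lactose monohydrate at 25 degC.
#' @param margules A [margules_model()].
#' @param mutarotation A [mutarotation_model()].
#' @param registry A [species_registry()].
#' @return An object of class `solubility_model`.
#' @export
#' @examples
#' sle <- solubility_model()
#' equilibrium_solubility(sle)
solubility_model <- function(K_sp = 0.00494, margules = margules_model(),
                             mutarotation = mutarotation_model(),
                             registry = species_registry()) {
  check_number(K_sp, "K_sp", lower = 0, allow_zero = FALSE)
  check_margules(margules)
  check_mutarotation(mutarotation)
  structure(
    list(
      K_sp = K_sp, margules = margules, mutarotation = mutarotation,
      registry = validate_registry(registry)
    ),
    class = "solubility_model"
  )
}

#' @export
print.solubility_model <- function(x, ...) {
  cat(sprintf(
    "<solubility_model> K_sp = %g, A = %g, K* = %g, dK_x/dx_w = %g\n",
    x$K_sp, x$margules$A, x$mutarotation$K_star, x$mutarotation$slope
  ))
  invisible(x)
}

check_sle <- function(model) {
  if (!inherits(model, "solubility_model")) {
    abort_domain("Expected a `solubility_model`.")
  }
  model
}

#' Solubility product from a measured equilibrium saturation point
#'
#' Evaluates \eqn{K_{sp} = a_w \gamma^*_\alpha x_\alpha} at a measured
#' mutarotation-equilibrium saturation composition `x_w_eq`. Algebraically the
#' result does not depend on the `K_x` composition slope.
#'
#' @param x_w_eq Water mole fraction(s) at saturation + mutarotation
#'   equilibrium.
#' @inheritParams solubility_model
#' @return The solubility product (dimensionless).
#' @export
#' @examples
#' ksp_from_equilibrium_point(0.9886) # ~0.00494
ksp_from_equilibrium_point <- function(x_w_eq, margules = margules_model(),
                                       mutarotation = mutarotation_model()) {
  g <- gamma_star_isomers(x_w_eq, margules, mutarotation)
  x_alpha <- (1 - x_w_eq) / (1 + g$K_x)
  water_activity(x_w_eq, margules) * g$gamma_alpha * x_alpha
}

#' Saturation mole fraction of alpha-lactose at a given water mole fraction
#'
#' Inverts the solubility-product condition at fixed `x_w`:
#' \eqn{x_{\alpha,sat}(x_w) = K_{sp} / (a_w(x_w)\gamma^*_\alpha(x_w))}.
#' Used both at and away from mutarotation equilibrium, under the model's
#' hypothesis that \eqn{a_w} and \eqn{\gamma^*_\alpha} depend on the total
#' dissolved sugar content (i.e. on `x_w`) rather than on the isomer ratio.
#'
#' @param x_w Water mole fraction(s) within the validity window.
#' @param model A [solubility_model()].
#' @return Saturation mole fraction(s) of alpha-lactose.
#' @export
x_alpha_sat <- function(x_w, model = solubility_model()) {
  check_sle(model)
  g <- gamma_star_isomers(x_w, model$margules, model$mutarotation)
  model$K_sp / (water_activity(x_w, model$margules) * g$gamma_alpha)
}

.x_alpha_sat <- function(x_w, K_sp, A, K_star, slope) {
  K_sp / (.aw(x_w, A) * exp(.ln_gamma_alpha(x_w, A, K_star, slope)))
}

#' Simultaneous solid--liquid and mutarotation equilibrium of lactose in water
#'
#' Solves \eqn{x_{\alpha,sat}(x_w)\,(1 + K_x(x_w)) = 1 - x_w} for the water
#' mole fraction by bracketed root finding on the validity window; at the root
#' the suspension is saturated with respect to the monohydrate and the
#' dissolved isomers are at their equilibrium ratio. The solution is
#' independent of the `K_x` slope (the \eqn{1 + K_x} factors cancel).
#'
#' @param model A [solubility_model()].
#' @param tol Absolute tolerance on the root residual.
#' @return A one-row tibble: `x_w_eq`, `x_alpha_eq`, `x_beta_eq`, `K_x_eq`,
#'   and the saturation concentrations `c_alpha_sat_eq`, `c_tot_sat_eq`
#'   in grams of (anhydrous) lactose per gram of water.
#' @export
#' @examples
#' equilibrium_solubility(solubility_model()) # x_w_eq ~ 0.9886
equilibrium_solubility <- function(model = solubility_model(), tol = 1e-12) {
  check_sle(model)
  m <- model$margules
  mut <- model$mutarotation
  lo <- mut$validity_window[1]
  f <- function(x_w) {
    .x_alpha_sat(x_w, model$K_sp, m$A, mut$K_star, mut$slope) *
      (1 + .kx(x_w, mut$K_star, mut$slope)) - (1 - x_w)
  }
  upper <- 1 - 1e-9
  if (f(lo) * f(upper) > 0) {
    abort(
      "No saturation point in the validity window for these parameters.",
      class = "isolact_no_solution_error"
    )
  }
  r <- uniroot(f, c(lo, upper), tol = 1e-14)
  x_w_eq <- r$root
  if (abs(f(x_w_eq)) > tol) {
    abort("Root residual above tolerance.", class = "isolact_numerical_error")
  }
  kx <- .kx(x_w_eq, mut$K_star, mut$slope)
  x_a <- (1 - x_w_eq) / (1 + kx)
  M_l <- molar_mass(model$registry, "alpha-lactose")
  M_w <- molar_mass(model$registry, "water")
  gw <- M_l / (x_w_eq * M_w) # mole fraction -> g per g water
  tibble(
    x_w_eq = x_w_eq,
    x_alpha_eq = x_a,
    x_beta_eq = kx * x_a,
    K_x_eq = kx,
    c_alpha_sat_eq = x_a * gw,
    c_tot_sat_eq = x_a * (1 + kx) * gw
  )
}

#' Solubility-depression parameter F
#'
#' First-order Taylor expansion of the saturation mole fraction of
#' alpha-lactose around the mutarotation-equilibrium saturation point: with
#' \eqn{S = dx_{\alpha,sat}/dx_w |_{eq} =
#' x_{\alpha,sat,eq}[-d\ln a_w/dx_w - d\ln\gamma^*_\alpha/dx_w]} (positive for
#' lactose defaults) and the mole-balance constraint
#' \eqn{x_w - x_{w,eq} = -(x_\beta - x_{\beta,eq}) -
#' (x_{\alpha,sat} - x_{\alpha,sat,eq})}, the depression of the alpha
#' saturation per unit of dissolved beta is \eqn{F = S/(1+S)} on the
#' mole-fraction basis.
#'
#' By default the composition dependence of `K_x` is frozen at its saturation
#' value (`include_slope = FALSE`), in which case
#' \eqn{d\ln\gamma^*_\alpha/dx_w = 2 A x_w}; setting `include_slope = TRUE`
#' adds the \eqn{K_x'/(1 + K_x)} term for sensitivity analysis.
#'
#' @inheritParams equilibrium_solubility
#' @param include_slope Include the `K_x` slope contribution to
#'   \eqn{d\ln\gamma^*_\alpha/dx_w}? Default `FALSE`.
#' @return The dimensionless `F` (mole-fraction basis); ~0.0433 for lactose
#'   defaults.
#' @export
f_parameter <- function(model = solubility_model(), include_slope = FALSE) {
  check_sle(model)
  eq <- equilibrium_solubility(model)
  A <- model$margules$A
  mut <- model$mutarotation
  x_w <- eq$x_w_eq
  dln_gamma <- 2 * A * x_w +
    if (include_slope) mut$slope / (1 + eq$K_x_eq) else 0
  x_sat <- .x_alpha_sat(x_w, model$K_sp, A, mut$K_star, mut$slope)
  S <- x_sat * (-.dln_aw_dxw(x_w, A) - dln_gamma)
  S / (1 + S)
}

#' Convert the F parameter between concentration bases
#'
#' `F` is a ratio of two concentration changes (alpha-lactose saturation vs
#' added depressant), so changing basis multiplies it by the ratio of the two
#' species' local (dilute-tracer) Jacobians \eqn{db_s/dx_s} evaluated at the
#' context composition: 1 for the mole-fraction basis, \eqn{M_s/\bar M} for
#' mass fraction of solution, and \eqn{M_s/(x_w M_w)} for grams per gram of
#' water. For two species of equal molar mass (the lactose anomers) every
#' conversion factor is unity; for a foreign depressant the factor is the
#' molar-mass ratio \eqn{M_\alpha/M_{dep}} when moving from the mole-fraction
#' to a mass-based basis.
#'
#' @param F_value The F parameter on `from_basis`.
#' @inheritParams convert_concentration
#' @param depressant Name of the depressing species (default the beta anomer).
#' @return The F parameter on `to_basis`.
#' @export
convert_f_basis <- function(F_value, from_basis, to_basis, comp,
                            depressant = "beta-lactose") {
  bases <- c("mole_fraction", "mass_fraction_solution", "g_per_g_water")
  from_basis <- rlang::arg_match(from_basis, bases)
  to_basis <- rlang::arg_match(to_basis, bases)
  if (identical(from_basis, to_basis)) {
    return(F_value)
  }
  M_bar <- sum(comp$mole_fraction * comp$molar_mass)
  M_w <- comp$molar_mass[comp$role == "solvent"][1]
  xw <- x_water(comp)
  lam <- function(species, basis) {
    M_s <- comp$molar_mass[match(tolower(species), tolower(comp$species))]
    if (is.na(M_s)) {
      abort_domain(sprintf("Species '%s' not in composition.", species))
    }
    switch(basis,
      mole_fraction = 1,
      mass_fraction_solution = M_s / M_bar,
      g_per_g_water = M_s / (xw * M_w)
    )
  }
  jac <- function(species) lam(species, to_basis) / lam(species, from_basis)
  F_value * jac("alpha-lactose") / jac(depressant)
}

#' Lactose solubility in the presence of a foreign sugar
#'
#' Predicts the total lactose solubility when a non-interconverting sugar is
#' dissolved alongside, using only the binary lactose--water parameters: the
#' foreign sugar enters solely by lowering the water mole fraction. The
#' saturation condition \eqn{a_w\gamma^*_\alpha x_\alpha = K_{sp}} is solved
#' together with the mole balance
#' \eqn{x_w(1 + \phi) + (1 + K_x(x_w))\,x_{\alpha,sat}(x_w) = 1}, where
#' \eqn{\phi} is the foreign-to-water mole ratio implied by the loading.
#'
#' @inheritParams equilibrium_solubility
#' @param foreign_loading Grams of foreign sugar per gram of water (>= 0);
#'   may be a vector.
#' @param foreign_species Registry name of the foreign sugar.
#' @return Total dissolved lactose at saturation, grams of anhydrous lactose
#'   per gram of water; strictly decreasing in `foreign_loading`.
#' @export
#' @examples
#' foreign_sugar_solubility(solubility_model(), c(0, 0.05, 0.1), "sucrose")
foreign_sugar_solubility <- function(model = solubility_model(),
                                     foreign_loading, foreign_species = "sucrose") {
  check_sle(model)
  if (any(foreign_loading < 0)) abort_domain("`foreign_loading` must be >= 0.")
  m <- model$margules
  mut <- model$mutarotation
  M_w <- molar_mass(model$registry, "water")
  M_l <- molar_mass(model$registry, "alpha-lactose")
  M_f <- molar_mass(model$registry, foreign_species)
  lo <- mut$validity_window[1]
  one <- function(load) {
    phi <- load * M_w / M_f # foreign moles per mole of water
    f <- function(x_w) {
      x_sat <- .x_alpha_sat(x_w, model$K_sp, m$A, mut$K_star, mut$slope)
      x_w * (1 + phi) + (1 + .kx(x_w, mut$K_star, mut$slope)) * x_sat - 1
    }
    if (f(lo) * f(1 - 1e-9) > 0) {
      abort_validity(
        "Foreign loading pushes the saturated solution outside the validity window."
      )
    }
    x_w <- uniroot(f, c(lo, 1 - 1e-9), tol = 1e-14)$root
    x_tot <- (1 + .kx(x_w, mut$K_star, mut$slope)) *
      .x_alpha_sat(x_w, model$K_sp, m$A, mut$K_star, mut$slope)
    x_tot * M_l / (x_w * M_w)
  }
  vapply(foreign_loading, one, numeric(1))
}

#' Foreign-sugar solubility-depression sweep
#'
#' Convenience wrapper evaluating [foreign_sugar_solubility()] on a grid of
#' loadings, returning results on both the g-per-g-water and
#' mass-fraction-of-solution bases.
#'
#' @inheritParams foreign_sugar_solubility
#' @param loadings Numeric vector of foreign-sugar loadings (g/g water).
#' @return A tibble: `loading`, `species`, `solubility_g_per_g_water`,
#'   `solubility_mass_fraction`.
#' @export
solubility_depression <- function(model = solubility_model(), loadings,
                                  foreign_species = "sucrose") {
  s <- foreign_sugar_solubility(model, loadings, foreign_species)
  tibble(
    loading = loadings,
    species = foreign_species,
    solubility_g_per_g_water = s,
    # solution mass per g water includes the dissolved lactose and the sugar
    solubility_mass_fraction = s / (1 + s + loadings)
  )
}

#' Classify the dissolution regime of a powder loading
#'
#' Compares the maximum attainable dissolved-lactose concentration of a
#' monohydrate loading (accounting for the water released by the hydrate:
#' \eqn{\chi L / (1 + (1-\chi)L)} grams of lactose per gram of water) against
#' the saturation concentrations at mutarotation equilibrium:
#' * **Type I** -- below `c_alpha_sat_eq`: the powder dissolves within
#'   seconds and the clear solution relaxes to mutarotation equilibrium;
#' * **Type II** -- between `c_alpha_sat_eq` and `c_tot_sat_eq`: saturation is
#'   reached first, then mutarotation undersaturates the solution and the
#'   solid eventually dissolves completely;
#' * **Type III** -- above `c_tot_sat_eq`: the suspension stays saturated
#'   while mutarotation equilibrium is established.
#'
#' @param loading Grams of monohydrate powder per gram of water (>= 0); may be
#'   a vector.
#' @inheritParams equilibrium_solubility
#' @return Character vector: `"Type I"`, `"Type II"` or `"Type III"`.
#' @export
#' @examples
#' classify_regime(c(0, 0.16, 0.30))
classify_regime <- function(loading, model = solubility_model()) {
  check_sle(model)
  if (any(loading < 0)) abort_domain("`loading` must be >= 0.")
  chi <- chi_stoichiometry(model$registry)
  eq <- equilibrium_solubility(model)
  potential <- chi * loading / (1 + (1 - chi) * loading)
  dplyr::case_when(
    potential <= eq$c_alpha_sat_eq ~ "Type I",
    potential <= eq$c_tot_sat_eq ~ "Type II",
    TRUE ~ "Type III"
  )
}

#' Regime thresholds on the powder-loading scale
#'
#' Loadings (g monohydrate per g water) at which the regime boundaries sit,
#' obtained by inverting the dissolved-lactose potential
#' \eqn{\chi L/(1 + (1-\chi)L)} at the two saturation concentrations.
#'
#' @inheritParams classify_regime
#' @return A one-row tibble: `type_I_II`, `type_II_III`.
#' @export
regime_thresholds <- function(model = solubility_model()) {
  check_sle(model)
  chi <- chi_stoichiometry(model$registry)
  eq <- equilibrium_solubility(model)
  inv <- function(c) c / (chi - (1 - chi) * c)
  tibble(
    type_I_II = inv(eq$c_alpha_sat_eq),
    type_II_III = inv(eq$c_tot_sat_eq)
  )
}
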