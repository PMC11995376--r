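#' Two-suffix Margules model for the water activity
#'
#' One-parameter excess-Gibbs-energy model for a binary solvent--solute
#' mixture, written on the mole-fraction scale with the pure liquid as the
#' water standard state:
#' \deqn{\ln \gamma_w = A (1 - x_w)^2.}
#' `A` is an empirical, temperature-specific constant that does not depend on
#' composition; for aqueous lactose at 25 degC the calibrated value is
#' `A = -5.8` (negative deviations from ideality, i.e. water--sugar
#' interactions stronger than the homotypic ones).
#'
#' @param A Margules constant (dimensionless, any finite sign).
#' @return An object of class `margules_model`.
#' @seealso [ln_gamma_water()], [water_activity()], [gamma_star_group()],
#'   [fit_margules()]
#' @export
#' @examples
#' m <- margules_model(-5.8)
#' water_activity(0.9886, m)
margules_model <- function(A = -5.8) {
  check_number(A, "A")
  structure(list(A = A), class = "margules_model")
}

#' @export
print.margules_model <- function(x, ...) {
  cat(sprintf("<margules_model> A = %g\n", x$A))
  invisible(x)
}

check_margules <- function(m) {
  if (!inherits(m, "margules_model")) abort_domain("Expected a `margules_model`.")
  m
}

check_xw_solvent <- function(x_w) {
  if (any(!is.finite(x_w)) || any(x_w <= 0) || any(x_w > 1)) {
    abort_domain("`x_w` must lie in (0, 1].")
  }
  x_w
}

#' Water activity coefficient, activity, and isomer-group activity coefficient
#'
#' `ln_gamma_water()` evaluates the Margules expression
#' \eqn{\ln \gamma_w = A(1-x_w)^2}; `water_activity()` returns
#' \eqn{a_w = x_w \gamma_w}; `gamma_star_group()` returns the activity
#' coefficient of the isomer group obtained by Gibbs--Duhem integration of the
#' Margules model from infinite dilution, on the solute standard state
#' (asterisk convention, \eqn{\gamma^* \to 1} as \eqn{x_w \to 1}):
#' \deqn{\ln \gamma^*_{iso} = A (x_w^2 - 1).}
#'
#' @param x_w Water mole fraction(s) in `(0, 1]`.
#' @param margules A [margules_model()].
#' @return Numeric vector, same length as `x_w`.
#' @export
ln_gamma_water <- function(x_w, margules = margules_model()) {
  check_margules(margules)
  check_xw_solvent(x_w)
  margules$A * (1 - x_w)^2
}

#' @rdname ln_gamma_water
#' @export
water_activity <- function(x_w, margules = margules_model()) {
  x_w * exp(ln_gamma_water(x_w, margules))
}

#' @rdname ln_gamma_water
#' @export
gamma_star_group <- function(x_w, margules = margules_model()) {
  check_margules(margules)
  check_xw_solvent(x_w)
  exp(margules$A * (x_w^2 - 1))
}

# unchecked fast paths for solver inner loops
.aw <- function(x_w, A) x_w * exp(A * (1 - x_w)^2)
.gamma_group <- function(x_w, A) exp(A * (x_w^2 - 1))
.dln_aw_dxw <- function(x_w, A) 1 / x_w - 2 * A * (1 - x_w)
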