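#' Per-isomer activity coefficients under mutarotation equilibrium
#'
#' For two isomers in chemical equilibrium in a solvent, integrating the
#' Gibbs--Duhem relation from infinite dilution (where both solute-standard-
#' state coefficients are unity and the measured ratio equals `K_star`) with
#' the two-suffix Margules model for the water activity gives closed forms
#' that depend on composition only through \eqn{x_w}:
#' \deqn{\ln \gamma^*_\alpha = A(x_w^2 - 1) + \ln\frac{1 + K_x(x_w)}{1 + K^*},}
#' \deqn{\ln \gamma^*_\beta  = A(x_w^2 - 1) + \ln\frac{1 + 1/K_x(x_w)}{1 + 1/K^*}.}
#' Subtracting the two recovers
#' \eqn{\ln \gamma^*_\alpha - \ln \gamma^*_\beta = \ln(K_x / K^*)}, the
#' thermodynamic-consistency identity that ties the drift of the measured
#' equilibrium ratio to the activity-coefficient ratio, and their
#' mole-fraction-weighted average equals the isomer-group coefficient up to an
#' exactly known ideal-mixing correction (a "corrected geometric average").
#'
#' @param x_w Water mole fraction(s) within the validity window.
#' @param margules A [margules_model()].
#' @param mutarotation A [mutarotation_model()].
#' @return A tibble with columns `x_w`, `K_x`, `gamma_alpha`, `gamma_beta`.
#'   Both coefficients tend to 1 as `x_w -> 1`.
#' @seealso [gamma_star_isomers_numeric()] for the numerical Gibbs--Duhem
#'   integration used as an independent oracle, [gamma_ratio_residual()] and
#'   [gamma_average_residual()] for the consistency identities.
#' @export
#' @examples
#' gamma_star_isomers(c(1, 0.9886), margules_model(-5.8),
#'                    mutarotation_model(1.60, slope = 3))
gamma_star_isomers <- function(x_w, margules = margules_model(),
                               mutarotation = mutarotation_model()) {
  check_margules(margules)
  kx <- equilibrium_ratio(x_w, mutarotation)
  base <- margules$A * (x_w^2 - 1)
  ks <- mutarotation$K_star
  tibble(
    x_w = x_w,
    K_x = kx,
    gamma_alpha = exp(base + log((1 + kx) / (1 + ks))),
    gamma_beta = exp(base + log((1 + 1 / kx) / (1 + 1 / ks)))
  )
}

# scalar fast path: ln gamma*_alpha without validation
.ln_gamma_alpha <- function(x_w, A, K_star, slope) {
  A * (x_w^2 - 1) + log((1 + .kx(x_w, K_star, slope)) / (1 + K_star))
}

#' Thermodynamic-consistency residuals of the per-isomer coefficients
#'
#' `gamma_ratio_residual()` returns
#' \eqn{\ln\gamma^*_\alpha - \ln\gamma^*_\beta - \ln(K_x/K^*)}, which must
#' vanish identically for thermodynamically consistent closed forms.
#' `gamma_average_residual()` checks that the composition-weighted average of
#' the per-isomer log-coefficients equals the isomer-group coefficient after
#' removing the ideal mixing term
#' \eqn{\ln\frac{1+K_x}{1+K^*} + \frac{K_x}{1+K_x}\ln\frac{K^*}{K_x}}:
#' the returned residual must also vanish. Both are used as property tests;
#' they hold to machine precision for any `A`, `K_star`, `slope` and `x_w` in
#' the validity window.
#'
#' @inheritParams gamma_star_isomers
#' @return Numeric residual(s), zero up to floating-point round-off.
#' @export
gamma_ratio_residual <- function(x_w, margules = margules_model(),
                                 mutarotation = mutarotation_model()) {
  g <- gamma_star_isomers(x_w, margules, mutarotation)
  log(g$gamma_alpha) - log(g$gamma_beta) - log(g$K_x / mutarotation$K_star)
}

#' @rdname gamma_ratio_residual
#' @export
gamma_average_residual <- function(x_w, margules = margules_model(),
                                   mutarotation = mutarotation_model()) {
  g <- gamma_star_isomers(x_w, margules, mutarotation)
  kx <- g$K_x
  ks <- mutarotation$K_star
  f_alpha <- 1 / (1 + kx) # x_alpha / x_iso
  f_beta <- kx / (1 + kx)
  avg <- f_alpha * log(g$gamma_alpha) + f_beta * log(g$gamma_beta)
  mixing <- log((1 + kx) / (1 + ks)) + f_beta * log(ks / kx)
  avg - mixing - log(gamma_star_group(x_w, margules))
}

#' Numerical Gibbs--Duhem integration of the per-isomer coefficients
#'
#' Independent numerical route to the same quantities as
#' [gamma_star_isomers()]: the differential
#' \deqn{d\ln\gamma^*_\alpha = \Big[\frac{1 - x_w\, d\ln a_w/dx_w}{1 - x_w}
#'       + \frac{K_x'}{1 + K_x}\Big] dx_w}
#' (and the analogous expression with \eqn{-K_x'/(K_x(1+K_x))} for the beta
#' isomer) is assembled directly from the Margules water activity and the
#' measured-ratio model, then integrated by the composite trapezoidal rule
#' from infinite dilution (`x_w = 1`) down to the target composition. No step
#' of the closed-form integration is reused, so this serves as an oracle for
#' it. The integrand's two singular-looking terms cancel analytically; at the
#' endpoint `x_w = 1` the removable limit (`2A`) is used.
#'
#' @inheritParams gamma_star_isomers
#' @param steps Number of trapezoid intervals (>= 100). At `steps = 1e4` the
#'   result agrees with the closed form to better than 1e-6 relative.
#' @param tol Convergence tolerance: the integral is also evaluated at half
#'   the steps and the relative change must not exceed `tol`.
#' @return A tibble with columns `x_w`, `gamma_alpha`, `gamma_beta`.
#' @export
gamma_star_isomers_numeric <- function(x_w, margules = margules_model(),
                                       mutarotation = mutarotation_model(),
                                       steps = 1e4, tol = 1e-6) {
  check_margules(margules)
  check_mutarotation(mutarotation)
  check_xw_window(x_w, mutarotation)
  if (steps < 100) abort_domain("`steps` must be at least 100.")
  A <- margules$A
  ks <- mutarotation$K_star
  sl <- mutarotation$slope

  integrand <- function(x, which) {
    base <- ifelse(
      x == 1, 2 * A,
      (1 - x * .dln_aw_dxw(x, A)) / (1 - x)
    )
    kx <- .kx(x, ks, sl)
    if (which == "alpha") base + sl / (1 + kx) else base - sl / (kx * (1 + kx))
  }
  trap <- function(target, n, which) {
    grid <- seq(target, 1, length.out = n + 1)
    f <- integrand(grid, which)
    h <- (1 - target) / n
    # ln gamma at target = integral from 1 down to target = -(trapz over grid)
    -h * (sum(f) - (f[1] + f[n + 1]) / 2)
  }
  one <- function(target, which) {
    if (target == 1) {
      return(1)
    }
    full <- trap(target, steps, which)
    half <- trap(target, max(100, steps %/% 2), which)
    if (abs(full - half) > tol * max(abs(full), 1e-12) + 1e-12) {
      abort(
        "Gibbs-Duhem quadrature did not converge; increase `steps`.",
        class = "isolact_numerical_error"
      )
    }
    exp(full)
  }
  tibble(
    x_w = x_w,
    gamma_alpha = vapply(x_w, one, numeric(1), which = "alpha"),
    gamma_beta = vapply(x_w, one, numeric(1), which = "beta")
  )
}
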