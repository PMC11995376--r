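#' Calibrate the Margules constant from water-activity data
#'
#' Fits `A` by least squares through the origin of the linearized Margules
#' relation: with \eqn{y = \ln(a_w / x_w)} and \eqn{z = (1 - x_w)^2},
#' \eqn{y = A z} exactly, and the Margules form forces a zero intercept
#' (\eqn{\ln \gamma_w = 0} at \eqn{x_w = 1}). The reported uncertainty is the
#' regression standard error of the slope. Records at `x_w = 1` carry no
#' information about `A` and are excluded from the fit.
#'
#' @param data Data frame with columns `x_w` (water mole fraction, in `(0,1]`)
#'   and `a_w` (water activity, in `(0, 1.05]`; small super-unity values are
#'   tolerated as measurement noise). An optional `sd` column (replicate
#'   standard deviation) enables a weighted fit.
#' @param weighted If `TRUE` and an `sd` column is present, weight records by
#'   `1/sd^2`. Off by default.
#' @return An object of class `margules_fit` with elements `A`, `se_A`, the
#'   underlying `lm` fit and the data used. Supports [tidy()], [glance()],
#'   [autoplot()] and [as_margules_model()].
#' @export
#' @examples
#' d <- synth_water_activity(fixture_spec(seed = 1))
#' fit_margules(d)
fit_margules <- function(data, weighted = FALSE) {
  data <- as_tibble(data)
  if (!all(c("x_w", "a_w") %in% names(data))) {
    abort_domain("`data` needs columns `x_w` and `a_w`.")
  }
  if (any(data$x_w <= 0) || any(data$x_w > 1)) {
    abort_domain("`x_w` must lie in (0, 1].")
  }
  if (any(data$a_w <= 0) || any(data$a_w > 1.05)) {
    abort_domain("`a_w` must lie in (0, 1.05].")
  }
  d <- dplyr::filter(data, .data$x_w < 1)
  if (dplyr::n_distinct(d$x_w) < 1 || nrow(d) < 2) {
    abort_domain(
      "Degenerate design: need at least two records with x_w < 1."
    )
  }
  d <- dplyr::mutate(d,
    z = (1 - .data$x_w)^2,
    y = log(.data$a_w / .data$x_w)
  )
  w <- if (weighted && "sd" %in% names(d)) 1 / d$sd^2 else NULL
  fit <- lm(y ~ 0 + z, data = d, weights = w)
  s <- summary(fit)$coefficients
  structure(
    list(
      A = unname(coef(fit)[["z"]]),
      se_A = unname(s["z", "Std. Error"]),
      fit = fit, data = data, n = nrow(d)
    ),
    class = "margules_fit"
  )
}

#' Calibrate the mutarotation equilibrium model from isomer-ratio data
#'
#' Ordinary least squares of the measured equilibrium ratio `K_x` on
#' \eqn{1 - x_w}. The intercept is the thermodynamic constant `K_star`
#' (the linear extrapolation of the measured ratios to infinite dilution,
#' `x_w -> 1`) and the negated coefficient is the composition slope
#' \eqn{dK_x/dx_w}.
#'
#' @param data Data frame with columns `x_w` and `K_x` (> 0); optional `sd`
#'   column for a weighted fit.
#' @inheritParams fit_margules
#' @return An object of class `mutarotation_fit` with elements `K_star`,
#'   `slope`, `se_K_star`, the `lm` fit and the data. Supports [tidy()],
#'   [glance()], [autoplot()] and [as_mutarotation_model()].
#' @export
fit_mutarotation <- function(data, weighted = FALSE) {
  data <- as_tibble(data)
  if (!all(c("x_w", "K_x") %in% names(data))) {
    abort_domain("`data` needs columns `x_w` and `K_x`.")
  }
  if (any(data$K_x <= 0)) abort_domain("`K_x` must be positive.")
  if (dplyr::n_distinct(data$x_w) < 2) {
    abort_domain("Degenerate design: need at least two distinct x_w values.")
  }
  d <- dplyr::mutate(data, z = 1 - .data$x_w)
  w <- if (weighted && "sd" %in% names(d)) 1 / d$sd^2 else NULL
  fit <- lm(K_x ~ z, data = d, weights = w)
  s <- summary(fit)$coefficients
  structure(
    list(
      K_star = unname(coef(fit)[["(Intercept)"]]),
      slope = -unname(coef(fit)[["z"]]),
      se_K_star = unname(s["(Intercept)", "Std. Error"]),
      fit = fit, data = data, n = nrow(d)
    ),
    class = "mutarotation_fit"
  )
}

#' Turn calibration fits into model objects
#'
#' @param fit A `margules_fit` or `mutarotation_fit`.
#' @param k_alpha Forward kinetic constant (1/h) to attach to the
#'   mutarotation model (not estimated by the equilibrium fit).
#' @return A [margules_model()] or [mutarotation_model()].
#' @export
as_margules_model <- function(fit) {
  stopifnot(inherits(fit, "margules_fit"))
  margules_model(fit$A)
}

#' @rdname as_margules_model
#' @export
as_mutarotation_model <- function(fit, k_alpha = 0.64) {
  stopifnot(inherits(fit, "mutarotation_fit"))
  mutarotation_model(
    K_star = fit$K_star, slope = max(0, fit$slope), k_alpha = k_alpha
  )
}

#' @export
print.margules_fit <- function(x, ...) {
  cat(sprintf(
    "<margules_fit> A = %.4f +/- %.4f (n = %d)\n", x$A, x$se_A, x$n
  ))
  invisible(x)
}

#' @export
print.mutarotation_fit <- function(x, ...) {
  cat(sprintf(
    "<mutarotation_fit> K* = %.4f +/- %.4f, dK_x/dx_w = %.3f (n = %d)\n",
    x$K_star, x$se_K_star, x$slope, x$n
  ))
  invisible(x)
}

# delimited-text readers ----------------------------------------------------

#' Read measurement tables from delimited text
#'
#' Comma-separated, UTF-8, header row required. `read_activity_data()` expects
#' columns `x_w` and `a_w`; `read_ratio_data()` expects `x_w` and `K_x`; an
#' optional `sd` column is kept if present.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_activity_data <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x_w", "a_w") %in% names(d))) {
    abort_domain(sprintf("%s must have columns x_w and a_w.", path))
  }
  d[intersect(c("x_w", "a_w", "sd"), names(d))]
}

#' @rdname read_activity_data
#' @export
read_ratio_data <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x_w", "K_x") %in% names(d))) {
    abort_domain(sprintf("%s must have columns x_w and K_x.", path))
  }
  d[intersect(c("x_w", "K_x", "sd"), names(d))]
}
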