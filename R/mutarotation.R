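#' Mutarotation model
#'
#' Holds the thermodynamic mutarotation equilibrium constant `K_star` (the
#' beta:alpha mole-fraction ratio extrapolated to infinite dilution, where the
#' activity-coefficient ratio is unity), the composition dependence of the
#' equilibrium ratio, and the forward kinetic constant.
#'
#' The composition dependence is linear in the water mole fraction, matching
#' how `K_star` is obtained by linear extrapolation of measured ratios:
#' \deqn{K_x(x_w) = K^* - s\,(1 - x_w),}
#' with `slope` \eqn{s = dK_x/dx_w \ge 0}, so that \eqn{K_x} decreases as the
#' solution gets more concentrated and \eqn{K_x(1) = K^*} exactly. The model
#' is declared valid for \eqn{x_w \in [0.9, 1]}; outside that window functions
#' raise a validity error rather than extrapolate silently.
#'
#' @param K_star Thermodynamic equilibrium constant (> 0). Default 1.60 for
#'   lactose at 25 degC (inferred; see the methods vignette).
#' @param slope Composition sensitivity \eqn{dK_x/dx_w \ge 0} (default 0, i.e.
#'   constant ratio).
#' @param k_alpha Forward mutarotation kinetic constant in 1/h (default 0.64
#'   for lactose at 25 degC).
#' @param validity_window Numeric length-2 range of `x_w` over which the model
#'   may be evaluated.
#' @return An object of class `mutarotation_model`.
#' @export
#' @examples
#' mut <- mutarotation_model(K_star = 1.60, slope = 3)
#' equilibrium_ratio(0.9886, mut)
mutarotation_model <- function(K_star = 1.60, slope = 0, k_alpha = 0.64,
                               validity_window = c(0.9, 1)) {
  check_number(K_star, "K_star", lower = 0, allow_zero = FALSE)
  check_number(slope, "slope", lower = 0)
  check_number(k_alpha, "k_alpha", lower = 0)
  if (K_star - slope * (1 - validity_window[1]) <= 0) {
    abort_validity(
      "K_x(x_w) must stay positive over the validity window; reduce `slope`."
    )
  }
  structure(
    list(
      K_star = K_star, slope = slope, k_alpha = k_alpha,
      validity_window = validity_window
    ),
    class = "mutarotation_model"
  )
}

#' @export
print.mutarotation_model <- function(x, ...) {
  cat(sprintf(
    "<mutarotation_model> K* = %g, dK_x/dx_w = %g, k_alpha = %g 1/h\n",
    x$K_star, x$slope, x$k_alpha
  ))
  invisible(x)
}

check_mutarotation <- function(mut) {
  if (!inherits(mut, "mutarotation_model")) {
    abort_domain("Expected a `mutarotation_model`.")
  }
  mut
}

check_xw_window <- function(x_w, mut) {
  w <- mut$validity_window
  if (any(!is.finite(x_w)) || any(x_w < w[1]) || any(x_w > w[2])) {
    abort_validity(sprintf(
      "`x_w` outside the model validity window [%g, %g].", w[1], w[2]
    ))
  }
  x_w
}

#' Equilibrium beta:alpha mole-fraction ratio at a given composition
#'
#' @param x_w Water mole fraction(s) within the model's validity window.
#' @param mutarotation A [mutarotation_model()].
#' @return \eqn{K_x(x_w) = K^* - s (1 - x_w)}, always positive.
#' @export
equilibrium_ratio <- function(x_w, mutarotation = mutarotation_model()) {
  check_mutarotation(mutarotation)
  check_xw_window(x_w, mutarotation)
  kx <- .kx(x_w, mutarotation$K_star, mutarotation$slope)
  if (any(kx <= 0)) {
    abort_validity("K_x(x_w) <= 0: model not valid at this composition.")
  }
  kx
}

.kx <- function(x_w, K_star, slope) K_star - slope * (1 - x_w)
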