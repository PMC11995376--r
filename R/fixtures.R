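#' Specification for synthetic measurement fixtures
#'
#' Describes the synthetic water-activity and isomer-ratio tables the
#' generators produce: the underlying true parameters, the composition grid,
#' and additive homoscedastic Gaussian noise (measurement tables of this kind
#' report symmetric +/- 1 sd error bars, which additive Gaussian noise
#' emulates). All generators are bit-reproducible for a fixed seed.
#'
#' @param A_true True Margules constant (default -5.8).
#' @param K_star_true True thermodynamic mutarotation constant (default 1.60).
#' @param slope_true True composition slope of the equilibrium ratio
#'   (default 1.5).
#' @param x_w_grid Water mole fractions of the measurement grid, within
#'   `(0.9, 1]` (default 20 points on `[0.96, 0.999]`, spanning dilute to
#'   supersaturated solutions).
#' @param noise_sd_aw Additive noise sd on the water activity (default 5e-4,
#'   the resolution of a dew-point water-activity meter).
#' @param noise_sd_kx Additive noise sd on the measured ratio (default 0.01).
#' @param seed Integer RNG seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(A_true = -5.8, K_star_true = 1.60, slope_true = 1.5,
                         x_w_grid = seq(0.96, 0.999, length.out = 20),
                         noise_sd_aw = 5e-4, noise_sd_kx = 0.01, seed = 1L) {
  check_number(A_true, "A_true")
  check_number(K_star_true, "K_star_true", lower = 0, allow_zero = FALSE)
  check_number(slope_true, "slope_true", lower = 0)
  check_number(noise_sd_aw, "noise_sd_aw", lower = 0)
  check_number(noise_sd_kx, "noise_sd_kx", lower = 0)
  if (any(x_w_grid <= 0.9) || any(x_w_grid > 1)) {
    abort_domain("`x_w_grid` must lie within (0.9, 1].")
  }
  structure(
    list(
      A_true = A_true, K_star_true = K_star_true, slope_true = slope_true,
      x_w_grid = x_w_grid, noise_sd_aw = noise_sd_aw,
      noise_sd_kx = noise_sd_kx, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate synthetic measurement tables
#'
#' `synth_water_activity()` draws water-activity measurements
#' \eqn{a_w = x_w \exp(A (1-x_w)^2) + \epsilon} and `synth_kx_ratio()` draws
#' equilibrium-ratio measurements
#' \eqn{K_x = K^* - s(1 - x_w) + \epsilon} on the grid of the spec, with iid
#' Gaussian noise. These tables have exactly the schema the calibration
#' readers and fitters expect.
#'
#' @param spec A [fixture_spec()].
#' @return A tibble: `x_w`, `a_w` (respectively `x_w`, `K_x`) plus an `sd`
#'   column recording the noise level.
#' @export
#' @examples
#' fit_margules(synth_water_activity(fixture_spec(seed = 7)))
synth_water_activity <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    x <- spec$x_w_grid
    a <- x * exp(spec$A_true * (1 - x)^2) +
      rnorm(length(x), sd = spec$noise_sd_aw)
    tibble(x_w = x, a_w = a, sd = spec$noise_sd_aw)
  })
}

#' @rdname synth_water_activity
#' @export
synth_kx_ratio <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    x <- spec$x_w_grid
    k <- spec$K_star_true - spec$slope_true * (1 - x) +
      rnorm(length(x), sd = spec$noise_sd_kx)
    if (any(k <= 0)) {
      abort(
        "Generated K_x <= 0; lower the noise or the slope.",
        class = "isolact_generation_error"
      )
    }
    tibble(x_w = x, K_x = k, sd = spec$noise_sd_kx)
  })
}

#' Write synthetic tables to delimited text
#'
#' Emits the same CSV schema the calibration readers consume.
#'
#' @param data A tibble from [synth_water_activity()] or [synth_kx_ratio()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
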