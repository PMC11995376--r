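# ggplot2 autoplot methods

#' @export
autoplot.margules_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(x_w = seq(min(d$x_w), max(d$x_w), length.out = 200))
  grid$a_w <- water_activity(grid$x_w, as_margules_model(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_w, y = .data$a_w)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = "water mole fraction",
      y = "water activity",
      title = sprintf("Margules fit: A = %.2f ± %.2f", object$A, object$se_A)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mutarotation_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(x_w = seq(min(d$x_w), 1, length.out = 100))
  grid$K_x <- object$K_star - object$slope * (1 - grid$x_w)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_w, y = .data$K_x)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::annotate(
      "point",
      x = 1, y = object$K_star, shape = 4, size = 3, colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "water mole fraction",
      y = expression(K[x]),
      title = sprintf(
        "Equilibrium-ratio fit: K* = %.3f ± %.3f",
        object$K_star, object$se_K_star
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sim_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object)[c("t", "c_alpha", "c_beta", "c_tot")],
    -"t",
    names_to = "series", values_to = "mass_fraction"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$t, y = .data$mass_fraction, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time [h]", y = "mass fraction of solution",
      title = sprintf("%s dissolution run", attr(object, "regime")),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a foreign-sugar solubility-depression sweep
#'
#' @param depression A tibble from [solubility_depression()].
#' @return A ggplot.
#' @export
plot_depression <- function(depression) {
  ggplot2::ggplot(
    depression,
    ggplot2::aes(x = .data$loading, y = .data$solubility_g_per_g_water)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "foreign sugar loading [g/g water]",
      y = "total lactose solubility [g/g water]",
      title = unique(depression$species)
    ) +
    ggplot2::theme_minimal()
}
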