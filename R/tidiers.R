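# broom-style tidiers for the fitted/derived objects

#' @export
tidy.margules_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = "A",
    estimate = x$A,
    std.error = x$se_A,
    statistic = s["z", "t value"],
    p.value = s["z", "Pr(>|t|)"]
  )
}

#' @export
glance.margules_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = x$n,
    df.residual = x$fit$df.residual
  )
}

#' @export
tidy.mutarotation_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("K_star", "slope"),
    estimate = c(x$K_star, x$slope),
    std.error = c(x$se_K_star, s["z", "Std. Error"]),
    statistic = c(s["(Intercept)", "t value"], -s["z", "t value"]),
    p.value = c(s["(Intercept)", "Pr(>|t|)"], s["z", "Pr(>|t|)"])
  )
}

#' @export
glance.mutarotation_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = x$n,
    df.residual = x$fit$df.residual
  )
}

#' @export
tidy.sim_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sim_result")
  for (a in c(
    "params", "regime", "dissolution_time", "conservation",
    "seed_population", "suspension_mass"
  )) {
    attr(out, a) <- NULL
  }
  out
}

#' @export
glance.sim_result <- function(x, ...) {
  cons <- attr(x, "conservation")
  last <- x[nrow(x), ]
  tibble(
    regime = attr(x, "regime"),
    dissolution_time = attr(x, "dissolution_time"),
    t_final = last$t,
    c_alpha_final = last$c_alpha,
    c_beta_final = last$c_beta,
    c_tot_final = last$c_tot,
    x_w_final = last$x_w,
    m_cry_final = last$m_cry,
    conservation_lactose = cons[["lactose"]],
    conservation_water = cons[["water"]],
    conservation_total = cons[["total"]]
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %s run, %d time points to %g h; solids %s\n",
    attr(x, "regime"), nrow(x), max(x$t),
    if (is.na(attr(x, "dissolution_time"))) {
      "persist"
    } else {
      sprintf("fully dissolved at %.3g h", attr(x, "dissolution_time"))
    }
  ))
  NextMethod()
}
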