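#' Rate laws of the dissolution--mutarotation model
#'
#' `mutarotation_rate()` is the first-order reversible interconversion rate
#' referenced to the mass of solution, \eqn{r = k_\alpha c_\alpha -
#' (k_\alpha / K_x) c_\beta} (mass fractions; the backward constant is tied to
#' the equilibrium ratio for thermodynamic consistency, and mass ratio equals
#' mole ratio because the anomers share a molar mass). `dissolution_rate()` is
#' the size-independent linear-driving-force shrinkage rate
#' \eqn{D = k_D (x_{\alpha,sat} - x_\alpha)} in m/s.
#'
#' @param c_alpha,c_beta Mass fractions of dissolved alpha-/beta-lactose in
#'   solution.
#' @param K_x Equilibrium beta:alpha ratio at the current composition (> 0).
#' @param k_alpha Forward kinetic constant, 1/h.
#' @return `mutarotation_rate()`: rate of change of the beta mass fraction,
#'   1/h; zero exactly at `c_beta = K_x * c_alpha`.
#' @export
mutarotation_rate <- function(c_alpha, c_beta, K_x, k_alpha = 0.64) {
  if (any(K_x <= 0)) abort_domain("`K_x` must be positive.")
  k_alpha * c_alpha - (k_alpha / K_x) * c_beta
}

#' @rdname mutarotation_rate
#' @param x_alpha_sat,x_alpha Saturation and actual alpha-lactose mole
#'   fractions.
#' @param k_D Dissolution kinetic constant, m/s.
#' @return `dissolution_rate()`: crystal shrinkage rate `-dL/dt` in m/s.
#' @export
dissolution_rate <- function(x_alpha_sat, x_alpha, k_D = 1e-3) {
  k_D * (x_alpha_sat - x_alpha)
}

#' Closed-form mutarotation relaxation of a solids-free solution
#'
#' With no solid phase the two-isomer linear kinetics at fixed total
#' concentration relax exponentially with rate
#' \eqn{\lambda = k_\alpha (1 + 1/K_x)}:
#' \eqn{c_\beta(t) = c_{\beta,eq} + (c_\beta(0) - c_{\beta,eq}) e^{-\lambda t}}
#' with \eqn{c_{\beta,eq} = c_{tot} K_x/(1+K_x)}. Used as the analytic oracle
#' for the simulator after complete dissolution.
#'
#' @param t Time(s) in hours.
#' @param c_alpha0,c_beta0 Initial mass fractions.
#' @inheritParams mutarotation_rate
#' @return A tibble with columns `t`, `c_alpha`, `c_beta`.
#' @export
mutarotation_relaxation <- function(t, c_alpha0, c_beta0, K_x,
                                    k_alpha = 0.64) {
  c_tot <- c_alpha0 + c_beta0
  c_beta_eq <- c_tot * K_x / (1 + K_x)
  lambda <- k_alpha * (1 + 1 / K_x)
  c_beta <- c_beta_eq + (c_beta0 - c_beta_eq) * exp(-lambda * t)
  tibble(t = t, c_alpha = c_tot - c_beta, c_beta = c_beta)
}

#' Simulation parameters
#'
#' Collects the physical constants, seed-distribution specification, loading
#' and solver controls of the dissolution simulator. Defaults are the
#' alpha-lactose monohydrate values at 25 degC; masses in grams, sizes in
#' metres, times in hours (the SI `k_D` in m/s is converted internally).
#'
#' @param loading Grams of monohydrate powder per gram of water (>= 0).
#' @param water_mass Grams of solvent water (default 50).
#' @param horizon Simulation horizon in hours (default 15).
#' @param rho_c Crystal density, kg/m^3 (default 1545).
#' @param k_v Volumetric shape factor (default pi/6).
#' @param k_D Dissolution kinetic constant, m/s (default 1e-3).
#' @param K_sp Solubility product (default 0.00494).
#' @param margules,mutarotation Activity models (see [margules_model()] and
#'   [mutarotation_model()]; `k_alpha` lives on the mutarotation model).
#' @param psd_mean,psd_sd,n_characteristics Seed PSD specification (see
#'   [seed_psd()]).
#' @param registry Species registry (supplies chi and molar masses).
#' @param rtol,atol_size,atol_mass Integrator tolerances (relative; absolute
#'   on sizes in m and on masses in g).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(loading, water_mass = 50, horizon = 15,
                       rho_c = 1545, k_v = pi / 6, k_D = 1e-3,
                       K_sp = 0.00494,
                       margules = margules_model(),
                       mutarotation = mutarotation_model(),
                       psd_mean = 10e-6, psd_sd = 1e-6,
                       n_characteristics = 200,
                       registry = species_registry(),
                       rtol = 1e-12, atol_size = 1e-16, atol_mass = 1e-12) {
  check_number(loading, "loading", lower = 0)
  check_number(water_mass, "water_mass", lower = 0, allow_zero = FALSE)
  check_number(horizon, "horizon", lower = 0, allow_zero = FALSE)
  check_number(rho_c, "rho_c", lower = 0, allow_zero = FALSE)
  check_number(k_v, "k_v", lower = 0, allow_zero = FALSE)
  check_number(k_D, "k_D", lower = 0, allow_zero = FALSE)
  check_number(K_sp, "K_sp", lower = 0, allow_zero = FALSE)
  check_margules(margules)
  check_mutarotation(mutarotation)
  structure(
    list(
      loading = loading, water_mass = water_mass, horizon = horizon,
      rho_c = rho_c, k_v = k_v, k_D = k_D, K_sp = K_sp,
      margules = margules, mutarotation = mutarotation,
      psd_mean = psd_mean, psd_sd = psd_sd,
      n_characteristics = n_characteristics,
      registry = validate_registry(registry),
      rtol = rtol, atol_size = atol_size, atol_mass = atol_mass
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> loading %g g/g water in %g g water, horizon %g h, %d characteristics\n",
    x$loading, x$water_mass, x$horizon, x$n_characteristics
  ))
  invisible(x)
}

as_solubility_model <- function(params) {
  solubility_model(
    K_sp = params$K_sp, margules = params$margules,
    mutarotation = params$mutarotation, registry = params$registry
  )
}

default_sim_times <- function(horizon) {
  # dense early grid resolves the seconds-scale dissolution transient
  t <- c(
    seq(0, min(0.02, horizon), by = 5e-4),
    seq(0.025, min(0.5, horizon), by = 0.005),
    if (horizon > 0.5) seq(0.51, horizon, by = 0.01)
  )
  sort(unique(c(t, horizon)))
}

#' Simulate the dissolution of alpha-lactose monohydrate
#'
#' Integrates the coupled model: one mass balance per solution component
#' (alpha-lactose, beta-lactose, water), first-order reversible mutarotation
#' in the liquid, a linear-driving-force dissolution rate that is independent
#' of crystal size, and the crystal population balance solved by the method
#' of characteristics (each characteristic size obeys `dL/dt = -D`; the
#' number weights per unit suspension mass are constant in time). Because `D`
#' does not depend on crystal size, all characteristics shrink in lockstep:
#' the solver integrates a single cumulative shrinkage coordinate
#' \eqn{s(t) = \int_0^t D\,dt'} and reconstructs
#' \eqn{L_i(t) = \max(L_{0,i} - s, 0)} exactly -- the method of
#' characteristics in its size-independent form. A characteristic whose
#' initial size has been consumed (`s > L_0i`) is frozen at zero and stops
#' contributing to the moments; its surface term vanishes quadratically
#' there, so the mass balances stay C1-smooth and conservative through every
#' crossing. Solid activity is taken as unity; the saturation mole fraction
#' driving dissolution is evaluated from the solubility product at the
#' current water mole fraction.
#'
#' Integration uses `deSolve::lsoda` (adaptive, stiffness-switching), which
#' resolves the seconds-scale initial dissolution transient as well as the
#' hours-scale mutarotation relaxation.
#'
#' @param params A [sim_params()].
#' @param times Optional output time grid (hours); defaults to a grid dense at
#'   early times.
#' @return A `sim_result`: tibble with columns `t` (h), `c_alpha`, `c_beta`,
#'   `c_tot` (mass fractions of solution), `c_alpha_gw`, `c_tot_gw` (g per g
#'   water), `x_w`, `a_w`, `gamma_alpha`, `x_alpha`, `x_alpha_sat`, `m_cry`
#'   (g). Attributes: `params`, `regime` (from [classify_regime()]),
#'   `dissolution_time` (h, `NA` if solids persist), `conservation`
#'   (worst-case relative drifts), `final` (last row).
#' @export
#' @examples
#' \donttest{
#' res <- simulate_dissolution(sim_params(loading = 0.30, horizon = 12))
#' glance(res)
#' }
simulate_dissolution <- function(params, times = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  chi <- chi_stoichiometry(p$registry)
  M_w <- molar_mass(p$registry, "water")
  M_l <- molar_mass(p$registry, "alpha-lactose")
  times <- times %||% default_sim_times(p$horizon)
  k_D_h <- p$k_D * 3600 # m/s -> m/h
  rho_g <- p$rho_c * 1e3 # g/m^3

  if (p$loading == 0) {
    pop <- seed_psd(p$psd_mean, p$psd_sd, p$n_characteristics)
    w <- rep(0, nrow(pop))
    L0 <- pop$size
    m_susp <- p$water_mass
  } else {
    pop <- seed_psd(p$psd_mean, p$psd_sd, p$n_characteristics)
    pop <- scale_psd_to_loading(pop, p$loading, p$water_mass, p$rho_c, p$k_v)
    w <- pop$weight
    L0 <- pop$size
    m_susp <- attr(pop, "suspension_mass")
  }
  nL <- length(L0)
  A <- p$margules$A
  ks <- p$mutarotation$K_star
  sl <- p$mutarotation$slope
  k_a <- p$mutarotation$k_alpha

  s_max <- max(L0) # beyond this every characteristic is exhausted

  rhs <- function(t, y, parms) {
    s <- y[1]
    m_a <- y[2]
    m_b <- y[3]
    m_w <- y[4]
    m_sol <- m_a + m_b + m_w
    n_w <- m_w / M_w
    n_a <- m_a / M_l
    n_b <- m_b / M_l
    n_tot <- n_w + n_a + n_b
    x_w <- n_w / n_tot
    x_a <- n_a / n_tot
    kx <- .kx(x_w, ks, sl)
    x_sat <- .x_alpha_sat(x_w, p$K_sp, A, ks, sl)
    # dissolution-only: growth is outside the model scope, so transient
    # overshoots of saturation (integrator-scale) do not regrow crystals
    D <- max(k_D_h * (x_sat - x_a), 0)
    L <- L0 - s
    active <- L > 0
    ds <- if (s < s_max) D else 0
    dm_cry <- -3 * rho_g * p$k_v * m_susp * D *
      sum(w[active] * L[active]^2)
    r <- k_a * (m_a / m_sol) - (k_a / kx) * (m_b / m_sol)
    dm_a <- -chi * dm_cry - r * m_sol
    dm_b <- r * m_sol
    dm_w <- -(1 - chi) * dm_cry
    list(c(ds, dm_a, dm_b, dm_w))
  }

  # solids-free kinetics (phase after complete dissolution): only mutarotation
  rhs_clear <- function(t, y, parms) {
    m_sol <- sum(y)
    kx_clear <- .kx(parms$x_w, ks, sl)
    r <- k_a * (y[1] / m_sol) - (k_a / kx_clear) * (y[2] / m_sol)
    list(c(-r * m_sol, r * m_sol, 0))
  }

  y0 <- c(0, 0, 0, p$water_mass)
  atol <- c(p$atol_size, rep(p$atol_mass, 3))
  sol <- deSolve::lsodar(
    y = y0, times = times, func = rhs, parms = NULL,
    rootfunc = function(t, y, parms) y[1] - s_max,
    rtol = p$rtol, atol = atol, maxsteps = 1e5
  )
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE integration failed.", class = "isolact_numerical_error")
  }
  troot <- attr(sol, "troot")
  event_time <- if (length(troot) && is.finite(troot[1])) troot[1] else NA_real_
  if (!is.na(event_time) && event_time < max(times)) {
    # complete dissolution: continue the smooth solids-free relaxation
    y_end <- sol[nrow(sol), -1]
    m_w_end <- y_end[4]
    n_clear <- (y_end[2] + y_end[3]) / M_l + m_w_end / M_w
    x_w_clear <- (m_w_end / M_w) / n_clear
    times2 <- c(event_time, times[times > event_time])
    sol2 <- deSolve::lsoda(
      y = y_end[2:4], times = times2, func = rhs_clear,
      parms = list(x_w = x_w_clear),
      rtol = p$rtol, atol = atol[2:4], maxsteps = 1e5
    )
    if (attr(sol2, "istate")[1] < 0) {
      abort("ODE integration failed.", class = "isolact_numerical_error")
    }
    sol2 <- sol2[-1, , drop = FALSE]
    sol <- rbind(
      sol,
      cbind(sol2[, 1], s_max, sol2[, 2:4], deparse.level = 0)
    )
  }

  # the shrinkage is non-decreasing by construction; cummax removes
  # ulp-scale wiggle from the solver's dense-output interpolation
  s_t <- cummax(sol[, 2])
  Lmat <- pmax(outer(-s_t, L0, `+`), 0) # L_i(t) = max(L0_i - s, 0)
  m_a <- sol[, 3]
  m_b <- sol[, 4]
  m_w <- sol[, 5]
  m_cry <- rho_g * p$k_v * m_susp * as.numeric(Lmat^3 %*% w)
  m_sol <- m_a + m_b + m_w
  n_w <- m_w / M_w
  n_a <- m_a / M_l
  n_b <- m_b / M_l
  x_w <- n_w / (n_w + n_a + n_b)
  x_a <- n_a / (n_w + n_a + n_b)
  res <- tibble(
    t = sol[, 1],
    c_alpha = m_a / m_sol,
    c_beta = m_b / m_sol,
    c_tot = (m_a + m_b) / m_sol,
    c_alpha_gw = m_a / m_w,
    c_tot_gw = (m_a + m_b) / m_w,
    x_w = x_w,
    a_w = .aw(x_w, A),
    gamma_alpha = exp(.ln_gamma_alpha(x_w, A, ks, sl)),
    x_alpha = x_a,
    x_alpha_sat = .x_alpha_sat(x_w, p$K_sp, A, ks, sl),
    m_cry = m_cry,
    shrinkage = s_t
  )

  m_cry0 <- p$loading * p$water_mass
  lactose_tot <- m_a + m_b + chi * m_cry
  water_tot <- m_w + (1 - chi) * m_cry
  denom_l <- max(chi * m_cry0, p$atol_mass)
  conservation <- c(
    lactose = max(abs(lactose_tot - chi * m_cry0)) / denom_l,
    water = max(abs(water_tot - (p$water_mass + (1 - chi) * m_cry0))) /
      (p$water_mass + (1 - chi) * m_cry0),
    total = max(abs(m_sol + m_cry - m_susp)) / m_susp
  )

  # the root event (largest characteristic consumed) is the exact time of
  # complete dissolution
  dissolution_time <- if (m_cry0 > 0) event_time else NA_real_

  structure(
    res,
    class = c("sim_result", class(res)),
    params = p,
    seed_population = tibble(size = L0, weight = w),
    suspension_mass = m_susp,
    regime = classify_regime(p$loading, as_solubility_model(p)),
    dissolution_time = dissolution_time,
    conservation = conservation
  )
}

#' Crystal population of a simulation at a given time
#'
#' Reconstructs the characteristic sizes at time `t` from the cumulative
#' shrinkage coordinate (characteristics consumed by then sit at zero size
#' with unchanged weight).
#'
#' @param result A `sim_result`.
#' @param t Time in hours (interpolated linearly in the shrinkage).
#' @return A `crystal_population` tibble (`size` m, `weight` per g
#'   suspension).
#' @export
population_at <- function(result, t) {
  stopifnot(inherits(result, "sim_result"))
  s <- approx(result$t, result$shrinkage, xout = t, ties = "ordered")$y
  pop <- attr(result, "seed_population")
  out <- tibble(size = pmax(pop$size - s, 0), weight = pop$weight)
  class(out) <- c("crystal_population", class(out))
  out
}

#' Quasi-equilibrium reference solution (fast-dissolution limit)
#'
#' Zero-dimensional reference model for suspensions that hold solids: while
#' crystals remain, the liquid is assumed to be exactly at solid--liquid
#' equilibrium (\eqn{x_\alpha = x_{\alpha,sat}(x_w)}, enforced algebraically
#' at every step) and only the beta-lactose mass evolves, by mutarotation;
#' the crystal mass is back-computed from the conservation laws. This skips
#' the seconds-scale dissolution transient and serves as an independent
#' reference for [simulate_dissolution()] when dissolution is much faster
#' than mutarotation (large `k_D`). Integration stops if the solid phase is
#' exhausted (Type II loadings).
#'
#' @inheritParams simulate_dissolution
#' @return A tibble with columns `t`, `c_alpha`, `c_beta`, `c_tot`, `x_w`,
#'   `m_cry`; attribute `depletion_time` (h) if the solids ran out before the
#'   horizon.
#' @export
quasi_equilibrium <- function(params, times = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  chi <- chi_stoichiometry(p$registry)
  M_w <- molar_mass(p$registry, "water")
  M_l <- molar_mass(p$registry, "alpha-lactose")
  sle <- as_solubility_model(p)
  if (classify_regime(p$loading, sle) == "Type I") {
    abort_domain(
      "Quasi-equilibrium reference needs a loading that sustains solids (Type II/III)."
    )
  }
  times <- times %||% default_sim_times(p$horizon)
  m_cry0 <- p$loading * p$water_mass
  W0 <- p$water_mass
  A <- p$margules$A
  ks <- p$mutarotation$K_star
  sl <- p$mutarotation$slope
  k_a <- p$mutarotation$k_alpha

  # solve m_cry such that the dissolved alpha sits exactly at saturation
  state_at <- function(m_beta, m_cry) {
    m_w <- W0 + (1 - chi) * (m_cry0 - m_cry)
    m_a <- chi * (m_cry0 - m_cry) - m_beta
    n_w <- m_w / M_w
    n_a <- m_a / M_l
    n_b <- m_beta / M_l
    n_tot <- n_w + n_a + n_b
    list(
      m_w = m_w, m_a = m_a,
      x_w = n_w / n_tot, x_a = n_a / n_tot
    )
  }
  residual <- function(m_cry, m_beta) {
    s <- state_at(m_beta, m_cry)
    s$x_a - .x_alpha_sat(s$x_w, p$K_sp, A, ks, sl)
  }
  solve_m_cry <- function(m_beta) {
    f0 <- residual(0, m_beta)
    if (f0 <= 0) {
      return(NA_real_)
    } # solids exhausted
    uniroot(residual, c(0, m_cry0), m_beta = m_beta, tol = 1e-13)$root
  }

  rhs <- function(t, y, parms) {
    m_cry <- solve_m_cry(y[1])
    if (is.na(m_cry)) {
      return(list(0))
    }
    s <- state_at(y[1], m_cry)
    m_sol <- s$m_w + s$m_a + y[1]
    kx <- .kx(s$x_w, ks, sl)
    r <- k_a * (s$m_a / m_sol) - (k_a / kx) * (y[1] / m_sol)
    list(r * m_sol)
  }
  rootfun <- function(t, y, parms) residual(0, y[1])
  sol <- deSolve::lsodar(
    y = c(m_beta = 0), times = times, func = rhs, parms = NULL,
    rootfunc = rootfun, rtol = 1e-10, atol = 1e-10
  )
  tt <- sol[, 1]
  m_beta <- sol[, 2]
  rows <- purrr::map2_dfr(tt, m_beta, function(t, mb) {
    mc <- solve_m_cry(mb)
    if (is.na(mc)) {
      return(tibble())
    }
    s <- state_at(mb, mc)
    m_sol <- s$m_w + s$m_a + mb
    tibble(
      t = t, c_alpha = s$m_a / m_sol, c_beta = mb / m_sol,
      c_tot = (s$m_a + mb) / m_sol, x_w = s$x_w, m_cry = mc
    )
  })
  depletion <- if (nrow(rows) < length(tt)) max(tt[seq_len(nrow(rows))]) else NA_real_
  structure(rows, depletion_time = depletion)
}
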