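#' Discretize a Gaussian seed crystal-size distribution into characteristics
#'
#' Stratified (equal-probability) quantile discretization of a Gaussian
#' number-weighted size distribution: characteristic `i` sits at the Gaussian
#' quantile of probability `(i - 1/2)/n` and carries weight `1/n`. This keeps
#' the simulator deterministic and is exact for a size-independent dissolution
#' rate, where every characteristic simply translates. Non-positive quantiles
#' are dropped (with their weight renormalized); a warning is raised if the
#' truncated probability mass reaches 1%.
#'
#' @param mean_size,sd_size Mean and standard deviation of the seed
#'   distribution, in metres (defaults 10 um and 1 um).
#' @param n_characteristics Number of characteristics (>= 1; use >= 10 for
#'   moment accuracy, 200 reproduces the analytic third moment to ~1e-4).
#' @return A tibble of class `crystal_population` with columns `size` (m) and
#'   `weight` (dimensionless, summing to one: a unit-normalized number
#'   distribution).
#' @export
#' @examples
#' pop <- seed_psd(10e-6, 1e-6, 200)
#' sum(pop$weight * pop$size^3) # ~ mu^3 + 3 mu sigma^2
seed_psd <- function(mean_size = 10e-6, sd_size = 1e-6,
                     n_characteristics = 200) {
  check_number(mean_size, "mean_size", lower = 0, allow_zero = FALSE)
  check_number(sd_size, "sd_size", lower = 0)
  if (n_characteristics < 1) abort_domain("Need at least one characteristic.")
  if (sd_size == 0 || n_characteristics == 1) {
    out <- tibble(size = mean_size, weight = 1)
  } else {
    p <- (seq_len(n_characteristics) - 0.5) / n_characteristics
    L <- qnorm(p, mean = mean_size, sd = sd_size)
    keep <- L > 0
    if (mean(!keep) >= 0.01) {
      warn("Seed PSD truncation removed >= 1% of the probability mass.")
    }
    out <- tibble(size = L[keep], weight = rep(1 / n_characteristics, sum(keep)))
    out$weight <- out$weight / sum(out$weight)
  }
  class(out) <- c("crystal_population", class(out))
  out
}

#' Total crystal mass of a population
#'
#' The suspended crystal mass is proportional to the third moment of the
#' number-weighted size distribution:
#' \eqn{m_{cry} = \rho_c k_v \sum_i w_i L_i^3 \, m_{susp}}, with `weight`
#' interpreted as crystals per gram of suspension when `suspension_mass` is
#' given in grams (the default `suspension_mass = 1` with unit-normalized
#' weights returns the mean single-crystal mass).
#'
#' @param population A [seed_psd()]-style tibble (`size` m, `weight`).
#' @param rho_c Crystal density, kg/m^3.
#' @param k_v Volumetric shape factor (pi/6 for spheres sized by diameter).
#' @param suspension_mass Suspension mass in grams.
#' @return Crystal mass in grams.
#' @export
crystal_mass <- function(population, rho_c = 1545, k_v = pi / 6,
                         suspension_mass = 1) {
  if (nrow(population) == 0) {
    return(0)
  }
  rho_g <- rho_c * 1e3 # kg/m^3 -> g/m^3
  rho_g * k_v * sum(population$weight * pmax(population$size, 0)^3) *
    suspension_mass
}

#' Scale a unit-normalized population to a powder loading
#'
#' Rescales the weights of a unit-normalized population so that its third
#' moment accounts for `loading` grams of crystals per gram of water, with
#' weights expressed per gram of suspension (water + crystals).
#'
#' @inheritParams crystal_mass
#' @param loading Grams of powder per gram of water.
#' @param water_mass Grams of solvent water.
#' @return The population with `weight` now in crystals per gram suspension,
#'   plus attributes `suspension_mass` and `crystal_mass` (g).
#' @export
scale_psd_to_loading <- function(population, loading, water_mass,
                                 rho_c = 1545, k_v = pi / 6) {
  m_cry <- loading * water_mass
  m_susp <- water_mass + m_cry
  per_crystal <- crystal_mass(population, rho_c, k_v, suspension_mass = 1)
  n_total <- m_cry / per_crystal # number of crystals
  population$weight <- population$weight * n_total / m_susp
  attr(population, "suspension_mass") <- m_susp
  attr(population, "crystal_mass") <- m_cry
  population
}
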