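#' Default run configuration
#'
#' The configuration is a nested key-value structure (YAML on disk) covering
#' the thermodynamic parameters, the solubility product, the crystal and seed
#' PSD description, the run definition and solver tolerances. Defaults are the
#' 25 degC alpha-lactose monohydrate parameter set.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(
    list(
      thermodynamics = list(A = -5.8, K_star = 1.60, slope = 0, k_alpha = 0.64),
      solubility = list(K_sp = 0.00494),
      crystal = list(rho_c = 1545, k_v = pi / 6),
      psd = list(mean_um = 10, sd_um = 1, n_characteristics = 200),
      run = list(
        loading = 0.30, water_mass = 50, horizon = 15, k_D = 1e-3, seed = 1
      ),
      solver = list(rtol = 1e-12, atol_size = 1e-16, atol_mass = 1e-12),
      species = list(),
      fixtures = list(
        slope_true = 1.5, noise_sd_aw = 5e-4, noise_sd_kx = 0.01,
        n_points = 20, x_w_min = 0.96, x_w_max = 0.999
      )
    ),
    class = "run_config"
  )
}

config_bounds <- list(
  "thermodynamics.K_star" = c(1e-6, Inf),
  "thermodynamics.slope" = c(0, Inf),
  "thermodynamics.k_alpha" = c(0, Inf),
  "solubility.K_sp" = c(1e-12, Inf),
  "crystal.rho_c" = c(1e-6, Inf),
  "crystal.k_v" = c(1e-6, Inf),
  "psd.mean_um" = c(1e-6, Inf),
  "psd.sd_um" = c(0, Inf),
  "psd.n_characteristics" = c(1, 1e5),
  "run.loading" = c(0, Inf),
  "run.water_mass" = c(1e-12, Inf),
  "run.horizon" = c(1e-12, Inf),
  "run.k_D" = c(1e-12, Inf),
  "solver.rtol" = c(1e-14, 1e-2)
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, merges it over [default_config()], rejects
#' unknown keys, and checks every numeric parameter against its physical
#' bounds, naming the offending key in the diagnostic. An empty (or `NULL`)
#' file yields the defaults.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_domain(sprintf("Config file '%s' does not exist.", path))
    }
    user <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) {
        abort_domain(sprintf("Could not parse '%s': %s", path, conditionMessage(e)))
      }
    )
    if (!is.null(user)) {
      if (!is.list(user)) abort_domain("Config must be a key-value mapping.")
      bad_sections <- setdiff(names(user), names(cfg))
      if (length(bad_sections)) {
        abort_domain(sprintf("Unknown config section(s): %s.", toString(bad_sections)))
      }
      for (sec in names(user)) {
        if (sec == "species") {
          cfg$species <- user$species
          next
        }
        bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
        if (length(bad)) {
          abort_domain(sprintf(
            "Unknown key(s) in section '%s': %s.", sec, toString(bad)
          ))
        }
        cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
      }
    }
  }
  for (key in names(config_bounds)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    b <- config_bounds[[key]]
    if (!is.numeric(val) || !is.finite(val) || val < b[1] || val > b[2]) {
      abort_domain(sprintf(
        "Config key '%s' = %s violates its bounds [%g, %g].",
        key, format(val), b[1], b[2]
      ))
    }
  }
  class(cfg) <- "run_config"
  cfg
}

config_registry <- function(cfg) {
  if (length(cfg$species)) {
    species_registry(dplyr::bind_rows(lapply(cfg$species, as_tibble)))
  } else {
    species_registry()
  }
}

#' Build model objects from a configuration
#'
#' @param cfg A `run_config` from [load_config()].
#' @return `config_models()`: list with `margules`, `mutarotation`,
#'   `solubility` and `registry`; `config_sim_params()`: a [sim_params()].
#' @export
config_models <- function(cfg) {
  th <- cfg$thermodynamics
  reg <- config_registry(cfg)
  m <- margules_model(th$A)
  mut <- mutarotation_model(th$K_star, th$slope, th$k_alpha)
  list(
    margules = m, mutarotation = mut,
    solubility = solubility_model(cfg$solubility$K_sp, m, mut, reg),
    registry = reg
  )
}

#' @rdname config_models
#' @export
config_sim_params <- function(cfg) {
  mod <- config_models(cfg)
  sim_params(
    loading = cfg$run$loading, water_mass = cfg$run$water_mass,
    horizon = cfg$run$horizon, rho_c = cfg$crystal$rho_c,
    k_v = cfg$crystal$k_v, k_D = cfg$run$k_D, K_sp = cfg$solubility$K_sp,
    margules = mod$margules, mutarotation = mod$mutarotation,
    psd_mean = cfg$psd$mean_um * 1e-6, psd_sd = cfg$psd$sd_um * 1e-6,
    n_characteristics = cfg$psd$n_characteristics,
    registry = mod$registry,
    rtol = cfg$solver$rtol, atol_size = cfg$solver$atol_size,
    atol_mass = cfg$solver$atol_mass
  )
}

#' Write a simulation time series (plus summary) to disk
#'
#' The time series goes to comma-separated UTF-8 text with a header row and
#' full double precision (times in hours); a paired YAML summary record
#' (`<path>.summary.yml`) carries the regime label, the complete-dissolution
#' time if any, the final state, the conservation diagnostics, the package
#' version and a hash of the generating configuration when one is supplied.
#'
#' @param result A `sim_result` from [simulate_dissolution()].
#' @param path Output CSV path.
#' @param config Optional `run_config` used to produce the run (hashed into
#'   the summary for provenance).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path, config = NULL) {
  out <- tidy(result)
  # %.17g guarantees a bit-exact write -> read round trip for doubles
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)
  ))
  readr::write_csv(out, path)
  g <- glance(result)
  summary <- c(
    lapply(as.list(g), function(v) if (is.numeric(v)) unname(v) else v),
    list(
      package_version = as.character(utils::packageVersion("isolact")),
      config_hash = if (is.null(config)) NA else rlang::hash(config)
    )
  )
  yaml::write_yaml(summary, paste0(path, ".summary.yml"))
  invisible(path)
}
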