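test_that("solubility product from the equilibrium point matches Table values", {
  expect_equal(
    ksp_from_equilibrium_point(0.9886, lactose_margules(), lactose_mut()),
    0.00494,
    tolerance = 1e-5 / 0.00494
  )
  expect_equal(
    ksp_from_equilibrium_point(1, lactose_margules(), lactose_mut()), 0
  )
  # slope invariance: the (1 + K_x) factors cancel algebraically
  for (sl in c(0, 1, 3)) {
    expect_equal(
      ksp_from_equilibrium_point(0.9886, lactose_margules(), lactose_mut(sl)),
      ksp_from_equilibrium_point(0.9886, lactose_margules(), lactose_mut(0)),
      tolerance = 1e-12
    )
  }
})

test_that("saturation mole fraction of alpha follows the solubility product", {
  expect_equal(
    x_alpha_sat(0.9886, lactose_sle(0)), 0.0043846,
    tolerance = 1e-6 / 0.0043846
  )
  expect_equal(
    x_alpha_sat(0.9886, lactose_sle(3)), 0.0044431,
    tolerance = 1e-6 / 0.0044431
  )
  doubled <- solubility_model(2 * 0.00494, lactose_margules(), lactose_mut())
  expect_equal(
    x_alpha_sat(0.9886, doubled), 2 * x_alpha_sat(0.9886, lactose_sle()),
    tolerance = 1e-14
  )
})

test_that("equilibrium solubility root-solve reproduces the saturation point", {
  eq <- equilibrium_solubility(lactose_sle())
  expect_equal(eq$x_w_eq, 0.9886, tolerance = 2e-4 / 0.9886)
  expect_equal(round(eq$x_w_eq, 4), 0.9886)
  # slope invariance of the root
  for (sl in c(1, 3)) {
    expect_equal(
      equilibrium_solubility(lactose_sle(sl))$x_w_eq, eq$x_w_eq,
      tolerance = 1e-10
    )
  }
  # vanishing solubility product pushes the solution to pure water
  tiny <- solubility_model(1e-7, lactose_margules(), lactose_mut())
  expect_gt(equilibrium_solubility(tiny)$x_w_eq, 0.99995)
  # internal consistency of the reported derived columns
  expect_equal(eq$x_beta_eq / eq$x_alpha_eq, eq$K_x_eq)
  expect_equal(
    eq$c_tot_sat_eq,
    (1 - eq$x_w_eq) * 342.30 / (eq$x_w_eq * 18.015),
    tolerance = 1e-12
  )
})

test_that("F parameter matches its brute-force finite-difference construction", {
  expect_equal(f_parameter(lactose_sle()), 0.0434, tolerance = 0.01)
  # brute force: perturb the dissolved beta around equilibrium by +/- delta and
  # re-solve the saturation condition for alpha at the perturbed composition
  model <- lactose_sle()
  eq <- equilibrium_solubility(model)
  delta <- 1e-5
  solve_xa <- function(x_beta) {
    f <- function(x_a) {
      x_w <- 1 - x_a - x_beta
      x_a - x_alpha_sat(x_w, model)
    }
    uniroot(f, c(1e-5, 0.02), tol = 1e-15)$root
  }
  xb <- eq$x_beta_eq
  F_fd <- -(solve_xa(xb + delta) - solve_xa(xb - delta)) / (2 * delta)
  expect_equal(f_parameter(model), F_fd, tolerance = 1e-4)
  # ideal solution: F nearly vanishes
  ideal <- solubility_model(0.0019, margules_model(0), lactose_mut())
  expect_lt(abs(f_parameter(ideal)), 0.005)
  # stronger negative deviations from ideality enlarge F
  strong <- solubility_model(0.00494, margules_model(-11.6), lactose_mut())
  expect_gt(f_parameter(strong), f_parameter(model))
  # slope-inclusive mode moves F but stays the same order
  expect_gt(f_parameter(lactose_sle(3), include_slope = TRUE), 0)
})

test_that("F basis conversion follows the dilute-tracer molar-mass Jacobians", {
  eq <- equilibrium_solubility(lactose_sle())
  comp <- composition_from_loading(eq$c_tot_sat_eq, eq$K_x_eq)
  F0 <- f_parameter(lactose_sle())
  expect_identical(
    convert_f_basis(F0, "mole_fraction", "mole_fraction", comp), F0
  )
  # equal molar masses of the anomers: conversion is exactly neutral
  expect_equal(
    convert_f_basis(F0, "mole_fraction", "mass_fraction_solution", comp), F0
  )
  # foreign depressant: ratio given by the molar masses, checked against a
  # finite-difference Jacobian of the basis-conversion maps
  compg <- composition_from_loading(
    eq$c_tot_sat_eq, eq$K_x_eq,
    foreign_loadings = c(glucose = 0.05)
  )
  Fg <- convert_f_basis(F0, "mole_fraction", "g_per_g_water", compg,
    depressant = "glucose"
  )
  expect_equal(Fg / F0, 342.30 / 180.16, tolerance = 1e-12)
  # finite-difference oracle: perturb each species concentration expressed on
  # both bases via convert_concentration and take the slope ratio
  fd_jac <- function(species) {
    eps <- 1e-7
    (convert_concentration(eps, "mole_fraction", "g_per_g_water", compg,
      species = species
    ) -
      convert_concentration(0, "mole_fraction", "g_per_g_water", compg,
        species = species
      )) / eps
  }
  expect_equal(Fg / F0, fd_jac("alpha-lactose") / fd_jac("glucose"),
    tolerance = 1e-8
  )
})

test_that("foreign sugars depress lactose solubility monotonically", {
  model <- lactose_sle()
  eq <- equilibrium_solubility(model)
  # zero loading reduces exactly to the binary solubility
  expect_equal(
    foreign_sugar_solubility(model, 0, "sucrose"), eq$c_tot_sat_eq,
    tolerance = 1e-10
  )
  loads <- seq(0, 0.3, by = 0.025)
  for (sp in c("sucrose", "glucose")) {
    s <- foreign_sugar_solubility(model, loads, sp)
    expect_true(all(diff(s) < 0))
  }
  # brute-force grid search cross-check at one sucrose loading
  sol <- foreign_sugar_solubility(model, 0.10, "sucrose")
  phi <- 0.10 * 18.015 / 342.30
  grid_xa <- seq(0.002, 0.006, length.out = 40001)
  resid <- vapply(grid_xa, function(xa) {
    x_w <- (1 - (1 + equilibrium_ratio(0.98, model$mutarotation)) * xa) / (1 + phi)
    # iterate the implicit K_x(x_w) dependence once (slope 0: exact)
    x_w2 <- (1 - (1 + equilibrium_ratio(x_w, model$mutarotation)) * xa) / (1 + phi)
    abs(xa - x_alpha_sat(x_w2, model))
  }, numeric(1))
  xa_best <- grid_xa[which.min(resid)]
  x_w_best <- (1 - (1 + 1.6) * xa_best) / (1 + phi)
  expect_equal(
    sol, xa_best * (1 + 1.6) * 342.30 / (x_w_best * 18.015),
    tolerance = 1e-3
  )
  expect_lt(sol, eq$c_tot_sat_eq)
  # two foreign sugars at equal mole loadings depress identically
  model2 <- model
  g_load <- 0.05
  s_load <- g_load * 342.30 / 180.16 # same moles of sucrose as glucose
  expect_equal(
    foreign_sugar_solubility(model, g_load, "glucose"),
    foreign_sugar_solubility(model, s_load, "sucrose"),
    tolerance = 1e-10
  )
  expect_error(
    foreign_sugar_solubility(model, 5, "sucrose"),
    class = "isolact_validity_error"
  )
})

test_that("regime classification brackets the loading thresholds", {
  model <- lactose_sle()
  expect_equal(classify_regime(0, model), "Type I")
  th <- regime_thresholds(model)
  expect_equal(
    classify_regime(
      c(th$type_I_II * 0.9, th$type_I_II * 1.05, th$type_II_III * 1.05),
      model
    ),
    c("Type I", "Type II", "Type III")
  )
  expect_equal(classify_regime(0.30, model), "Type III")
  # consistency with the simulator's asymptotics: the boundary is where the
  # fully-dissolved concentration (hydrate water included) hits saturation
  chi <- chi_stoichiometry()
  eq <- equilibrium_solubility(model)
  L <- th$type_II_III
  expect_equal(chi * L / (1 + (1 - chi) * L), eq$c_tot_sat_eq, tolerance = 1e-10)
})
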