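test_that("Margules water activity matches direct evaluation", {
  m <- lactose_margules()
  expect_equal(ln_gamma_water(1, m), 0)
  expect_equal(ln_gamma_water(0.9886, m), -5.8 * 0.0114^2, tolerance = 1e-12)
  expect_equal(ln_gamma_water(0.9886, m), -7.538e-4, tolerance = 1e-3)
  expect_equal(ln_gamma_water(c(0.95, 0.99), margules_model(0)), c(0, 0))
  expect_equal(water_activity(1, m), 1)
  expect_equal(water_activity(0.9886, m), 0.98786, tolerance = 1e-5)
  expect_equal(water_activity(0.95, margules_model(0)), 0.95)
  expect_error(ln_gamma_water(0, m), class = "isolact_domain_error")
  expect_error(ln_gamma_water(1.01, m), class = "isolact_domain_error")
})

test_that("isomer-group activity coefficient is the Gibbs-Duhem integral of Margules", {
  m <- lactose_margules()
  expect_equal(gamma_star_group(1, m), 1)
  expect_equal(gamma_star_group(0.9886, m), exp(-5.8 * (0.9886^2 - 1)))
  expect_equal(gamma_star_group(0.9886, m), 1.1405, tolerance = 1e-4)
  expect_equal(gamma_star_group(0.9886, margules_model(0)), 1)
})

test_that("equilibrium ratio model is linear in x_w with K_x(1) = K*", {
  expect_equal(equilibrium_ratio(1, lactose_mut(5)), 1.60)
  expect_equal(equilibrium_ratio(0.9886, lactose_mut(0)), 1.60)
  expect_equal(equilibrium_ratio(0.9886, lactose_mut(3)), 1.60 - 3 * 0.0114)
  expect_error(equilibrium_ratio(0.85, lactose_mut()), class = "isolact_validity_error")
  # slope that would drive K_x negative inside the window is rejected upfront
  expect_error(mutarotation_model(0.1, slope = 2), class = "isolact_validity_error")
})

test_that("per-isomer coefficients: closed forms and infinite-dilution limit", {
  g <- gamma_star_isomers(1, lactose_margules(), lactose_mut(3))
  expect_equal(g$gamma_alpha, 1)
  expect_equal(g$gamma_beta, 1)
  g0 <- gamma_star_isomers(0.9886, lactose_margules(), lactose_mut(0))
  # constant K_x makes both equal the group coefficient
  expect_equal(g0$gamma_alpha, g0$gamma_beta)
  expect_equal(g0$gamma_alpha, gamma_star_group(0.9886, lactose_margules()))
  g3 <- gamma_star_isomers(0.9886, lactose_margules(), lactose_mut(3))
  expect_equal(g3$gamma_alpha, 1.1255, tolerance = 1e-3)
  expect_equal(g3$gamma_beta, 1.1501, tolerance = 1e-3)
})

test_that("consistency identities vanish on randomized parameter tuples", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      A <- runif(1, -12, 2)
      ks <- runif(1, 0.5, 3)
      sl <- runif(1, 0, min(3, (ks - 0.05) / 0.1))
      xw <- runif(1, 0.9, 1)
      m <- margules_model(A)
      mut <- mutarotation_model(ks, sl)
      expect_lt(abs(gamma_ratio_residual(xw, m, mut)), 1e-12)
      expect_lt(abs(gamma_average_residual(xw, m, mut)), 1e-12)
    }
  })
})

test_that("numerical Gibbs-Duhem integration agrees with the closed forms", {
  m <- lactose_margules()
  for (sl in c(0, 3)) {
    mut <- lactose_mut(sl)
    for (xw in c(1, 0.9886, 0.95, 0.91)) {
      num <- gamma_star_isomers_numeric(xw, m, mut, steps = 1e4)
      cf <- gamma_star_isomers(xw, m, mut)
      expect_equal(num$gamma_alpha, cf$gamma_alpha, tolerance = 1e-6)
      expect_equal(num$gamma_beta, cf$gamma_beta, tolerance = 1e-6)
    }
  }
  expect_error(
    gamma_star_isomers_numeric(0.95, m, lactose_mut(), steps = 50),
    class = "isolact_domain_error"
  )
})

test_that("Gibbs-Duhem residual vanishes along a composition grid", {
  # x_w dln(a_w) + x_iso dln(a_iso) = 0 up to O(dx^2) discretization error
  m <- lactose_margules()
  xw <- seq(0.92, 0.999, length.out = 400)
  ln_aw <- log(water_activity(xw, m))
  ln_aiso <- log(gamma_star_group(xw, m) * (1 - xw))
  mid_xw <- (xw[-1] + xw[-length(xw)]) / 2
  resid <- mid_xw * diff(ln_aw) + (1 - mid_xw) * diff(ln_aiso)
  dx <- diff(xw)[1]
  expect_lt(max(abs(resid)), 50 * dx^2)
  # residual shrinks quadratically with the grid spacing
  xw2 <- seq(0.92, 0.999, length.out = 799)
  ln_aw2 <- log(water_activity(xw2, m))
  ln_aiso2 <- log(gamma_star_group(xw2, m) * (1 - xw2))
  mid2 <- (xw2[-1] + xw2[-length(xw2)]) / 2
  resid2 <- mid2 * diff(ln_aw2) + (1 - mid2) * diff(ln_aiso2)
  expect_lt(max(abs(resid2)), max(abs(resid)) / 3)
})

test_that("per-isomer coefficients increase as the solution concentrates (A < 0)", {
  xw <- seq(0.999, 0.92, length.out = 50)
  g <- gamma_star_isomers(xw, lactose_margules(), lactose_mut(0.5))
  expect_true(all(diff(g$gamma_alpha) > 0))
  expect_true(all(diff(g$gamma_beta) > 0))
})
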