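# shorter runs than the acceptance suite: 60 characteristics keep the moment
# error ~1e-3, ample for these property checks
quick_params <- function(loading, horizon = 8, ...) {
  sim_params(
    loading = loading, horizon = horizon, n_characteristics = 60, ...
  )
}

test_that("rate laws match their closed forms", {
  expect_equal(mutarotation_rate(0.1, 0.16, K_x = 1.6, k_alpha = 0.64), 0)
  expect_equal(mutarotation_rate(0.1, 0, 1.6, 0.64), 0.064)
  expect_error(mutarotation_rate(0.1, 0.1, 0), class = "isolact_domain_error")
  expect_equal(dissolution_rate(0.00438, 0.00338, 1e-3), 1e-6)
  expect_equal(
    dissolution_rate(0.004, 0.003, 2e-3),
    2 * dissolution_rate(0.004, 0.003, 1e-3)
  )
  # solids-free relaxation rate: k_alpha (1 + 1/K_x) = 1.04 1/h at defaults
  r <- mutarotation_relaxation(c(0, 1), c_alpha0 = 0.05, c_beta0 = 0, K_x = 1.6)
  dev0 <- r$c_beta[1] - 0.05 * 1.6 / 2.6
  dev1 <- r$c_beta[2] - 0.05 * 1.6 / 2.6
  expect_equal(log(dev0 / dev1), 0.64 * (1 + 1 / 1.6), tolerance = 1e-12)
})

test_that("a zero loading yields an all-zero lactose trajectory", {
  res <- simulate_dissolution(quick_params(0, horizon = 1))
  expect_true(all(res$c_alpha == 0))
  expect_true(all(res$c_beta == 0))
  expect_true(all(res$m_cry == 0))
  expect_equal(attr(res, "regime"), "Type I")
})

test_that("mass conservation holds through dissolution, depletion and relaxation", {
  for (loading in c(0.30, 0.16)) {
    res <- simulate_dissolution(quick_params(loading))
    expect_lt(max(attr(res, "conservation")), 1e-8)
    # monotone PSD shrinkage
    expect_true(all(diff(res$shrinkage) >= 0))
  }
})

test_that("a Type III run converges to the equilibria-module saturation state", {
  res <- simulate_dissolution(sim_params(loading = 0.30, horizon = 20))
  expect_equal(attr(res, "regime"), "Type III")
  expect_true(is.na(attr(res, "dissolution_time")))
  last <- res[nrow(res), ]
  kx <- equilibrium_ratio(last$x_w)
  expect_equal(last$c_beta / last$c_alpha, kx, tolerance = 1e-3)
  eq <- equilibrium_solubility(lactose_sle())
  c_alpha_eq <- eq$c_alpha_sat_eq / (1 + eq$c_tot_sat_eq)
  expect_equal(last$c_alpha, c_alpha_eq, tolerance = 1e-3)
  expect_gt(last$m_cry, 0)
})

test_that("a Type II run fires the dissolution event then follows the analytic kinetics", {
  res <- simulate_dissolution(sim_params(loading = 0.16, horizon = 12))
  expect_equal(attr(res, "regime"), "Type II")
  td <- attr(res, "dissolution_time")
  expect_false(is.na(td))
  expect_true(all(res$m_cry[res$t > td] == 0))
  seg <- res[res$t > td, ]
  an <- mutarotation_relaxation(
    seg$t - seg$t[1], seg$c_alpha[1], seg$c_beta[1],
    K_x = equilibrium_ratio(seg$x_w[1]), k_alpha = 0.64
  )
  expect_lt(max(abs(seg$c_beta - an$c_beta)), 1e-6)
  expect_lt(max(abs(seg$c_alpha - an$c_alpha)), 1e-6)
  # loading-derived final total concentration (everything dissolved)
  chi <- chi_stoichiometry()
  c_tot_expected <- chi * 0.16 / (1 + 0.16)
  expect_equal(res$c_tot[nrow(res)], c_tot_expected, tolerance = 1e-9)
  # mutarotation effectively complete on the 12 h scale once solids are gone
  last <- res[nrow(res), ]
  kx <- equilibrium_ratio(last$x_w)
  expect_lt(abs(last$c_beta / last$c_alpha - kx) / kx, 1e-3)
})

test_that("dissolution is orders of magnitude faster than mutarotation", {
  res <- simulate_dissolution(sim_params(loading = 0.30, horizon = 20))
  t_alpha <- res$t[which(abs(res$x_alpha / res$x_alpha_sat - 1) < 0.01)[1]]
  c_beta_final <- res$c_beta[nrow(res)]
  t_beta <- res$t[which(abs(res$c_beta / c_beta_final - 1) < 0.01)[1]]
  expect_lt(t_alpha, 0.01 * t_beta)
  expect_lt(t_alpha, 0.2)
})

test_that("the long-time state does not depend on the dissolution kinetic constant", {
  finals <- purrr::map_dfr(c(1e-4, 1e-3, 1e-2), function(kd) {
    res <- simulate_dissolution(quick_params(0.30, horizon = 20, k_D = kd))
    res[nrow(res), c("c_alpha", "c_beta", "x_w")]
  })
  expect_lt(diff(range(finals$c_alpha)), 1e-6)
  expect_lt(diff(range(finals$c_beta)), 1e-6)
  expect_lt(diff(range(finals$x_w)), 1e-6)
})

test_that("quasi-equilibrium reference agrees with the full simulator", {
  p <- quick_params(0.30, horizon = 10)
  qe <- quasi_equilibrium(p)
  sim <- simulate_dissolution(p, times = qe$t)
  i <- qe$t >= 0.2
  expect_lt(max(abs(sim$c_beta[i] / qe$c_beta[i] - 1)), 0.01)
  # at every step the dissolved alpha sits exactly at saturation
  n_a <- qe$c_alpha / 342.30
  n_b <- qe$c_beta / 342.30
  n_w <- (1 - qe$c_tot) / 18.015
  x_a_implied <- n_a / (n_a + n_b + n_w)
  expect_equal(
    x_a_implied, x_alpha_sat(qe$x_w, lactose_sle()),
    tolerance = 1e-8
  )
  expect_error(quasi_equilibrium(quick_params(0.01)), class = "isolact_domain_error")
})

test_that("population snapshots shrink but keep their weights", {
  res <- simulate_dissolution(quick_params(0.30, horizon = 2))
  p0 <- population_at(res, 0)
  p1 <- population_at(res, 2)
  expect_equal(p1$weight, p0$weight)
  expect_true(all(p1$size < p0$size))
  expect_true(all(p1$size >= 0))
})
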