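test_that("closed-form bias terms match the moment-matrix oracle", {
  set.seed(41)
  for (i in 1:50) {
    lam <- runif(1, 0, 0.6); del <- runif(1, 0, 0.6); kap <- runif(1, -0.6, 0.6)
    o <- oracle_plim(lam, del, kap)
    expect_equal(collider_bias_g(lam, del, kap), o$bias_g, tolerance = 1e-12)
    expect_equal(collider_bias_e(lam, del, kap), o$bias_e, tolerance = 1e-12)
  }
})

test_that("bias formulas reproduce the worked-example and boundary values", {
  expect_equal(round(collider_bias_g(0.300, 0.250, 0.250), 3), -0.021)
  expect_equal(collider_bias_g(0, 0.25, 0.25), 0)
  expect_equal(collider_bias_g(0.5, 0.38, 0.38), -0.09626667,
               tolerance = 1e-7)
  expect_equal(collider_bias_e(0.3, 0, 0.4), 0)
  expect_equal(collider_bias_e(0, 0.25, 0.25), 0.0625)
  expect_equal(round(collider_bias_e(0.3, 0.25, 0.25), 4), 0.0687)
  expect_error(collider_bias_g(1, 0.2, 0.2), class = "collider_domain_error")
  expect_error(collider_bias_e(1.2, 0.2, 0.2), class = "collider_domain_error")
})

test_that("population_fit agrees with the oracle and its own closed forms", {
  set.seed(42)
  for (i in 1:25) {
    p <- collider_params(lambda_ge = runif(1, 0, 0.6),
                         delta_ue = runif(1, 0, 0.6),
                         kappa_uy = runif(1, -0.6, 0.6),
                         beta_gy = runif(1, -1, 1),
                         gamma_ey = runif(1, -1, 1))
    pf <- population_fit(p)
    o <- oracle_plim(p$lambda_ge, p$delta_ue, p$kappa_uy,
                     p$beta_gy, p$gamma_ey, p$sigma_y)
    expect_equal(pf$b_g_plim, o$b_g, tolerance = 1e-12)
    expect_equal(pf$b_e_plim, o$b_e, tolerance = 1e-12)
    expect_equal(pf$r2_fitted, o$r2_fitted, tolerance = 1e-12)
    expect_equal(pf$r2_true_share, o$r2_true_share, tolerance = 1e-12)
    expect_lt(abs(pf$bias_g -
                collider_bias_g(p$lambda_ge, p$delta_ue, p$kappa_uy)), 1e-10)
    expect_lt(abs(pf$bias_e -
                collider_bias_e(p$lambda_ge, p$delta_ue, p$kappa_uy)), 1e-10)
  }
})

test_that("population_fit handles the exogenous and unsupported cases", {
  pf <- population_fit(collider_params())
  expect_equal(pf$bias_g, 0)
  expect_equal(pf$bias_e, 0)
  expect_equal(pf$r2_inflation, 0)
  expect_error(population_fit(collider_params(theta_gxe = 0.1)),
               class = "collider_unsupported_model_error")
  expect_error(population_fit(collider_params(phi_exu = 0.3)),
               class = "collider_unsupported_model_error")
  td <- tidy(population_fit(collider_params(lambda_ge = 0.3,
                                            delta_ue = 0.25,
                                            kappa_uy = 0.25)))
  expect_named(td, c("term", "plim", "truth", "bias"))
  expect_equal(td$term, c("g", "e"))
})

test_that("bias signs, monotonicity, and symmetry follow the collider structure", {
  grid <- expand.grid(lam = c(0, 0.2, 0.4, 0.6), del = c(0, 0.2, 0.4),
                      kap = c(0, 0.2, 0.4))
  for (i in seq_len(nrow(grid))) {
    pf <- population_fit(collider_params(lambda_ge = grid$lam[i],
                                         delta_ue = grid$del[i],
                                         kappa_uy = grid$kap[i]))
    expect_lte(pf$bias_g, 0)
    expect_gte(pf$bias_e, 0)
    expect_gte(pf$r2_inflation, -1e-12)
  }
  # |bias_g| nondecreasing in each argument
  lams <- seq(0, 0.89, by = 0.01)
  expect_true(all(diff(abs(collider_bias_g(lams, 0.3, 0.3))) >= 0))
  dels <- seq(0, 0.89, by = 0.01)
  expect_true(all(diff(abs(collider_bias_g(0.3, dels, 0.3))) >= 0))
  expect_true(all(diff(abs(collider_bias_g(0.3, 0.3, dels))) >= 0))
  # flipping the confounder's outcome effect flips both biases
  expect_equal(collider_bias_g(0.3, 0.25, -0.25),
               -collider_bias_g(0.3, 0.25, 0.25))
  expect_equal(collider_bias_e(0.3, 0.25, -0.25),
               -collider_bias_e(0.3, 0.25, 0.25))
})

test_that("explained-variance inflation vanishes exactly when the confounded path is closed", {
  for (lam in c(0, 0.3, 0.5)) {
    # either leg of the U path zero -> no inflation
    expect_equal(population_fit(collider_params(
      lambda_ge = lam, delta_ue = 0, kappa_uy = 0.4))$r2_inflation, 0)
    expect_equal(population_fit(collider_params(
      lambda_ge = lam, delta_ue = 0.4, kappa_uy = 0))$r2_inflation, 0)
    # both legs active -> strictly positive
    expect_gt(population_fit(collider_params(
      lambda_ge = lam, delta_ue = 0.4, kappa_uy = 0.4))$r2_inflation, 0)
  }
})

test_that("sensitivity attributes attenuation per the published arithmetic", {
  s <- sensitivity(0.185, 0.055, 0.300, 0.250, 0.250)
  expect_equal(round(s$fraction_collider, 2), 0.16)
  expect_equal(s$attenuation, 0.130)
  expect_equal(round(abs(s$bias_g), 3), 0.021)

  expect_equal(sensitivity(0.185, 0.055, 0, 0.250, 0.250)$fraction_collider, 0)
  expect_equal(sensitivity(1.0, 0.5, 0.3, 0.25, 0.25)$fraction_collider,
               0.0412, tolerance = 1e-3)

  expect_error(sensitivity(0.2, 0.2, 0.3, 0.25, 0.25),
               class = "collider_degenerate_attenuation_error")
  expect_warning(sensitivity(0.2, 0.19, 0.5, 0.5, 0.5),
                 class = "collider_bias_exceeds_attenuation")
})

test_that("percent reduction mirrors the published 70% example", {
  expect_equal(round(percent_reduction(0.185, 0.055)), 70)
  expect_equal(percent_reduction(0.185, 0.055), 70.27027, tolerance = 1e-6)
  expect_equal(percent_reduction(0.4, 0.4), 0)
  expect_equal(percent_reduction(0.185, 0), 100)
  expect_error(percent_reduction(0, 0.1), class = "collider_domain_error")
})
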