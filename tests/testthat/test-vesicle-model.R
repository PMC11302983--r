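test_that("binomial release moments follow mu = npq, var = np(1-p)q^2", {
  m <- psp_moments(list(n = 1, p = 1, q = 2))
  expect_equal(m$mu, 2)
  expect_equal(m$var, 0)
  m <- psp_moments(list(n = 10, p = 0.5, q = 0.2))
  expect_equal(m$mu, 1)
  expect_equal(m$var, 0.1)
  m <- psp_moments(list(n = 4, p = 0.25, q = 1))
  expect_equal(m$mu, 1)
  expect_equal(m$var, 0.75)
  expect_error(psp_moments(list(n = -1, p = 0.5, q = 1)), "non-negative")
  expect_error(psp_moments(list(n = 1, p = 1.5, q = 1)), "p must")
})

test_that("Hill equation maps calcium to release probability", {
  expect_equal(hill_release_probability(2, 2, 3), 0.5)
  expect_equal(hill_release_probability(0, 1, 4), 0)
  expect_equal(hill_release_probability(2, 1, 4), 16 / 17)
  ca <- seq(0, 5, by = 0.25)
  expect_true(all(diff(hill_release_probability(ca, 1.3, 4)) > 0))
  expect_error(hill_release_probability(-1, 1, 4), "non-negative")
})

test_that("cost curves hold the PSP mean fixed and behave monotonically", {
  for (mech in c("calcium", "surface", "actin", "trafficking")) {
    cc <- cost_curve(mech, mu_fix = 1.7)
    expect_true(all(cc$cost > 0))
    expect_true(all(cc$sigma > 0))
    d <- diff(cc$sigma)
    expect_true(all(d > 0) || all(d < 0))
    # cost strictly decreasing in sigma
    ord <- order(cc$sigma)
    expect_true(all(diff(cc$cost[ord]) < 0))
    # mean constraint: recompute mu from the stored sweep
    if (mech == "calcium") {
      q <- 1.7 / (vesicle_params()$n * cc$p)
      mu <- vesicle_params()$n * cc$p * q
    } else {
      p <- vesicle_params()$p
      n <- 1.7 / (p * cc$r^3)
      mu <- n * p * cc$r^3
    }
    expect_equal(mu, rep(1.7, nrow(cc)), tolerance = 1e-10)
  }
})

test_that("trafficking: doubling the radius at fixed mean cuts the cost 8-fold", {
  cc <- cost_curve("trafficking", mu_fix = 1, sweep_grid = c(1, 2))
  expect_equal(cc$cost[2] / cc$cost[1], 1 / 8)
})

test_that("calcium cost diverges and sigma vanishes as p approaches 1", {
  cc <- cost_curve("calcium", sweep_grid = c(0.9, 0.99, 0.999, 0.999999))
  expect_true(all(diff(cc$cost) > 0))
  expect_true(all(diff(cc$sigma) < 0))
  # Ca ratio = (1e6 / 9)^(1/4) ~ 18.2 for the default Hill coefficient 4
  expect_gt(cc$cost[4] / cc$cost[1], 10)
  expect_lt(cc$sigma[4] / cc$sigma[1], 0.01)
})

test_that("fitted exponents recover the four biophysical scalings", {
  expected <- c(calcium = -1 / 2, surface = -2 / 3, actin = -4 / 3,
                trafficking = -2)
  for (mech in names(expected)) {
    fit <- fit_power_exponent(cost_curve(mech))
    expect_equal(fit$slope, expected[[mech]], tolerance = 1e-6)
    expect_equal(fit$rho_hat, -expected[[mech]], tolerance = 1e-6)
  }
})

test_that("exponent fit is exact on a synthetic power law", {
  sigma <- exp(seq(-2, 2, length.out = 25))
  curve <- data.frame(sigma = sigma, cost = sigma^(-3))
  fit <- fit_power_exponent(curve)
  expect_equal(fit$slope, -3, tolerance = 1e-12)
  expect_error(fit_power_exponent(curve[1:2, ]), "3 points")
  expect_error(fit_power_exponent(data.frame(sigma = c(1, -1, 2),
                                             cost = c(1, 2, 3))), "positive")
})

test_that("curves match the closed-form elimination of the swept variable", {
  mu <- 2.5
  prm <- vesicle_params()

  # trafficking/surface/actin: sigma^2 = mu (1-p) q = mu (1-p) r^3,
  # n = mu / (p r^3)  =>  cost = n r^k = (mu/p) r^(k-3)
  r <- exp(seq(log(0.6), log(1.8), length.out = 20))
  sig <- sqrt(mu * (1 - prm$p) * r^3)
  for (mech in c("surface", "actin", "trafficking")) {
    k <- c(surface = 2, actin = 1, trafficking = 0)[[mech]]
    cc <- cost_curve(mech, mu_fix = mu, sweep_grid = r)
    expect_equal(cc$sigma, sig, tolerance = 1e-12)
    expect_equal(cc$cost, (mu / prm$p) * r^(k - 3), tolerance = 1e-12)
  }

  # calcium: q absorbs the mean at fixed n, so p/(1-p) = mu^2/(n sigma^2)
  # exactly and cost = K (mu^2 / (n sigma^2))^(1/m)
  p <- seq(0.9, 0.999, length.out = 20)
  cc <- cost_curve("calcium", mu_fix = mu, sweep_grid = p)
  expect_equal(cc$cost,
               prm$K * (mu^2 / (prm$n * cc$sigma^2))^(1 / prm$m),
               tolerance = 1e-12)
})

test_that("cost curve rejects invalid sweeps", {
  expect_error(cost_curve("calcium", sweep_grid = c(0.5, 0.5)), "monotone")
  expect_error(cost_curve("calcium", sweep_grid = c(0.9, 1.1)), "p in")
  expect_error(cost_curve("surface", sweep_grid = c(-1, 1)), "positive")
  expect_error(cost_curve("surface", mu_fix = -1), "mu_fix")
})
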