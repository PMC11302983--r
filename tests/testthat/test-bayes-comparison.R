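test_that("Laplace posterior sd is the inverse root curvature", {
  expect_equal(laplace_posterior_sd(4), 0.5)
  expect_equal(laplace_posterior_sd(1), 1)
  expect_equal(laplace_posterior_sd(c(0.25, 100)), c(2, 0.1))
  expect_error(laplace_posterior_sd(0), "positive curvature")
  expect_error(laplace_posterior_sd(-2), "positive curvature")
})

test_that("analytic noise level is the stationary point of the 1-D objective", {
  expect_equal(analytic_sigma(1, 1, 2), 2^(1 / 4))
  # independent numeric oracles: minimiser of 0.5 H s^2 + c s^-rho, and the
  # root of its derivative
  for (H in c(0.1, 1, 10)) {
    for (cc in c(0.01, 0.1, 1)) {
      for (rho in c(1 / 2, 2 / 3, 4 / 3, 2)) {
        f <- function(s) 0.5 * H * s^2 + cc * s^(-rho)
        fp <- function(s) H * s - cc * rho * s^(-rho - 1)
        opt <- stats::optimize(f, c(1e-4, 1e3), tol = 1e-12)$minimum
        root <- stats::uniroot(fp, c(1e-6, 1e4), tol = 1e-14)$root
        ana <- analytic_sigma(H, cc, rho)
        expect_equal(ana, root, tolerance = 1e-8)
        expect_equal(ana, opt, tolerance = 1e-6)
      }
    }
  }
  # monotone in importance and in the cost multiplier
  expect_true(all(diff(analytic_sigma(c(0.1, 1, 10), 1, 2)) < 0))
  expect_true(all(diff(analytic_sigma(1, c(0.1, 1, 10), 2)) > 0))
  expect_error(analytic_sigma(-1, 1, 1), "positive")
})

test_that("efficient noise scales as posterior spread to the power 2/(rho+2)", {
  H <- 10^seq(-1, 2, length.out = 20)
  for (rho in c(1 / 2, 2 / 3, 4 / 3, 2)) {
    sa <- sigma_vs_posterior_slope(H, c = c_from_scale(rho, 0.01), rho = rho)
    expect_equal(sa$slope, 2 / (rho + 2), tolerance = 1e-10)
    expect_lt(sa$slope, 1)
  }
  expect_equal(sigma_vs_posterior_slope(H, 1, 2)$slope, 0.5, tolerance = 1e-10)
  expect_equal(sigma_vs_posterior_slope(H, 1, 1 / 2)$slope, 0.8,
               tolerance = 1e-10)
  expect_equal(sigma_vs_posterior_slope(H, 1, 2 / 3)$slope, 0.75,
               tolerance = 1e-10)
  expect_equal(sigma_vs_posterior_slope(H, 1, 4 / 3)$slope, 0.6,
               tolerance = 1e-10)
  # slope approaches one from below as rho -> 0
  expect_equal(sigma_vs_posterior_slope(H, 1, 1e-6)$slope, 1, tolerance = 1e-5)
  expect_error(sigma_vs_posterior_slope(c(1, 1, 1), 1, 2), "all curvatures")
  expect_error(sigma_vs_posterior_slope(c(1, 2), 1, 2), "at least 3")
})

test_that("variational fit recovers the exact 1-weight conjugate posterior", {
  set.seed(10)
  x <- rnorm(30)
  w_true <- 0.8
  tau <- 0.5
  y <- x * w_true + rnorm(30, sd = tau)
  post_var <- 1 / (sum(x^2) / tau^2 + 1)   # unit Gaussian prior
  post_mean <- post_var * sum(x * y) / tau^2
  fit <- fit_variational_posterior(matrix(x), y, noise_sd = tau, prior_sd = 1,
                                   seed = 7)
  expect_equal(fit$sd, sqrt(post_var), tolerance = 0.05)
  expect_equal(fit$mean, post_mean, tolerance = 0.05)
})

test_that("with the likelihood switched off the posterior returns the prior", {
  set.seed(3)
  X <- matrix(rnorm(20 * 2), 20, 2)
  y <- rnorm(20)
  fit <- fit_variational_posterior(X, y, noise_sd = 1, prior_sd = 0.7,
                                   data_weight = 0, n_steps = 1500, seed = 2)
  expect_equal(fit$sd, c(0.7, 0.7), tolerance = 0.02)
  expect_equal(fit$mean, c(0, 0), tolerance = 0.02)
})

test_that("the smoothed ELBO trajectory increases over training", {
  set.seed(4)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- X %*% c(1, -0.5, 0.2) + rnorm(40, sd = 0.5)
  fit <- fit_variational_posterior(X, y, noise_sd = 0.5, seed = 5)
  sm <- stats::filter(fit$elbo_path, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_gt(sm[length(sm)], sm[1])
  # most smoothed steps move uphill
  expect_gt(mean(diff(sm) >= 0), 0.5)
})

test_that("variational and Laplace posteriors agree on a conjugate problem", {
  set.seed(11)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- X %*% c(0.5, -1, 0.3) + rnorm(60, sd = 0.4)
  H <- diag(crossprod(X)) / 0.4^2 + 1   # likelihood curvature + unit prior
  lap <- laplace_posterior_sd(H)
  fit <- fit_variational_posterior(X, y, noise_sd = 0.4, prior_sd = 1,
                                   seed = 9)
  expect_equal(fit$sd, lap, tolerance = 0.05)
})

test_that("trained toy ensembles track the analytic slope within tolerance", {
  h <- 10^seq(-1, 2, length.out = 12)
  toy <- make_quadratic_toy(h)
  rho <- 2 / 3
  spec <- cost_spec(c = 0.5, rho = rho, lambda = 0)
  fit <- train_quadratic(toy, spec, n_steps = 3000, seed = 6)
  sa <- sigma_vs_posterior_slope(h, 0.5, rho, sigma_trained = fit$sigma)
  expect_equal(sa$slope, 2 / (rho + 2), tolerance = 0.1)
  expect_lt(sa$slope, 1)
})
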