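test_that("softplus noise parameterisation is positive, monotone and stable", {
  expect_equal(sigma_from_phi(0), log(2))
  expect_equal(sigma_from_phi(50), 50, tolerance = 1e-12)
  expect_gt(sigma_from_phi(-50), 0)
  expect_equal(sigma_from_phi(-50), exp(-50), tolerance = 1e-12)
  phi <- seq(-20, 20, by = 0.5)
  expect_true(all(diff(sigma_from_phi(phi)) > 0))
  expect_equal(sigma_from_phi(phi_from_sigma(c(1e-6, 0.1, 3, 40))),
               c(1e-6, 0.1, 3, 40), tolerance = 1e-12)
})

test_that("weight sampling is reparameterised and deterministic given seed", {
  net <- init_network(network_config(widths = c(3, 4, 2)), seed = 5)
  s1 <- sample_weights(net, seed = 9)
  s2 <- sample_weights(net, seed = 9)
  expect_identical(s1, s2)
  for (l in 1:2) {
    sig <- sigma_from_phi(net$layers[[l]]$phi)
    expect_equal(s1$W[[l]], net$layers[[l]]$mu + sig * s1$xi[[l]])
  }
})

test_that("sampled weights match the Gaussian moments", {
  # one shared (mu, sigma) across a wide layer: across-synapse statistics of
  # a single draw estimate the single-synapse distribution
  net <- init_network(network_config(widths = c(300, 300, 2)),
                      sigma_init = 0.5, seed = 1)
  net$layers[[1]]$mu[] <- 0.7
  smp <- sample_weights(net, seed = 4)
  w <- as.vector(smp$W[[1]])
  n <- length(w)
  se_mean <- 0.5 / sqrt(n)
  expect_lt(abs(mean(w) - 0.7), 4 * se_mean)
  se_var <- 0.5^2 * sqrt(2 / (n - 1))
  expect_lt(abs(var(w) - 0.25), 4 * se_var)
})

test_that("the zero-noise limit collapses samples onto the means", {
  net <- init_network(network_config(widths = c(3, 4, 2)), sigma_init = 1e-30,
                      seed = 2)
  smp <- sample_weights(net, seed = 1)
  for (l in 1:2) {
    expect_equal(smp$W[[l]], net$layers[[l]]$mu, tolerance = 1e-12)
  }
})

test_that("forward pass rectifies hidden units and scores the output layer", {
  cfg <- network_config(widths = c(2, 1, 2))
  net <- init_network(cfg, seed = 1)
  # zero network: uniform class probabilities
  net$layers[[1]]$mu[] <- 0
  net$layers[[2]]$mu[] <- 0
  sc <- forward(c(0.3, 0.7), mean_weights(net), net)
  expect_equal(as.vector(sc), c(0, 0))
  expect_equal(performance_cost(sc, 0L), log(2))

  # single unit, w = [1, -1], x = [0.5, 2]: pre-activation -1.5, ReLU -> 0
  net$layers[[1]]$mu[, 1] <- c(1, -1)
  net$layers[[2]]$mu[] <- 3
  fp <- effsyn:::forward_pass(matrix(c(0.5, 2), 1), mean_weights(net), net)
  expect_equal(fp$Z[[1]][1, 1], -1.5)
  expect_equal(fp$A[[2]][1, 1], 0)

  expect_error(forward(c(1, 2, 3), mean_weights(net), net), "input width")
})

test_that("a hand-set chain of units reproduces hand-computed output", {
  cfg <- network_config(widths = c(2, 2, 1))
  net <- init_network(cfg, seed = 1)
  net$layers[[1]]$mu <- matrix(c(1, 0.5, -1, 2), 2, 2)
  net$layers[[1]]$bias <- c(0.1, -0.2)
  net$layers[[2]]$mu <- matrix(c(2, -3), 2, 1)
  net$layers[[2]]$bias <- 0.05
  x <- c(0.4, 0.6)
  h <- pmax(c(sum(c(1, 0.5) * x) - 0.1, sum(c(-1, 2) * x) + 0.2), 0)
  expect_equal(as.vector(forward(x, mean_weights(net), net)),
               sum(c(2, -3) * h) - 0.05)
})

test_that("hidden activations are non-negative for random inputs", {
  net <- init_network(network_config(widths = c(6, 5, 4, 3)), sigma_init = 0.3,
                      seed = 3)
  x <- matrix(runif(20 * 6, -2, 2), 20, 6)
  fp <- effsyn:::forward_pass(x, sample_weights(net, seed = 8), net)
  expect_true(all(fp$A[[2]] >= 0))
  expect_true(all(fp$A[[3]] >= 0))
})

test_that("stochastic forward in the zero-noise limit equals a plain MLP", {
  net <- init_network(network_config(widths = c(10, 7, 5, 3)),
                      sigma_init = 1e-30, seed = 6)
  x <- matrix(runif(15 * 10), 15, 10)
  W <- lapply(net$layers, `[[`, "mu")
  b <- lapply(net$layers, `[[`, "bias")
  expect_equal(forward(x, sample_weights(net, seed = 2), net),
               plain_forward(x, W, b), tolerance = 1e-12)
})

test_that("homogeneous mode keeps one shared noise level through training", {
  ds <- tiny_task()
  net <- init_network(tiny_net_config(), noise_mode = "homogeneous", seed = 4)
  fit <- train(net, ds, cost_spec(c = 1e-4, rho = 2),
               train_config(epochs = 2, eta_base = 5e-3, seed = 4))
  sig <- unlist(lapply(1:3, function(l) effsyn:::layer_sigma(fit$net, l)))
  expect_equal(var(sig), 0)
  expect_gt(sig[1], 0)
})
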