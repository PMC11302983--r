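test_that("training is deterministic given the seed", {
  ds <- tiny_task()
  cfg <- train_config(epochs = 2, eta_base = 5e-3, seed = 12)
  spec <- cost_spec(c = 1e-5, rho = 2)
  f1 <- train(init_network(tiny_net_config(), seed = 12), ds, spec, cfg)
  f2 <- train(init_network(tiny_net_config(), seed = 12), ds, spec, cfg)
  expect_identical(f1$net, f2$net)
  expect_identical(f1$history, f2$history)
  expect_identical(nrow(f1$history), 2L)
  expect_true(all(f1$history$mean_sigma > 0))
})

test_that("without energetic costs the trained noise shrinks", {
  ds <- tiny_task()
  net <- init_network(tiny_net_config(), sigma_init = 0.1, seed = 5)
  s0 <- mean_sigma(net)
  fit <- train(net, ds, cost_spec(c = 0, rho = 2, lambda = 0),
               train_config(epochs = 4, eta_base = 5e-3, seed = 5))
  expect_lt(mean_sigma(fit$net), s0)
})

test_that("trained noise on a quadratic toy matches the stationary point", {
  toy <- make_quadratic_toy(1)
  fit <- train_quadratic(toy, cost_spec(c = 1, rho = 2, lambda = 0), seed = 3)
  expect_equal(fit$sigma, 2^(1 / 4), tolerance = 0.05)
})

test_that("quadratic training is deterministic given the seed", {
  toy <- make_quadratic_toy(c(0.5, 4), c(1, -1))
  spec <- cost_spec(c = 0.3, rho = 2 / 3, lambda = 0)
  f1 <- train_quadratic(toy, spec, n_steps = 500, seed = 8)
  f2 <- train_quadratic(toy, spec, n_steps = 500, seed = 8)
  expect_identical(f1, f2)
})

test_that("accuracy under shuffled labels sits at chance", {
  ds <- tiny_task()
  ds$labels <- with(list(), {
    set.seed(1)
    sample(ds$labels)
  })
  net <- init_network(tiny_net_config(), sigma_init = 0.05, seed = 2)
  acc <- evaluate_accuracy(net, ds, n_noise_samples = 5, seed = 2)
  n_test <- sum(ds$split == "test")
  expect_lt(abs(acc - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / n_test))
})

test_that("zero-noise accuracy equals the deterministic accuracy", {
  ds <- tiny_task()
  net <- init_network(tiny_net_config(), sigma_init = 1e-30, seed = 2)
  expect_identical(
    evaluate_accuracy(net, ds, n_noise_samples = 3, seed = 1),
    evaluate_accuracy(net, ds, use_mean_weights = TRUE)
  )
  expect_error(evaluate_accuracy(net, ds, n_noise_samples = 0), "noise_samples")
})

test_that("averaging more noise samples stabilises the accuracy estimate", {
  ds <- tiny_task()
  net <- init_network(tiny_net_config(), sigma_init = 0.4, seed = 7)
  acc_few <- vapply(1:20, function(s) {
    evaluate_accuracy(net, ds, n_noise_samples = 1, seed = s)
  }, numeric(1))
  acc_many <- vapply(1:20, function(s) {
    evaluate_accuracy(net, ds, n_noise_samples = 10, seed = 100 + s)
  }, numeric(1))
  expect_lt(sd(acc_many), sd(acc_few))
})

test_that("with costs off the trainer reduces to a plain Adam MLP", {
  ds <- tiny_task()
  cfg <- train_config(epochs = 3, eta_base = 5e-3, beta2 = 0.99,
                      sigma_init = 1e-12, seed = 21)
  net0 <- init_network(tiny_net_config(), sigma_init = 1e-12, seed = 21)
  fit <- train(net0, ds, cost_spec(c = 0, rho = 2, lambda = 0), cfg)

  tr <- dataset_split(ds, "train")
  schedule <- effsyn:::with_local_seed(21, effsyn:::make_batch_schedule(
    nrow(tr$features), cfg$batch_size, cfg$epochs))
  plain <- plain_train(lapply(net0$layers, `[[`, "mu"),
                       lapply(net0$layers, `[[`, "bias"),
                       tr$features, tr$labels, schedule,
                       eta = cfg$eta_base, beta2 = cfg$beta2)
  for (l in 1:3) {
    expect_equal(fit$net$layers[[l]]$mu, plain$W[[l]], tolerance = 1e-6)
    expect_equal(fit$net$layers[[l]]$bias, plain$b[[l]], tolerance = 1e-6)
  }
  # and training made progress
  expect_lt(fit$history$performance[3], fit$history$performance[1])
})

test_that("divergence raises an error naming the offending term", {
  ds <- tiny_task()
  net <- init_network(tiny_net_config(), sigma_init = 1e-4, seed = 1)
  spec <- cost_spec(c = 1e308, rho = 2)
  expect_error(
    train(net, ds, spec, train_config(epochs = 1, seed = 1)),
    "reliability"
  )
})

test_that("c sweep rejects unsorted grids and annotates failures", {
  ds <- tiny_task()
  cfg <- train_config(epochs = 1, seed = 1)
  expect_error(sweep_c(c(1, 0), 2, ds, cfg, tiny_net_config()), "sorted")
  expect_error(
    sweep_c(c(0, 1e308), 2, ds, cfg, tiny_net_config(),
            modes = "heterogeneous"),
    "c = 1e\\+308"
  )
})
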