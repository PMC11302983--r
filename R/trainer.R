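#' Training hyperparameters
#'
#' Defaults follow the reference training regime: base learning rate
#' 5e-4, minibatch size 20, 50 epochs, means initialised Uniform(-0.1, 0.1)
#' and noise initialised homogeneously at sigma = 1e-4. The per-parameter
#' learning rate is adaptive, \eqn{\eta_i = \eta_{base}/\sqrt{\langle g_i^2
#' \rangle}}, realised as Adam with second-moment decay `beta2` and
#' regulariser `eps` added before division; important synapses receive large
#' gradients and hence small learning rates.
#'
#' @param eta_base base learning rate (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param epochs training epochs (>= 1).
#' @param sigma_init initial noise standard deviation (> 0).
#' @param mu_range half-width of the uniform mean initialisation.
#' @param beta1,beta2 Adam moment decay constants.
#' @param eps denominator regulariser of the adaptive rate.
#' @param sigma_floor floor applied to sigma inside the reliability-cost
#'   gradient only, preventing overflow of \eqn{\sigma^{-\rho-1}} at small
#'   initial noise; reported sigma values are never clipped.
#' @param n_eval_noise weight samples averaged when evaluating accuracy.
#' @param seed integer seed fixing initialisation, batch order and noise
#'   draws.
#' @return object of class `train_config`.
#' @export
train_config <- function(eta_base = 5e-4, batch_size = 20, epochs = 50,
                         sigma_init = 1e-4, mu_range = 0.1,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         sigma_floor = 1e-8, n_eval_noise = 10, seed = 1) {
  if (eta_base <= 0 || batch_size < 1 || epochs < 1 || sigma_init <= 0) {
    stop_arg("need eta_base > 0, batch_size >= 1, epochs >= 1, sigma_init > 0")
  }
  structure(list(eta_base = eta_base, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), sigma_init = sigma_init,
                 mu_range = mu_range, beta1 = beta1, beta2 = beta2, eps = eps,
                 sigma_floor = sigma_floor,
                 n_eval_noise = as.integer(n_eval_noise),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Minibatch index schedule: a list of index vectors, one per step, covering
# `epochs` shuffled passes over n samples. Deterministic given the RNG state.
make_batch_schedule <- function(n, batch_size, epochs) {
  steps <- list()
  for (e in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    steps <- c(steps, lapply(starts, function(s) {
      perm[s:min(s + batch_size - 1L, n)]
    }))
  }
  steps
}

# --- Adam ------------------------------------------------------------------

adam_state <- function(template) {
  lapply(template, function(x) list(m = x * 0, v = x * 0))
}

adam_update <- function(state, grads, params, cfg, t) {
  bc1 <- 1 - cfg$beta1^t
  bc2 <- 1 - cfg$beta2^t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    state[[k]]$m <- cfg$beta1 * state[[k]]$m + (1 - cfg$beta1) * g
    state[[k]]$v <- cfg$beta2 * state[[k]]$v + (1 - cfg$beta2) * g^2
    mhat <- state[[k]]$m / bc1
    vhat <- state[[k]]$v / bc2
    params[[k]] <- params[[k]] - cfg$eta_base * mhat / (sqrt(vhat) + cfg$eps)
  }
  list(state = state, params = params)
}

# --- gradients -------------------------------------------------------------

# Backward pass for one weight sample on one minibatch.
# Returns per-layer: gW (d perf / d w, batch-mean), gb, plus the forward pass.
backward_pass <- function(x, y, sample, net) {
  fp <- forward_pass(x, sample, net)
  L <- length(net$layers)
  B <- nrow(x)
  scores <- fp$scores
  probs <- exp(scores - row_logsumexp(scores))
  D <- probs
  D[cbind(seq_len(B), y + 1L)] <- D[cbind(seq_len(B), y + 1L)] - 1
  D <- D / B
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fp$A[[l]], D)
    gb[[l]] <- -colSums(D)
    if (l > 1L) {
      D <- (D %*% t(sample$W[[l]])) * (fp$Z[[l - 1L]] > 0)
    }
  }
  list(gW = gW, gb = gb, fp = fp)
}

# d reliability / d sigma for one layer's sigma matrix.
reliability_grad_sigma <- function(sigma, spec, sigma_floor) {
  if (spec$c == 0) return(sigma * 0)
  sg <- pmax(sigma, sigma_floor)
  if (spec$reliability_form == "power") {
    -spec$c * spec$rho * sg^(-spec$rho - 1)
  } else {
    -spec$c / sg
  }
}

#' Train a stochastic synapse network
#'
#' Minibatch gradient descent on the overall cost. Each step draws one
#' weight sample per minibatch (or per example, see [network_config()]),
#' computes the cross-entropy on the batch plus the magnitude and
#' reliability costs, and backpropagates through the reparameterisation
#' \eqn{w = \mu + \sigma\xi} to both \eqn{\mu} and \eqn{\phi}:
#' \eqn{\partial L/\partial \mu_i = g_i + \lambda\,\mathrm{sign}(\mu_i)} and
#' \eqn{\partial L/\partial \phi_i = (g_i \xi_i + \partial
#' \mathrm{rel}/\partial\sigma_i)\,\mathrm{sigmoid}(\phi_i)}, where
#' \eqn{g_i} is the gradient with respect to the realised weight. Updates
#' use the adaptive per-parameter rate (Adam). In homogeneous noise mode
#' the shared \eqn{\phi} receives the summed gradient of all its synapses.
#'
#' @param net an initialised `synapse_params` (see [init_network()]).
#' @param dataset a `synapse_dataset`; the train split is used for
#'   optimisation and the val split for per-epoch accuracy.
#' @param spec a [cost_spec()].
#' @param config a [train_config()].
#' @return list with `net` (trained parameters) and `history`
#'   (`train_history`: per-epoch data.frame with performance cost, val
#'   accuracy, mean sigma and the cost breakdown) plus `g2` (per-layer
#'   running mean-squared weight gradients at the end of training).
#' @export
train <- function(net, dataset, spec, config) {
  train_ds <- dataset_split(dataset, "train")
  val_ds <- dataset_split(dataset, "val")
  x_all <- train_ds$features
  y_all <- train_ds$labels
  L <- length(net$layers)
  shared <- net$noise_mode == "homogeneous"

  with_local_seed(config$seed, {
    schedule <- make_batch_schedule(nrow(x_all), config$batch_size, config$epochs)
    steps_per_epoch <- length(schedule) / config$epochs

    mu_st <- adam_state(lapply(net$layers, `[[`, "mu"))
    b_st <- adam_state(lapply(net$layers, `[[`, "bias"))
    phi_st <- if (shared && net$config$share_phi == "network") {
      adam_state(list(0))
    } else {
      adam_state(lapply(net$layers, `[[`, "phi"))
    }
    g2 <- lapply(net$layers, function(l) l$mu * 0)

    hist <- vector("list", config$epochs)
    t <- 0L
    for (step in seq_along(schedule)) {
      t <- t + 1L
      idx <- schedule[[step]]
      x <- x_all[idx, , drop = FALSE]
      y <- y_all[idx]

      if (net$config$sample_per_example) {
        acc <- NULL
        for (j in seq_along(idx)) {
          smp <- sample_weights(net)
          bp <- backward_pass(x[j, , drop = FALSE], y[j], smp, net)
          if (is.null(acc)) {
            acc <- bp
            acc$xi <- smp$xi
            acc$gWxi <- lapply(seq_len(L), function(l) bp$gW[[l]] * smp$xi[[l]])
          } else {
            for (l in seq_len(L)) {
              acc$gW[[l]] <- acc$gW[[l]] + bp$gW[[l]]
              acc$gb[[l]] <- acc$gb[[l]] + bp$gb[[l]]
              acc$gWxi[[l]] <- acc$gWxi[[l]] + bp$gW[[l]] * smp$xi[[l]]
            }
          }
        }
        gW <- lapply(acc$gW, function(g) g / length(idx))
        gb <- lapply(acc$gb, function(g) g / length(idx))
        gWxi <- lapply(acc$gWxi, function(g) g / length(idx))
      } else {
        smp <- sample_weights(net)
        bp <- backward_pass(x, y, smp, net)
        gW <- bp$gW
        gb <- bp$gb
        gWxi <- lapply(seq_len(L), function(l) gW[[l]] * smp$xi[[l]])
      }

      g_mu <- lapply(seq_len(L), function(l) {
        gW[[l]] + spec$lambda * sign(net$layers[[l]]$mu)
      })
      g_phi <- lapply(seq_len(L), function(l) {
        sig <- layer_sigma(net, l)
        (gWxi[[l]] + reliability_grad_sigma(sig, spec, config$sigma_floor)) *
          sigmoid(if (length(net$layers[[l]]$phi) == 1L) {
            matrix(net$layers[[l]]$phi, nrow(sig), ncol(sig))
          } else {
            net$layers[[l]]$phi
          })
      })
      for (l in seq_len(L)) g2[[l]] <- config$beta2 * g2[[l]] +
        (1 - config$beta2) * gW[[l]]^2

      mu_list <- lapply(net$layers, `[[`, "mu")
      up <- adam_update(mu_st, g_mu, mu_list, config, t)
      mu_st <- up$state
      for (l in seq_len(L)) net$layers[[l]]$mu <- up$params[[l]]

      b_list <- lapply(net$layers, `[[`, "bias")
      up <- adam_update(b_st, gb, b_list, config, t)
      b_st <- up$state
      for (l in seq_len(L)) net$layers[[l]]$bias <- up$params[[l]]

      if (shared && net$config$share_phi == "network") {
        gsum <- sum(vapply(g_phi, sum, numeric(1)))
        up <- adam_update(phi_st, list(gsum), list(net$layers[[1]]$phi),
                          config, t)
        phi_st <- up$state
        for (l in seq_len(L)) net$layers[[l]]$phi <- up$params[[1]]
      } else if (shared) {
        gsum <- lapply(g_phi, sum)
        phi_list <- lapply(net$layers, `[[`, "phi")
        up <- adam_update(phi_st, gsum, phi_list, config, t)
        phi_st <- up$state
        for (l in seq_len(L)) net$layers[[l]]$phi <- up$params[[l]]
      } else {
        phi_list <- lapply(net$layers, `[[`, "phi")
        up <- adam_update(phi_st, g_phi, phi_list, config, t)
        phi_st <- up$state
        for (l in seq_len(L)) net$layers[[l]]$phi <- up$params[[l]]
      }

      if (step %% steps_per_epoch == 0) {
        epoch <- step / steps_per_epoch
        smp_eval <- sample_weights(net)
        scores <- forward(x_all, smp_eval, net)
        safe <- function(f) tryCatch(f, error = function(e) NaN)
        mu_now <- lapply(net$layers, `[[`, "mu")
        sig_now <- lapply(seq_len(L), function(l) layer_sigma(net, l))
        terms <- c(
          performance = safe(performance_cost(scores, y_all)),
          magnitude = safe(magnitude_cost(mu_now, spec$lambda)),
          reliability = safe(if (spec$reliability_form == "power") {
            reliability_cost(sig_now, spec$c, spec$rho)
          } else {
            spec$c * entropic_cost(sig_now)
          })
        )
        if (any(!is.finite(terms))) {
          stop("training diverged: non-finite ",
               paste(names(terms)[!is.finite(terms)], collapse = ", "),
               " cost at epoch ", epoch)
        }
        cb <- structure(list(performance = terms[["performance"]],
                             magnitude = terms[["magnitude"]],
                             reliability = terms[["reliability"]],
                             total = sum(terms)),
                        class = "cost_breakdown")
        val_acc <- if (nrow(val_ds$features) > 0) {
          mean(max.col(forward(val_ds$features, mean_weights(net), net)) - 1L ==
                 val_ds$labels)
        } else {
          NA_real_
        }
        hist[[epoch]] <- data.frame(
          epoch = epoch, performance = cb$performance,
          magnitude = cb$magnitude, reliability = cb$reliability,
          total = cb$total, val_accuracy = val_acc,
          mean_sigma = mean_sigma(net)
        )
      }
    }
    history <- do.call(rbind, hist)
    class(history) <- c("train_history", "data.frame")
    list(net = net, history = history, g2 = g2)
  })
}

#' Classification accuracy under synaptic noise
#'
#' Accuracy averaged over independent weight samples, reflecting what a
#' noisy network actually delivers at test time. With
#' `use_mean_weights = TRUE` (or in the zero-noise limit) this reduces to
#' the deterministic accuracy at the synaptic means.
#'
#' @param net a `synapse_params`.
#' @param dataset a `synapse_dataset`.
#' @param n_noise_samples number of weight samples averaged (>= 1).
#' @param seed integer seed for the noise draws.
#' @param split which split to evaluate (default `"test"`).
#' @param use_mean_weights evaluate at `w = mu` instead of sampling.
#' @return accuracy in \[0, 1\].
#' @export
evaluate_accuracy <- function(net, dataset, n_noise_samples = 10, seed = 1,
                              split = "test", use_mean_weights = FALSE) {
  ds <- dataset_split(dataset, split)
  if (nrow(ds$features) == 0) stop_arg("empty dataset split: ", split)
  if (n_noise_samples < 1) stop_arg("n_noise_samples must be >= 1")
  if (use_mean_weights) {
    pred <- max.col(forward(ds$features, mean_weights(net), net)) - 1L
    return(mean(pred == ds$labels))
  }
  with_local_seed(seed, {
    accs <- vapply(seq_len(n_noise_samples), function(s) {
      smp <- sample_weights(net)
      pred <- max.col(forward(ds$features, smp, net)) - 1L
      mean(pred == ds$labels)
    }, numeric(1))
    mean(accs)
  })
}

#' Sweep the reliability-cost multiplier
#'
#' Trains one network per (c, noise mode) pair and tabulates the
#' performance-reliability tradeoff: as `c` grows, precision becomes more
#' expensive, the optimised noise rises and accuracy falls; per-synapse
#' (heterogeneous) noise maintains higher accuracy than a single shared
#' (homogeneous) noise level at the same `c`. The reported reliability-cost
#' column uses the tangency convention at scale `s = 1`, i.e.
#' \eqn{(1/\rho)\sum_i \sigma_i^{-\rho}}, so curves for different exponents
#' share an axis.
#'
#' @param c_grid non-negative, sorted multipliers.
#' @param rho power-law exponent.
#' @param dataset a `synapse_dataset`.
#' @param config a [train_config()].
#' @param net_config a [network_config()].
#' @param modes noise modes to run (default both).
#' @param lambda magnitude-cost multiplier.
#' @return data.frame with columns `c`, `mode`, `accuracy`, `mean_sigma`,
#'   `reliability_cost`, `rho`, in grid order for each mode.
#' @export
sweep_c <- function(c_grid, rho, dataset, config, net_config,
                    modes = c("heterogeneous", "homogeneous"),
                    lambda = 1e-4) {
  if (is.unsorted(c_grid) || any(c_grid < 0)) {
    stop_arg("c_grid must be sorted and non-negative")
  }
  rows <- list()
  for (mode in modes) {
    for (ci in seq_along(c_grid)) {
      cval <- c_grid[ci]
      spec <- cost_spec(c = cval, rho = rho, lambda = lambda)
      net <- init_network(net_config, noise_mode = mode,
                          sigma_init = config$sigma_init,
                          mu_range = config$mu_range, seed = config$seed)
      fit <- tryCatch(
        train(net, dataset, spec, config),
        error = function(e) {
          stop("sweep failed at c = ", cval, ", mode = ", mode, ": ",
               conditionMessage(e), call. = FALSE)
        }
      )
      sig <- unlist(lapply(seq_along(fit$net$layers),
                           function(l) layer_sigma(fit$net, l)))
      rows[[length(rows) + 1L]] <- data.frame(
        c = cval, mode = mode,
        accuracy = evaluate_accuracy(fit$net, dataset,
                                     n_noise_samples = config$n_eval_noise,
                                     seed = config$seed),
        mean_sigma = mean(sig),
        reliability_cost = reliability_cost(sig, c_from_scale(rho, s = 1), rho),
        rho = rho
      )
    }
  }
  do.call(rbind, rows)
}

#' Train noise levels on a quadratic toy problem
#'
#' Optimises per-synapse \eqn{(\mu_i, \phi_i)} on the loss
#' \eqn{\sum_i \tfrac12 h_i (w_i - w^*_i)^2} plus the energetic costs, with
#' weights sampled by the reparameterisation each step. Because the loss is
#' exactly quadratic with curvature \eqn{h_i}, the expected objective in
#' \eqn{\sigma_i} is \eqn{\tfrac12 h_i \sigma_i^2 + c\sigma_i^{-\rho}},
#' whose stationary point \eqn{\sigma^*_i = (c\rho/h_i)^{1/(\rho+2)}} the
#' trained noise should recover (see [analytic_sigma()]).
#'
#' @param toy a [make_quadratic_toy()] object.
#' @param spec a [cost_spec()].
#' @param n_steps optimisation steps.
#' @param n_draws weight samples averaged per gradient step.
#' @param eta_base,beta1,beta2,eps Adam constants. The defaults use a larger
#'   base step and a shorter second-moment memory than the network trainer:
#'   over a few thousand steps a long memory of the initially enormous
#'   reliability gradients would throttle the ascent of the noise
#'   parameters (see the vignette section on optimiser settings).
#' @param sigma_init initial noise level.
#' @param mu_init initial means (default zeros).
#' @param tail_frac fraction of final steps over which sigma is averaged to
#'   smooth sampling jitter in the reported value.
#' @param seed integer seed.
#' @return list with `sigma` (tail-averaged), `sigma_final`, `mu`, and the
#'   per-step `sigma_path` matrix.
#' @export
train_quadratic <- function(toy, spec, n_steps = 4000, n_draws = 8,
                            eta_base = 0.01, beta1 = 0.9, beta2 = 0.99,
                            eps = 1e-8, sigma_init = 0.1,
                            mu_init = rep(0, length(toy$h)),
                            tail_frac = 0.25, seed = 1) {
  k <- length(toy$h)
  cfg <- list(eta_base = eta_base, beta1 = beta1, beta2 = beta2, eps = eps)
  with_local_seed(seed, {
    mu <- as.numeric(mu_init)
    phi <- rep(phi_from_sigma(sigma_init), k)
    st <- adam_state(list(mu = mu, phi = phi))
    sigma_path <- matrix(NA_real_, n_steps, k)
    for (t in seq_len(n_steps)) {
      sigma <- sigma_from_phi(phi)
      xi <- matrix(stats::rnorm(n_draws * k), n_draws, k)
      w <- matrix(mu, n_draws, k, byrow = TRUE) +
        matrix(sigma, n_draws, k, byrow = TRUE) * xi
      gw <- sweep(w, 2L, toy$w_star) * matrix(toy$h, n_draws, k, byrow = TRUE)
      g_mu <- colMeans(gw) + spec$lambda * sign(mu)
      g_sigma <- colMeans(gw * xi) +
        reliability_grad_sigma(sigma, spec, 1e-8)
      g_phi <- g_sigma * sigmoid(phi)
      up <- adam_update(st, list(mu = g_mu, phi = g_phi),
                        list(mu = mu, phi = phi), cfg, t)
      st <- up$state
      mu <- up$params$mu
      phi <- up$params$phi
      sigma_path[t, ] <- sigma_from_phi(phi)
    }
    tail_rows <- max(1L, floor(tail_frac * n_steps))
    tail_idx <- (n_steps - tail_rows + 1L):n_steps
    list(
      sigma = colMeans(sigma_path[tail_idx, , drop = FALSE]),
      sigma_final = sigma_path[n_steps, ],
      mu = mu,
      sigma_path = sigma_path
    )
  })
}

#' Write a training history to CSV
#' @param history a `train_history`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_train_history <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}
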