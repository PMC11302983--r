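#' Empirical Fisher estimate of synapse importance
#'
#' Diagonal-Hessian proxy \eqn{H_{ii} \approx \langle g_i^2 \rangle}: with
#' all parameters frozen and weights fixed at their means \eqn{w = \mu}
#' (no noise), the squared per-synapse gradient of the performance cost is
#' averaged over minibatches across several passes of the data. Synapses
#' whose presynaptic unit never fires receive exactly zero importance.
#'
#' @param net a trained `synapse_params`.
#' @param dataset a `synapse_dataset`; the train split is used.
#' @param n_epochs passes over the data (default 10).
#' @param batch_size minibatch size for the averaging.
#' @param seed integer seed for the batch shuffling.
#' @return list of per-layer matrices of \eqn{H_{ii}} values (same shapes
#'   as the `mu` matrices).
#' @export
empirical_fisher <- function(net, dataset, n_epochs = 10, batch_size = 20,
                             seed = 1) {
  if (n_epochs < 1) stop_arg("n_epochs must be >= 1")
  bad <- vapply(net$layers, function(l) any(!is.finite(l$mu)), logical(1))
  if (any(bad)) stop_arg("network parameters contain non-finite values")
  ds <- dataset_split(dataset, "train")
  x_all <- ds$features
  y_all <- ds$labels
  smp <- mean_weights(net)
  L <- length(net$layers)
  acc <- lapply(net$layers, function(l) l$mu * 0)
  n_batches <- 0L
  with_local_seed(seed, {
    schedule <- make_batch_schedule(nrow(x_all), batch_size, n_epochs)
    for (idx in schedule) {
      bp <- backward_pass(x_all[idx, , drop = FALSE], y_all[idx], smp, net)
      for (l in seq_len(L)) acc[[l]] <- acc[[l]] + bp$gW[[l]]^2
      n_batches <- n_batches + 1L
    }
  })
  lapply(acc, function(a) a / n_batches)
}

#' Empirical Fisher on a quadratic toy with noisy targets
#'
#' Counterpart of [empirical_fisher()] where the closed form is available:
#' each observation perturbs the optimum, \eqn{w^*_j = w^* + \epsilon_j}
#' with \eqn{\epsilon_j \sim N(0, \tau^2)}, and the per-observation gradient
#' at the frozen point \eqn{w = \mu} is \eqn{g_j = h(\mu - w^*_j)}. The
#' average squared gradient therefore estimates
#' \eqn{h^2[(\mu - w^*)^2 + \tau^2]}.
#'
#' @param toy a [make_quadratic_toy()] object.
#' @param mu point at which gradients are evaluated (defaults to the
#'   optimum).
#' @param noise_sd observation-noise standard deviation \eqn{\tau}.
#' @param n_samples observations averaged.
#' @param seed integer seed.
#' @return vector of per-synapse mean-squared gradients.
#' @export
empirical_fisher_quadratic <- function(toy, mu = toy$w_star, noise_sd = 0.1,
                                       n_samples = 10000, seed = 1) {
  k <- length(toy$h)
  with_local_seed(seed, {
    eps <- matrix(stats::rnorm(n_samples * k, sd = noise_sd), n_samples, k)
    g <- (matrix(mu - toy$w_star, n_samples, k, byrow = TRUE) - eps) *
      matrix(toy$h, n_samples, k, byrow = TRUE)
    colMeans(g^2)
  })
}

#' Adaptive per-synapse learning rates
#'
#' \eqn{\eta_i = \eta_{base} / (\sqrt{\langle g_i^2 \rangle} + \epsilon)}:
#' the learning rate actually applied by the optimiser's normalisation.
#' Important synapses (large mean-squared gradient) get small rates, so the
#' learning rate doubles as an experimentally accessible importance proxy.
#'
#' @param g2 mean-squared gradients (vector or matrix, >= 0).
#' @param eta_base base learning rate.
#' @param eps denominator regulariser keeping the rate finite at `g2 = 0`.
#' @return learning rates, same shape as `g2`.
#' @export
adaptive_learning_rates <- function(g2, eta_base = 5e-4, eps = 1e-8) {
  if (any(g2 < 0)) stop_arg("mean-squared gradients must be >= 0")
  eta_base / (sqrt(g2) + eps)
}

#' Average input rates of presynaptic units
#'
#' Mean absolute activation, over the dataset, of each unit feeding the
#' synapses of one layer, with weights fixed at the means. For hidden
#' presynaptic layers these are ReLU outputs, so the absolute value is the
#' plain mean rate.
#'
#' @param net a `synapse_params`.
#' @param dataset a `synapse_dataset` (all splits are used).
#' @param layer index of the synaptic layer (1 = input-to-first-hidden);
#'   rates are those of its presynaptic units.
#' @return numeric vector, one rate per presynaptic unit.
#' @export
input_rates <- function(net, dataset, layer = 2) {
  L <- length(net$layers)
  if (layer < 1 || layer > L) stop_arg("layer must be in 1..", L)
  fp <- forward_pass(dataset$features, mean_weights(net), net)
  colMeans(abs(fp$A[[layer]]))
}

#' Rank correlation and slope on logarithmic axes
#'
#' Spearman rank correlation and least-squares slope of `log(b)` on
#' `log(a)`, computed on the pairs where both entries are strictly
#' positive (others are dropped and counted). Rank correlation is invariant
#' to the log transform and robust to the heavy tails typical of
#' importance and variance distributions.
#'
#' @param a,b positive quantities of equal length.
#' @return object of class `correlation_result`: list with `coefficient`,
#'   `slope`, `n` (surviving pairs), `n_dropped`.
#' @export
log_log_correlation <- function(a, b) {
  if (length(a) != length(b)) stop_arg("a and b must have equal length")
  keep <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  if (sum(keep) < 3) stop_arg("fewer than 3 positive pairs survive")
  la <- log(a[keep]); lb <- log(b[keep])
  structure(list(
    coefficient = stats::cor(la, lb, method = "spearman"),
    slope = unname(stats::coef(stats::lm(lb ~ la))[2]),
    n = sum(keep),
    n_dropped = sum(!keep)
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("rank correlation %.3f, log-log slope %.3f (n = %d, dropped %d)\n",
              x$coefficient, x$slope, x$n, x$n_dropped))
  invisible(x)
}

#' Per-synapse importance/variability report for one layer
#'
#' Assembles, for every synapse of the chosen layer: the empirical-Fisher
#' importance \eqn{H_{ii}}, the adaptive learning rate \eqn{\eta_i}
#' computed from the same mean-squared gradients, the presynaptic input
#' rate \eqn{|x|}, and the optimised PSP variance \eqn{\sigma_i^2}. The
#' energy-efficient solution ties these together: high importance and high
#' input rate go with low variance, low importance with high variance and
#' high learning rate.
#'
#' @param net a trained `synapse_params`.
#' @param dataset a `synapse_dataset`.
#' @param layer synaptic layer to analyse (default 2: the weights between
#'   the two hidden layers).
#' @param n_epochs data passes for the Fisher average (default 10).
#' @param eta_base,eps see [adaptive_learning_rates()].
#' @param seed integer seed.
#' @return object of class `diagnostics_report`: data.frame with one row
#'   per synapse (`pre`, `post`, `H`, `g2`, `eta`, `input_rate`, `sigma2`).
#' @export
diagnostics_report <- function(net, dataset, layer = 2, n_epochs = 10,
                               eta_base = 5e-4, eps = 1e-8, seed = 1) {
  H_all <- empirical_fisher(net, dataset, n_epochs = n_epochs, seed = seed)
  H <- H_all[[layer]]
  rates <- input_rates(net, dataset, layer = layer)
  sig <- layer_sigma(net, layer)
  d <- dim(H)
  out <- data.frame(
    pre = rep(seq_len(d[1]), times = d[2]),
    post = rep(seq_len(d[2]), each = d[1]),
    H = as.vector(H),
    g2 = as.vector(H),
    eta = as.vector(adaptive_learning_rates(H, eta_base, eps)),
    input_rate = rates[rep(seq_len(d[1]), times = d[2])],
    sigma2 = as.vector(sig)^2
  )
  class(out) <- c("diagnostics_report", "data.frame")
  out
}

#' The three importance-variability correlations
#'
#' Computes the rank correlations characteristic of energy-efficient
#' heterogeneous noise: importance vs variance (negative), learning rate vs
#' variance (positive), input rate vs variance (negative).
#'
#' @param report a [diagnostics_report()].
#' @return named list of `correlation_result`s: `H_sigma2`, `eta_sigma2`,
#'   `rate_sigma2`.
#' @export
variability_correlations <- function(report) {
  list(
    H_sigma2 = log_log_correlation(report$H, report$sigma2),
    eta_sigma2 = log_log_correlation(report$eta, report$sigma2),
    rate_sigma2 = log_log_correlation(report$input_rate, report$sigma2)
  )
}

#' Write a diagnostics report to CSV
#' @param report a `diagnostics_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diagnostics_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
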