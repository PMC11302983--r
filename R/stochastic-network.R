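#' Network architecture configuration
#'
#' Fully connected feedforward rate network. Hidden units use a ReLU rate
#' nonlinearity applied to the somatic potential \eqn{\sum_i w_i x_i - w_0};
#' the output layer returns unsquashed class scores (softmax lives inside
#' the performance cost).
#'
#' @param widths integer vector of layer widths from input to output,
#'   default `c(784, 100, 100, 10)`. At least one hidden layer.
#' @param sample_per_example logical; if `TRUE` weights are resampled for
#'   every example instead of once per minibatch. Default `FALSE` (one
#'   sample per minibatch, resampled each step).
#' @param share_phi one of `"network"` or `"layer"`: in homogeneous noise
#'   mode, whether a single noise parameter is shared across the whole
#'   network (default) or one per layer.
#' @return object of class `network_config`.
#' @export
network_config <- function(widths = c(784, 100, 100, 10),
                           sample_per_example = FALSE,
                           share_phi = c("network", "layer")) {
  if (length(widths) < 3) stop_arg("need at least one hidden layer")
  if (any(widths < 1)) stop_arg("all layer widths must be >= 1")
  structure(list(widths = as.integer(widths),
                 sample_per_example = isTRUE(sample_per_example),
                 share_phi = match.arg(share_phi)),
            class = "network_config")
}

#' Initialise stochastic synapse parameters
#'
#' Every synapse carries a PSP mean \eqn{\mu_i} and an unconstrained noise
#' parameter \eqn{\phi_i} with \eqn{\sigma_i = \mathrm{softplus}(\phi_i)}.
#' Means are initialised from Uniform(-0.1, 0.1) and the noise level
#' homogeneously at `sigma_init` (default 1e-4). Biases are deterministic,
#' initialised at zero, and carry no noise or energetic cost.
#'
#' In `"homogeneous"` noise mode a single \eqn{\phi} is shared by all
#' synapses in the network (or one per layer, see [network_config()]), so
#' the optimised noise is forced to be identical across synapses.
#'
#' @param config a [network_config()].
#' @param noise_mode `"heterogeneous"` (per-synapse noise) or
#'   `"homogeneous"` (shared noise).
#' @param sigma_init initial noise standard deviation (> 0).
#' @param mu_range half-width of the uniform mean initialisation.
#' @param seed integer seed; initialisation is deterministic given it.
#' @return object of class `synapse_params`: list with per-layer `mu`
#'   matrices (fan-in x fan-out), `phi` (matrices, or scalars when shared),
#'   `bias` vectors, plus `config` and `noise_mode`.
#' @export
init_network <- function(config, noise_mode = c("heterogeneous", "homogeneous"),
                         sigma_init = 1e-4, mu_range = 0.1, seed = 1) {
  noise_mode <- match.arg(noise_mode)
  if (sigma_init <= 0) stop_arg("sigma_init must be positive")
  w <- config$widths
  L <- length(w) - 1L
  phi0 <- phi_from_sigma(sigma_init)
  with_local_seed(seed, {
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      mu <- matrix(stats::runif(w[l] * w[l + 1], -mu_range, mu_range),
                   w[l], w[l + 1])
      phi <- if (noise_mode == "heterogeneous") {
        matrix(phi0, w[l], w[l + 1])
      } else {
        phi0  # scalar; resolved through shared_phi()
      }
      layers[[l]] <- list(mu = mu, phi = phi, bias = rep(0, w[l + 1]))
    }
    if (noise_mode == "homogeneous" && config$share_phi == "network") {
      # collapse to one scalar stored on layer 1; others reference it
      for (l in seq_len(L)) layers[[l]]$phi <- phi0
    }
    net <- list(layers = layers, config = config, noise_mode = noise_mode)
    class(net) <- "synapse_params"
    net
  })
}

#' @export
print.synapse_params <- function(x, ...) {
  w <- x$config$widths
  cat(sprintf("stochastic synapse network %s, %s noise, %d synapses\n",
              paste(w, collapse = "-"), x$noise_mode, n_synapses(x)))
  cat(sprintf("mean sigma: %.4g\n", mean_sigma(x)))
  invisible(x)
}

#' Number of synapses (excluding biases)
#' @param net a `synapse_params` object.
#' @return integer count.
#' @export
n_synapses <- function(net) {
  sum(vapply(net$layers, function(l) length(l$mu), numeric(1)))
}

# Per-layer sigma matrix, honouring shared phi in homogeneous mode.
layer_sigma <- function(net, l) {
  phi <- net$layers[[l]]$phi
  s <- sigma_from_phi(phi)
  if (length(s) == 1L) {
    matrix(s, nrow(net$layers[[l]]$mu), ncol(net$layers[[l]]$mu))
  } else {
    s
  }
}

#' Average noise standard deviation across all synapses
#'
#' The tradeoff curves report this all-layer average; per-layer values are
#' available via `per_layer = TRUE`.
#'
#' @param net a `synapse_params` object.
#' @param per_layer if `TRUE`, return one mean per layer.
#' @return numeric scalar (or vector).
#' @export
mean_sigma <- function(net, per_layer = FALSE) {
  m <- vapply(seq_along(net$layers),
              function(l) mean(layer_sigma(net, l)), numeric(1))
  n <- vapply(net$layers, function(l) length(l$mu), numeric(1))
  if (per_layer) m else sum(m * n) / sum(n)
}

#' Sample realised weights by the reparameterisation trick
#'
#' Draws standard-normal noise \eqn{\xi_i} and forms
#' \eqn{w_i = \mu_i + \sigma_i \xi_i} for every synapse. Storing \eqn{\xi}
#' is what lets gradients flow to both \eqn{\mu} and \eqn{\phi} through a
#' realised sample.
#'
#' @param net a `synapse_params` object.
#' @param seed optional integer; draws are deterministic given it.
#' @return object of class `weight_sample`: per-layer lists `W` (realised
#'   weights) and `xi` (the noise draws), plus the seed.
#' @export
sample_weights <- function(net, seed = NULL) {
  draw <- function() {
    xi <- lapply(net$layers, function(l) {
      matrix(stats::rnorm(length(l$mu)), nrow(l$mu), ncol(l$mu))
    })
    W <- lapply(seq_along(net$layers), function(l) {
      net$layers[[l]]$mu + layer_sigma(net, l) * xi[[l]]
    })
    structure(list(W = W, xi = xi, seed = seed), class = "weight_sample")
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Deterministic weights at the synaptic means
#'
#' Equivalent to the zero-noise limit: a `weight_sample` with `xi = 0`,
#' `W = mu`. Used for evaluation at the mean and for the empirical Fisher.
#'
#' @param net a `synapse_params` object.
#' @return a `weight_sample`.
#' @export
mean_weights <- function(net) {
  xi <- lapply(net$layers, function(l) {
    matrix(0, nrow(l$mu), ncol(l$mu))
  })
  W <- lapply(net$layers, function(l) l$mu)
  structure(list(W = W, xi = xi, seed = NULL), class = "weight_sample")
}

# Full forward pass keeping intermediate activations for backprop.
# x: batch x input matrix. Returns list(A = activations incl. input,
# Z = pre-activations, scores).
forward_pass <- function(x, sample, net) {
  L <- length(net$layers)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- x
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% sample$W[[l]] -
      matrix(net$layers[[l]]$bias, nrow(x), length(net$layers[[l]]$bias),
             byrow = TRUE)
    A[[l + 1L]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(A = A, Z = Z, scores = A[[L + 1L]])
}

#' Forward pass through the stochastic network
#'
#' Computes per-layer rates \eqn{f(Wx - w_0)} with ReLU hidden units and
#' returns raw class scores for the output layer.
#'
#' @param x feature matrix (batch x input width) or a single feature vector.
#' @param sample a `weight_sample` (see [sample_weights()], [mean_weights()]).
#' @param net the `synapse_params` the sample was drawn from.
#' @return matrix of class scores (batch x output width).
#' @export
forward <- function(x, sample, net) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != net$config$widths[1]) {
    stop_arg("input width ", ncol(x), " does not match network input width ",
             net$config$widths[1])
  }
  forward_pass(x, sample, net)$scores
}
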