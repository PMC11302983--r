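#' Objective hyperparameters
#'
#' The training objective trades task performance against two energetic
#' costs:
#' \deqn{\mathrm{overall} = \mathrm{performance} + \lambda \sum_i |\mu_i|
#'       + c \sum_i \sigma_i^{-\rho}.}
#' `c` scales the reliability cost (precision is expensive), `rho` is the
#' power-law exponent fixed by the dominant biophysical mechanism (1/2
#' calcium, 2/3 membrane surface, 4/3 actin, 2 trafficking), and `lambda`
#' scales the L1 magnitude cost. `s` is the scale at which the power-law
#' cost touches the entropy bound (see [entropy_bound_gap()]); setting
#' `c = s^rho / rho` instantiates that tangency.
#'
#' @param c reliability-cost multiplier (>= 0).
#' @param rho power-law exponent (> 0).
#' @param lambda magnitude-cost multiplier (>= 0), default 1e-4.
#' @param s entropy-bound scale (> 0), default 0.01.
#' @param reliability_form `"power"` for the biophysical cost
#'   `c * sum(sigma^-rho)`; `"entropic"` for the ideal cost
#'   `sum(-log sigma)` scaled by `c`.
#' @return object of class `cost_spec`.
#' @export
cost_spec <- function(c = 0, rho = 2, lambda = 1e-4, s = 0.01,
                      reliability_form = c("power", "entropic")) {
  if (c < 0 || lambda < 0) stop_arg("c and lambda must be >= 0")
  if (rho <= 0 || s <= 0) stop_arg("rho and s must be > 0")
  structure(list(c = c, rho = rho, lambda = lambda, s = s,
                 reliability_form = match.arg(reliability_form)),
            class = "cost_spec")
}

#' Reliability-cost multiplier tangent to the entropy bound
#'
#' The choice `c = s^rho / rho` makes the power-law reliability cost touch
#' the entropic (ELBO) cost at `sigma = s`, avoiding large additive offsets
#' when comparing costs across exponents.
#'
#' @param rho power-law exponent (> 0).
#' @param s tangency scale (> 0), default 0.01.
#' @return the multiplier `c`.
#' @export
c_from_scale <- function(rho, s = 0.01) {
  if (any(rho <= 0) || any(s <= 0)) stop_arg("rho and s must be positive")
  s^rho / rho
}

#' Mean cross-entropy performance cost
#'
#' Mean over the batch of \eqn{-\log \mathrm{softmax}(z)_{y}} in nats.
#'
#' @param scores matrix of class scores (batch x classes) or a vector for a
#'   single example.
#' @param labels integer class ids in `0:(n_classes - 1)`.
#' @return non-negative scalar.
#' @export
performance_cost <- function(scores, labels) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (any(!is.finite(scores))) stop("non-finite class scores in performance cost")
  labels <- as.integer(labels)
  if (length(labels) != nrow(scores)) stop_arg("one label per score row required")
  if (any(labels < 0L) || any(labels >= ncol(scores))) {
    stop_arg("labels out of range")
  }
  lse <- row_logsumexp(scores)
  picked <- scores[cbind(seq_len(nrow(scores)), labels + 1L)]
  mean(lse - picked)
}

#' L1 magnitude cost on PSP means
#'
#' \eqn{\lambda \sum_i |\mu_i|}: large mean PSPs need more neurotransmitter,
#' higher release probability and more postsynaptic receptors.
#'
#' @param mu numeric vector (or list of matrices) of synaptic means.
#' @param lambda multiplier (>= 0).
#' @return scalar cost.
#' @export
magnitude_cost <- function(mu, lambda) {
  if (lambda < 0) stop_arg("lambda must be >= 0")
  if (is.list(mu)) mu <- unlist(mu, use.names = FALSE)
  lambda * sum(abs(mu))
}

#' Power-law reliability cost
#'
#' \eqn{c \sum_i \sigma_i^{-\rho}}: the energetic price of precise
#' transmission, strictly decreasing and convex in each \eqn{\sigma_i}.
#'
#' @param sigma vector of noise standard deviations (> 0).
#' @param c multiplier (>= 0).
#' @param rho exponent (> 0).
#' @return scalar cost.
#' @export
reliability_cost <- function(sigma, c, rho) {
  if (is.list(sigma)) sigma <- unlist(sigma, use.names = FALSE)
  if (any(sigma <= 0)) stop_arg("all sigma must be > 0")
  if (c < 0 || rho <= 0) stop_arg("need c >= 0 and rho > 0")
  c * sum(sigma^(-rho))
}

#' Entropic (ELBO) reliability cost
#'
#' The negative entropy of the Gaussian noise distribution up to its
#' additive constant: \eqn{\sum_i -\log \sigma_i}. This is the "ideal"
#' reliability cost that appears in the evidence lower bound; the
#' biophysical power-law costs upper-bound it (see [entropy_bound_gap()]).
#'
#' @param sigma vector of noise standard deviations (> 0).
#' @return scalar (can be negative).
#' @export
entropic_cost <- function(sigma) {
  if (is.list(sigma)) sigma <- unlist(sigma, use.names = FALSE)
  if (any(sigma <= 0)) stop_arg("all sigma must be > 0")
  sum(-log(sigma))
}

#' Gap between the power-law cost and the entropy bound
#'
#' For any \eqn{\sigma, \rho, s > 0},
#' \deqn{\frac{s^\rho}{\rho} \sigma^{-\rho} - \log s - \frac{1}{\rho}
#'       \;\ge\; -\log \sigma,}
#' an instance of \eqn{\log x \le x - 1} applied to
#' \eqn{x = (\sigma/s)^{-\rho}}, with equality exactly at \eqn{\sigma = s}.
#' This function returns the (non-negative) difference between the two
#' sides. Because of it, the overall training cost with `c = s^rho/rho`
#' upper-bounds the negative ELBO up to additive constants, so decreasing
#' the energetic objective tightens a variational bound.
#'
#' @param sigma noise standard deviation(s) (> 0, vectorised).
#' @param rho power-law exponent (> 0).
#' @param s tangency scale (> 0).
#' @return non-negative gap, zero iff `sigma == s`.
#' @export
entropy_bound_gap <- function(sigma, rho, s) {
  if (any(sigma <= 0) || any(rho <= 0) || any(s <= 0)) {
    stop_arg("sigma, rho, s must all be positive")
  }
  (s^rho / rho) * sigma^(-rho) - log(s) - 1 / rho + log(sigma)
}

#' Decompose the overall cost for one weight sample
#'
#' Evaluates the three objective terms on a batch and returns them with
#' their exact sum. The reliability term follows `spec$reliability_form`.
#'
#' @param scores class scores for the batch.
#' @param labels integer labels.
#' @param net the `synapse_params` whose parameters are being charged.
#' @param spec a [cost_spec()].
#' @return object of class `cost_breakdown`: list with `performance`,
#'   `magnitude`, `reliability`, `total`.
#' @export
cost_breakdown <- function(scores, labels, net, spec) {
  mu <- lapply(net$layers, `[[`, "mu")
  sigma <- lapply(seq_along(net$layers), function(l) layer_sigma(net, l))
  perf <- performance_cost(scores, labels)
  mag <- magnitude_cost(mu, spec$lambda)
  rel <- if (spec$reliability_form == "power") {
    reliability_cost(sigma, spec$c, spec$rho)
  } else {
    spec$c * entropic_cost(sigma)
  }
  structure(list(performance = perf, magnitude = mag, reliability = rel,
                 total = perf + mag + rel),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("cost: total %.6g = performance %.6g + magnitude %.6g + reliability %.6g\n",
              x$total, x$performance, x$magnitude, x$reliability))
  invisible(x)
}
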