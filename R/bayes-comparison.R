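#' Laplace posterior standard deviation from curvature
#'
#' The Laplace approximation places a Gaussian at the posterior mode with
#' variance equal to the inverse curvature, so per coordinate
#' \eqn{\sigma_{post} = H_{ii}^{-1/2}}. For an exactly quadratic
#' (Gaussian-likelihood) problem this is the exact posterior standard
#' deviation.
#'
#' @param H diagonal Hessian entries (> 0, vectorised).
#' @return posterior standard deviations.
#' @export
laplace_posterior_sd <- function(H) {
  if (any(H <= 0)) {
    stop_arg("Laplace variance requires positive curvature (H > 0)")
  }
  H^(-0.5)
}

#' Analytic energy-efficient noise level
#'
#' Expanding the performance cost to second order around the trained mean,
#' the expected objective in one synapse's noise is
#' \eqn{\tfrac12 H \sigma^2 + c \sigma^{-\rho}}, whose unique stationary
#' point is
#' \deqn{\sigma^* = \left(\frac{c\rho}{H}\right)^{1/(\rho+2)}.}
#' Decreasing in importance `H`, increasing in the cost multiplier `c`.
#'
#' @param H curvature / importance (> 0, vectorised).
#' @param c reliability-cost multiplier (> 0).
#' @param rho power-law exponent (> 0).
#' @return optimal noise standard deviations.
#' @export
analytic_sigma <- function(H, c, rho) {
  if (any(H <= 0) || any(c <= 0) || any(rho <= 0)) {
    stop_arg("H, c, rho must all be positive")
  }
  (c * rho / H)^(1 / (rho + 2))
}

#' Slope of efficient variability against posterior spread
#'
#' On log axes the analytic energy-efficient noise is linear in the Laplace
#' posterior standard deviation:
#' \eqn{\log\sigma^* = \mathrm{const} + \tfrac{2}{\rho+2}\log\sigma_{post}},
#' so the fitted slope equals \eqn{2/(\rho+2)} exactly. The slope is always
#' below one — optimised variability is less heterogeneous than posterior
#' spread — and approaches one as \eqn{\rho \to 0}, where the power-law
#' cost best mimics the entropic (ideal Bayesian) cost. Trained noise
#' levels can be supplied in place of the analytic ones, in which case the
#' fitted slope carries sampling error.
#'
#' @param H curvature values, at least 3, not all equal.
#' @param c reliability-cost multiplier.
#' @param rho power-law exponent.
#' @param sigma_trained optional empirically trained noise levels paired
#'   with `H`; default uses [analytic_sigma()].
#' @return object of class `slope_analysis`: list with `rho`, `c`, `slope`
#'   (fitted), `theoretical` (`2/(rho+2)`), and the per-synapse `pairs`
#'   data.frame (`log_sigma_post`, `log_sigma_eff`).
#' @export
sigma_vs_posterior_slope <- function(H, c, rho, sigma_trained = NULL) {
  if (length(H) < 3) stop_arg("need at least 3 curvature values")
  if (length(unique(H)) < 2) stop_arg("all curvatures equal: slope undefined")
  sd_post <- laplace_posterior_sd(H)
  sig <- if (is.null(sigma_trained)) analytic_sigma(H, c, rho) else sigma_trained
  if (length(sig) != length(H)) stop_arg("sigma_trained must pair with H")
  pairs <- data.frame(log_sigma_post = log(sd_post), log_sigma_eff = log(sig))
  slope <- unname(stats::coef(
    stats::lm(log_sigma_eff ~ log_sigma_post, data = pairs))[2])
  structure(list(rho = rho, c = c, slope = slope,
                 theoretical = 2 / (rho + 2), pairs = pairs),
            class = "slope_analysis")
}

#' @export
print.slope_analysis <- function(x, ...) {
  cat(sprintf("sigma vs posterior slope: fitted %.4f (theory 2/(rho+2) = %.4f) at rho = %.4g, c = %.4g\n",
              x$slope, x$theoretical, x$rho, x$c))
  invisible(x)
}

#' Mean-field variational posterior for a linear-Gaussian model
#'
#' Bayes-by-backprop baseline: fits a factorised Gaussian
#' \eqn{q(w) = \prod_i N(\mu_i, \sigma_i^2)} to the posterior of
#' \eqn{y \sim N(Xw, \tau^2 I)} with prior \eqn{w_i \sim N(0,
#' \sigma_{prior}^2)}, by maximising the evidence lower bound
#' \deqn{\mathrm{ELBO} = E_q[\log p(y \mid X w)] - KL(q \,\|\, p)}
#' via the reparameterisation trick and adaptive gradient steps. The
#' conjugate linear-Gaussian setting has a closed-form posterior, making
#' this the quantitative cross-check for the Laplace route used at network
#' scale.
#'
#' @param X design matrix (observations x weights).
#' @param y response vector.
#' @param noise_sd observation noise standard deviation \eqn{\tau} (known).
#' @param prior_sd prior standard deviation (default 1).
#' @param data_weight multiplier on the likelihood term; 0 recovers the
#'   prior exactly.
#' @param n_steps optimisation steps.
#' @param n_draws weight samples per gradient estimate.
#' @param eta_base,beta1,beta2,eps Adam constants.
#' @param tail_frac fraction of final steps over which the posterior scale
#'   is averaged, smoothing Monte-Carlo equilibrium jitter.
#' @param seed integer seed.
#' @return object of class `posterior_estimate`: list with `mean`, `sd`
#'   (tail-averaged), `method = "variational"`, `prior_sd`, and the
#'   per-step `elbo_path`.
#' @export
fit_variational_posterior <- function(X, y, noise_sd, prior_sd = 1,
                                      data_weight = 1, n_steps = 3000,
                                      n_draws = 8, eta_base = 0.02,
                                      beta1 = 0.9, beta2 = 0.99, eps = 1e-8,
                                      tail_frac = 0.25, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_arg("X rows must match length(y)")
  if (noise_sd <= 0 || prior_sd <= 0) stop_arg("noise_sd and prior_sd must be > 0")
  k <- ncol(X)
  tau2 <- noise_sd^2
  cfg <- list(eta_base = eta_base, beta1 = beta1, beta2 = beta2, eps = eps)
  with_local_seed(seed, {
    mu <- rep(0, k)
    phi <- rep(phi_from_sigma(prior_sd), k)
    st <- adam_state(list(mu = mu, phi = phi))
    elbo_path <- numeric(n_steps)
    sigma_path <- matrix(NA_real_, n_steps, k)
    mu_path <- matrix(NA_real_, n_steps, k)
    for (t in seq_len(n_steps)) {
      sigma <- sigma_from_phi(phi)
      xi <- matrix(stats::rnorm(n_draws * k), n_draws, k)
      W <- matrix(mu, n_draws, k, byrow = TRUE) +
        matrix(sigma, n_draws, k, byrow = TRUE) * xi
      R <- matrix(y, n_draws, length(y), byrow = TRUE) - W %*% t(X)
      # d log-lik / d w = X'(y - Xw)/tau2, one row per draw
      gl <- R %*% X / tau2
      loglik <- rowSums(-0.5 * R^2 / tau2 - 0.5 * log(2 * pi * tau2))
      kl <- sum(log(prior_sd / sigma) + (sigma^2 + mu^2) / (2 * prior_sd^2) - 0.5)
      elbo_path[t] <- data_weight * mean(loglik) - kl
      if (!is.finite(elbo_path[t])) {
        stop("variational fit diverged: non-finite ELBO at step ", t)
      }
      g_mu <- -data_weight * colMeans(gl) + mu / prior_sd^2
      g_sigma <- -data_weight * colMeans(gl * xi) +
        sigma / prior_sd^2 - 1 / sigma
      g_phi <- g_sigma * sigmoid(phi)
      up <- adam_update(st, list(mu = g_mu, phi = g_phi),
                        list(mu = mu, phi = phi), cfg, t)
      st <- up$state
      mu <- up$params$mu
      phi <- up$params$phi
      sigma_path[t, ] <- sigma_from_phi(phi)
      mu_path[t, ] <- mu
    }
    tail_rows <- max(1L, floor(tail_frac * n_steps))
    tail_idx <- (n_steps - tail_rows + 1L):n_steps
    structure(list(mean = colMeans(mu_path[tail_idx, , drop = FALSE]),
                   sd = colMeans(sigma_path[tail_idx, , drop = FALSE]),
                   method = "variational", prior_sd = prior_sd,
                   elbo_path = elbo_path),
              class = "posterior_estimate")
  })
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat(sprintf("%s posterior over %d weights; sd range [%.4g, %.4g]\n",
              x$method, length(x$sd), min(x$sd), max(x$sd)))
  invisible(x)
}
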