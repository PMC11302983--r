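#' Presynaptic biophysical parameters
#'
#' Parameters of the binomial quantal-release model and the calcium-release
#' coupling: `n` docked vesicles each release independently with probability
#' `p` on a presynaptic spike, each contributing a quantal postsynaptic
#' potential (PSP) of size `q`. Quantal size scales with vesicle volume,
#' `q = r^3` in arbitrary units with `r` the vesicle radius. Release
#' probability is coupled to intracellular calcium through a Hill equation
#' with half-saturation `K` and coefficient `m`.
#'
#' The default Hill coefficient `m = 4` reflects the steep cooperativity of
#' calcium-triggered release and is the value under which the calcium cost
#' scales exactly as \eqn{\sigma^{-1/2}}.
#'
#' @param n vesicle count (positive; real values allowed for sweeps).
#' @param p release probability in (0, 1).
#' @param q quantal PSP size (positive, mV-like units).
#' @param r vesicle radius (positive, arbitrary length units; `q` follows
#'   `r^3` in the constrained sweeps).
#' @param Ca intracellular calcium concentration (positive, arbitrary units).
#' @param K Hill half-saturation constant (same units as `Ca`).
#' @param m Hill coefficient (positive, dimensionless).
#' @return object of class `vesicle_params`.
#' @export
vesicle_params <- function(n = 10, p = 0.5, q = 1, r = 1, Ca = 1, K = 1, m = 4) {
  if (n <= 0 || q <= 0 || r <= 0 || Ca <= 0 || K <= 0 || m <= 0) {
    stop_arg("n, q, r, Ca, K, m must all be positive")
  }
  if (p <= 0 || p >= 1) stop_arg("p must lie strictly in (0, 1)")
  structure(list(n = n, p = p, q = q, r = r, Ca = Ca, K = K, m = m),
            class = "vesicle_params")
}

#' PSP mean and variance under binomial quantal release
#'
#' With `n` vesicles releasing independently with probability `p`, each of
#' quantal size `q`, the PSP mean and variance are
#' \deqn{\mu = n p q, \qquad \sigma^2 = n p (1 - p) q^2.}
#'
#' @param params a [vesicle_params()] object, or a list with fields `n`,
#'   `p`, `q` (vectorised over any of them).
#' @return list with elements `mu` and `var`.
#' @examples
#' psp_moments(list(n = 10, p = 0.5, q = 0.2)) # mu = 1, var = 0.1
#' @export
psp_moments <- function(params) {
  n <- params$n; p <- params$p; q <- params$q
  if (any(n < 0) || any(q < 0)) stop_arg("n and q must be non-negative")
  if (any(p < 0) || any(p > 1)) stop_arg("p must lie in [0, 1]")
  list(mu = n * p * q, var = n * p * (1 - p) * q^2)
}

#' Release probability from calcium via the Hill equation
#'
#' \deqn{p = \frac{Ca^m}{K^m + Ca^m}}
#' Monotone increasing in calcium, in \[0, 1).
#'
#' @param Ca calcium concentration (>= 0, vectorised).
#' @param K half-saturation constant (> 0).
#' @param m Hill coefficient (> 0).
#' @return release probability.
#' @export
hill_release_probability <- function(Ca, K, m) {
  if (any(Ca < 0)) stop_arg("Ca must be non-negative")
  if (K <= 0 || m <= 0) stop_arg("K and m must be positive")
  # (Ca/K)^m / (1 + (Ca/K)^m), stable for large Ca
  t <- (Ca / K)^m
  t / (1 + t)
}

# Invert the Hill relation: calcium needed for release probability p.
hill_calcium <- function(p, K, m) {
  if (any(p < 0) || any(p >= 1)) stop_arg("p must lie in [0, 1) to invert")
  K * (p / (1 - p))^(1 / m)
}

#' Energetic cost versus PSP reliability for one biophysical mechanism
#'
#' Sweeps one biophysical variable while re-solving the remaining free
#' variable so the PSP mean stays fixed at `mu_fix`, and records the
#' energetic cost of the configuration against the PSP standard deviation.
#' All proportionality constants are 1; costs are in arbitrary units. The
#' four mechanisms:
#'
#' * `"calcium"`: sweep release probability `p` (the grid); calcium pumped
#'   out after each spike costs `Ca = K (p/(1-p))^(1/m)`. The mean is held
#'   by adjusting quantal size at fixed vesicle count, under which
#'   `p/(1-p) = mu^2 / (n sigma^2)` exactly, so the cost is an exact power
#'   law in sigma with exponent `-2/m`.
#' * `"surface"`: sweep vesicle radius `r` (the grid) at fixed `p` with
#'   `q = r^3`; membrane surface cost `n r^2`, with `n = mu/(p r^3)`.
#' * `"actin"`: as surface, but cost is filament length `n r`.
#' * `"trafficking"`: as surface, but cost is vesicle count `n`.
#'
#' @param mechanism one of `"calcium"`, `"surface"`, `"actin"`,
#'   `"trafficking"`.
#' @param mu_fix the PSP mean held constant along the sweep (> 0).
#' @param sweep_grid strictly monotone grid of the swept variable
#'   (`p` for calcium, `r` otherwise). Defaults: `p` in \[0.9, 0.999\]
#'   (the high-reliability regime), `r` in \[0.5, 2\].
#' @param params a [vesicle_params()] supplying the fixed quantities.
#' @return object of class `cost_curve`: data.frame with columns
#'   `mechanism`, `sigma`, `cost`, `mu_fix` plus the swept variable.
#' @export
cost_curve <- function(mechanism = c("calcium", "surface", "actin", "trafficking"),
                       mu_fix = 1, sweep_grid = NULL,
                       params = vesicle_params()) {
  mechanism <- match.arg(mechanism)
  if (mu_fix <= 0) stop_arg("mu_fix must be positive")
  if (is.null(sweep_grid)) {
    sweep_grid <- if (mechanism == "calcium") {
      seq(0.9, 0.999, length.out = 50)
    } else {
      exp(seq(log(0.5), log(2), length.out = 50))
    }
  }
  d <- diff(sweep_grid)
  if (length(sweep_grid) < 2 || !(all(d > 0) || all(d < 0))) {
    stop_arg("sweep_grid must be strictly monotone with >= 2 points")
  }

  if (mechanism == "calcium") {
    p <- sweep_grid
    if (any(p <= 0) || any(p >= 1)) stop_arg("calcium sweep needs p in (0, 1)")
    n <- params$n
    q <- mu_fix / (n * p)        # quantal size absorbs the mean constraint
    cost <- hill_calcium(p, params$K, params$m)
    mom <- psp_moments(list(n = n, p = p, q = q))
    swept <- data.frame(p = p)
  } else {
    r <- sweep_grid
    if (any(r <= 0)) stop_arg("radius sweep must be positive")
    p <- params$p
    q <- r^3                      # vesicle volume sets quantal size
    n <- mu_fix / (p * q)
    if (any(n <= 0)) stop_arg("sweep implies non-physical vesicle count")
    cost <- switch(mechanism,
      surface = n * r^2,
      actin = n * r,
      trafficking = n
    )
    mom <- psp_moments(list(n = n, p = p, q = q))
    swept <- data.frame(r = r)
  }

  if (any(abs(mom$mu - mu_fix) > 1e-10 * mu_fix)) {
    stop("internal error: PSP mean drifted along the sweep")
  }
  out <- data.frame(
    mechanism = mechanism,
    sigma = sqrt(mom$var),
    cost = cost,
    mu_fix = mu_fix
  )
  out <- cbind(out, swept)
  class(out) <- c("cost_curve", "data.frame")
  out
}

#' Fit the power-law exponent of a cost curve
#'
#' Least-squares slope of `log(cost)` against `log(sigma)`. The constrained
#' mechanism curves are exact power laws, so the fit recovers the mechanism
#' exponent up to floating point: calcium \eqn{-1/2} (at Hill coefficient 4),
#' surface \eqn{-2/3}, actin \eqn{-4/3}, trafficking \eqn{-2}.
#'
#' @param curve a `cost_curve` (or any data.frame with positive `sigma` and
#'   `cost` columns and >= 3 rows).
#' @return list with `slope` (signed) and `rho_hat = -slope`.
#' @export
fit_power_exponent <- function(curve) {
  if (nrow(curve) < 3) stop_arg("need at least 3 points to fit an exponent")
  if (any(curve$sigma <= 0) || any(curve$cost <= 0)) {
    stop_arg("sigma and cost must be positive for a log-log fit")
  }
  fit <- stats::lm(log(cost) ~ log(sigma), data = curve)
  slope <- unname(stats::coef(fit)[2])
  list(slope = slope, rho_hat = -slope)
}

#' Write a cost curve to CSV
#'
#' @param curve a `cost_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cost_curve <- function(curve, path) {
  utils::write.csv(curve[c("mechanism", "sigma", "cost", "mu_fix")],
                   path, row.names = FALSE)
  invisible(path)
}
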