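# Internal numeric helpers shared across modules.

#' Softplus map from unconstrained noise parameter to standard deviation
#'
#' Synaptic noise is parameterised by an unconstrained real \eqn{\phi} with
#' \eqn{\sigma = \mathrm{softplus}(\phi) = \log(1 + e^{\phi})}, which keeps
#' \eqn{\sigma} strictly positive without clipping. Computed overflow-safely:
#' for large \eqn{\phi} the map is the identity plus an exponentially small
#' correction.
#'
#' @param phi numeric vector (any real values).
#' @return numeric vector of strictly positive standard deviations.
#' @examples
#' sigma_from_phi(0)    # log(2)
#' sigma_from_phi(50)   # ~50
#' @export
sigma_from_phi <- function(phi) {
  # log1p(exp(phi)) overflows for large phi; use max(phi, 0) + log1p(exp(-|phi|))
  pmax(phi, 0) + log1p(exp(-abs(phi)))
}

#' Inverse softplus
#'
#' Maps a positive standard deviation back to the unconstrained parameter
#' \eqn{\phi} such that `sigma_from_phi(phi) == sigma`. Used to initialise
#' \eqn{\phi} from a requested starting noise level.
#'
#' @param sigma numeric vector of positive values.
#' @return numeric vector of unconstrained parameters.
#' @export
phi_from_sigma <- function(sigma) {
  stopifnot(all(sigma > 0))
  # log(exp(sigma) - 1), stable for small sigma via expm1 and for large via
  # sigma + log(1 - exp(-sigma))
  ifelse(sigma > 30, sigma, log(expm1(sigma)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise log-sum-exp, numerically shifted.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators are pure functions of their
# arguments.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_arg <- function(...) stop(..., call. = FALSE)
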