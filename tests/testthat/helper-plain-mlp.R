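# Independent plain (deterministic-weight) MLP used as an oracle for the
# zero-noise limit of the stochastic network. Written separately from the
# package internals on purpose: forward, backward and Adam are re-derived
# here from scratch.

plain_forward <- function(x, W, b) {
  a <- x
  L <- length(W)
  for (l in seq_len(L)) {
    z <- a %*% W[[l]] - matrix(b[[l]], nrow(a), length(b[[l]]), byrow = TRUE)
    a <- if (l < L) z * (z > 0) else z
  }
  a
}

plain_softmax_ce <- function(scores, labels) {
  mx <- apply(scores, 1, max)
  lse <- mx + log(rowSums(exp(scores - mx)))
  mean(lse - scores[cbind(seq_len(nrow(scores)), labels + 1L)])
}

# Minimal Adam MLP trainer over a precomputed batch schedule.
plain_train <- function(W, b, x_all, y_all, schedule,
                        eta = 5e-3, beta1 = 0.9, beta2 = 0.99, eps = 1e-8) {
  L <- length(W)
  zeros <- function(p) lapply(p, function(m) m * 0)
  mW <- zeros(W); vW <- zeros(W); mB <- zeros(b); vB <- zeros(b)
  t <- 0
  for (idx in schedule) {
    t <- t + 1
    x <- x_all[idx, , drop = FALSE]
    y <- y_all[idx]
    A <- vector("list", L + 1); Z <- vector("list", L)
    A[[1]] <- x
    for (l in seq_len(L)) {
      Z[[l]] <- A[[l]] %*% W[[l]] -
        matrix(b[[l]], nrow(x), length(b[[l]]), byrow = TRUE)
      A[[l + 1]] <- if (l < L) Z[[l]] * (Z[[l]] > 0) else Z[[l]]
    }
    sc <- A[[L + 1]]
    p <- exp(sc - apply(sc, 1, max))
    p <- p / rowSums(p)
    D <- p
    D[cbind(seq_len(nrow(x)), y + 1L)] <- D[cbind(seq_len(nrow(x)), y + 1L)] - 1
    D <- D / nrow(x)
    for (l in rev(seq_len(L))) {
      gW <- t(A[[l]]) %*% D
      gb <- -colSums(D)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gb
      vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gb^2
      if (l > 1) D <- (D %*% t(W[[l]])) * (Z[[l - 1]] > 0)
      W[[l]] <- W[[l]] - eta * (mW[[l]] / (1 - beta1^t)) /
        (sqrt(vW[[l]] / (1 - beta2^t)) + eps)
      b[[l]] <- b[[l]] - eta * (mB[[l]] / (1 - beta1^t)) /
        (sqrt(vB[[l]] / (1 - beta2^t)) + eps)
    }
  }
  list(W = W, b = b)
}
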