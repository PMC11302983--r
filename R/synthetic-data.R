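#' Synthetic classification tasks with heterogeneous input rates
#'
#' Generates a multi-class task that emulates the structure the network
#' experiments rely on: non-negative features bounded in \[0, 1\], class
#' structure learnable by a small multilayer perceptron, and per-feature mean
#' activation ("input rate") spanning several orders of magnitude. The last
#' property mirrors pixel statistics of handwritten-digit images, where
#' border pixels are almost always dark and central pixels bright, and it is
#' what the input-rate diagnostics depend on.
#'
#' Each class has a Gaussian template over features; a sample is its class
#' template plus within-class Gaussian jitter, clipped to \[0, 1\], then
#' multiplied by a per-feature rate scale drawn log-uniformly from
#' \eqn{[10^{-h}, 1]} where `h = rate_heterogeneity`. With `h = 0` all
#' features share the same scale and column means differ only by sampling
#' error.
#'
#' @param n_classes integer >= 2, number of classes.
#' @param n_features integer >= 2, feature dimension.
#' @param n_samples integer >= `n_classes`, total samples across splits.
#' @param rate_heterogeneity non-negative real; decades spanned by the
#'   per-feature rate scale. Default 3, matching the several-decade spread of
#'   per-pixel mean intensities in digit images.
#' @param seed integer; fixes all randomness. The generator is a pure
#'   function of its arguments.
#' @param split fractions for train/validation/test, summing to 1.
#' @return an object of class `synapse_dataset`: list with `features`
#'   (n_samples x n_features matrix in \[0, 1\]), `labels` (integer class ids
#'   in `0:(n_classes - 1)`), `split` (factor with levels train/val/test),
#'   `rate_scale` (the planted per-feature scales), `n_classes`.
#' @export
make_classification_task <- function(n_classes, n_features, n_samples,
                                     rate_heterogeneity = 3, seed = 1,
                                     split = c(train = 0.8, val = 0.1, test = 0.1)) {
  if (n_classes < 2 || n_features < 2 || n_samples < n_classes) {
    stop_arg("need n_classes >= 2, n_features >= 2, n_samples >= n_classes")
  }
  if (rate_heterogeneity < 0) stop_arg("rate_heterogeneity must be >= 0")
  if (abs(sum(split) - 1) > 1e-8) stop_arg("split fractions must sum to 1")

  with_local_seed(seed, {
    templates <- matrix(stats::runif(n_classes * n_features, 0.15, 0.85),
                        n_classes, n_features)
    rate_scale <- 10^stats::runif(n_features, -rate_heterogeneity, 0)
    labels <- as.integer((seq_len(n_samples) - 1L) %% n_classes)
    labels <- sample(labels)
    jitter <- matrix(stats::rnorm(n_samples * n_features, sd = 0.12),
                     n_samples, n_features)
    x <- templates[labels + 1L, , drop = FALSE] + jitter
    x <- pmin(pmax(x, 0), 1)
    x <- sweep(x, 2L, rate_scale, `*`)

    n_train <- floor(split[[1]] * n_samples)
    n_val <- floor(split[[2]] * n_samples)
    tags <- rep(c("train", "val", "test"),
                c(n_train, n_val, n_samples - n_train - n_val))
    ds <- list(
      features = x,
      labels = labels,
      split = factor(tags, levels = c("train", "val", "test")),
      rate_scale = rate_scale,
      n_classes = as.integer(n_classes)
    )
    class(ds) <- "synapse_dataset"
    ds
  })
}

#' @export
print.synapse_dataset <- function(x, ...) {
  cat(sprintf("synthetic classification task: %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), x$n_classes))
  cat("splits:", paste(sprintf("%s=%d", levels(x$split), table(x$split)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Subset a dataset to one split
#'
#' @param dataset a `synapse_dataset`.
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @return a `synapse_dataset` restricted to the requested split.
#' @export
dataset_split <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  keep <- dataset$split == which
  out <- dataset
  out$features <- dataset$features[keep, , drop = FALSE]
  out$labels <- dataset$labels[keep]
  out$split <- dataset$split[keep]
  out
}

#' Diagonal quadratic toy problem with known Hessian
#'
#' A loss surface \eqn{L(w) = \sum_i \tfrac12 h_i (w_i - w^*_i)^2} whose
#' Hessian is exactly `diag(h_values)`. Curvature `h_i` plays the role of
#' synapse importance: deviations on a high-curvature coordinate are costly.
#' Used to validate the trainer against the analytic stationary noise level
#' and to ground the Fisher/posterior comparisons where everything has a
#' closed form.
#'
#' @param h_values positive curvatures, one per synapse.
#' @param w_star optimum weights (defaults to zeros).
#' @param seed optional integer stored for downstream sampling.
#' @return object of class `quadratic_toy` with fields `h`, `w_star`,
#'   and functions `loss(w)` and `grad(w)`.
#' @export
make_quadratic_toy <- function(h_values, w_star = rep(0, length(h_values)),
                               seed = NULL) {
  if (any(h_values <= 0)) stop_arg("all curvatures h must be > 0")
  if (length(w_star) != length(h_values)) {
    stop_arg("w_star and h_values must have the same length")
  }
  h <- as.numeric(h_values)
  ws <- as.numeric(w_star)
  toy <- list(
    h = h,
    w_star = ws,
    seed = seed,
    loss = function(w) sum(0.5 * h * (w - ws)^2),
    grad = function(w) h * (w - ws)
  )
  class(toy) <- "quadratic_toy"
  toy
}

#' Read images and labels in IDX binary format
#'
#' Optional loader for real digit images stored in the classic IDX format
#' (big-endian, magic numbers `0x00000803` for image tensors and
#' `0x00000801` for label vectors). Pixels are rescaled from \[0, 255\] to
#' \[0, 1\]. Never required by the rest of the package; all experiments run
#' on [make_classification_task()] data.
#'
#' @param images_path path to the IDX image file.
#' @param labels_path path to the IDX label file.
#' @param split fractions for train/val/test tags, summing to 1.
#' @return a `synapse_dataset` (see [make_classification_task()]).
#' @export
load_idx_images <- function(images_path, labels_path,
                            split = c(train = 0.8, val = 0.1, test = 0.1)) {
  read_u32 <- function(con) {
    v <- readBin(con, "integer", n = 1L, size = 4L, endian = "big", signed = TRUE)
    if (length(v) != 1L) stop_arg("truncated IDX file")
    v
  }
  con <- file(images_path, "rb"); on.exit(close(con), add = TRUE)
  magic <- read_u32(con)
  if (magic != 2051L) stop_arg("bad IDX magic number in image file: ", magic)
  n_img <- read_u32(con); nr <- read_u32(con); nc <- read_u32(con)
  npx <- n_img * nr * nc
  px <- readBin(con, "integer", n = npx, size = 1L, signed = FALSE)
  if (length(px) != npx) stop_arg("truncated IDX image file")

  con2 <- file(labels_path, "rb"); on.exit(close(con2), add = TRUE)
  magic2 <- read_u32(con2)
  if (magic2 != 2049L) stop_arg("bad IDX magic number in label file: ", magic2)
  n_lab <- read_u32(con2)
  if (n_lab != n_img) {
    stop_arg("image/label count mismatch: ", n_img, " images vs ", n_lab, " labels")
  }
  lab <- readBin(con2, "integer", n = n_lab, size = 1L, signed = FALSE)
  if (length(lab) != n_lab) stop_arg("truncated IDX label file")

  x <- matrix(px / 255, nrow = n_img, ncol = nr * nc, byrow = TRUE)
  n_train <- floor(split[[1]] * n_img)
  n_val <- floor(split[[2]] * n_img)
  tags <- rep(c("train", "val", "test"), c(n_train, n_val, n_img - n_train - n_val))
  ds <- list(
    features = x,
    labels = as.integer(lab),
    split = factor(tags, levels = c("train", "val", "test")),
    rate_scale = NULL,
    n_classes = length(unique(lab))
  )
  class(ds) <- "synapse_dataset"
  ds
}
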