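# Small shared fixtures, built in code at test time.

tiny_task <- function(seed = 11) {
  make_classification_task(n_classes = 3, n_features = 20, n_samples = 400,
                           rate_heterogeneity = 2, seed = seed)
}

tiny_net_config <- function() network_config(widths = c(20, 8, 8, 3))

ci_task <- function(seed = 11) {
  make_classification_task(n_classes = 4, n_features = 100, n_samples = 4000,
                           rate_heterogeneity = 3, seed = seed)
}

ci_net_config <- function() network_config(widths = c(100, 32, 32, 4))

ci_train_config <- function(seed = 2, ...) {
  train_config(eta_base = 5e-3, epochs = 30, beta2 = 0.99, seed = seed, ...)
}

# Write a matching IDX image/label fixture pair; images is a list of
# equally-sized integer matrices (0..255 pixel values).
write_idx_fixture <- function(images, labels, dir = tempfile("idx")) {
  dir.create(dir)
  img_path <- file.path(dir, "images.idx")
  lab_path <- file.path(dir, "labels.idx")
  nr <- nrow(images[[1]]); nc <- ncol(images[[1]])
  con <- file(img_path, "wb")
  writeBin(c(2051L, length(images), nr, nc), con, size = 4L, endian = "big")
  for (im in images) {
    writeBin(as.raw(as.integer(t(im))), con)
  }
  close(con)
  con <- file(lab_path, "wb")
  writeBin(c(2049L, length(labels)), con, size = 4L, endian = "big")
  writeBin(as.raw(as.integer(labels)), con)
  close(con)
  list(images = img_path, labels = lab_path)
}
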