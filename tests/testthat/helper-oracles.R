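# Independent oracles used across the suite. These deliberately avoid the
# package's backward-pass code paths: losses are computed from the forward
# pass alone and gradients by central finite differences.

softmax_ref <- function(z) {
  ez <- exp(z - max(z))
  ez / sum(ez)
}

# Softmax cross-entropy loss of a network on one example, from the forward
# pass only.
loss_at <- function(params, x, target) {
  a_n <- forward(params, x)$activations[[length(params$weights)]]
  -log(sum(softmax_ref(a_n) * target))
}

# Central finite differences of the loss with respect to every weight.
finite_diff_grads <- function(params, x, target, h = 1e-5) {
  lapply(seq_along(params$weights), function(l) {
    W <- params$weights[[l]]
    G <- W * 0
    for (i in seq_len(nrow(W))) {
      for (j in seq_len(ncol(W))) {
        up <- params; up$weights[[l]][i, j] <- W[i, j] + h
        dn <- params; dn$weights[[l]][i, j] <- W[i, j] - h
        G[i, j] <- (loss_at(up, x, target) - loss_at(dn, x, target)) / (2 * h)
      }
    }
    G
  })
}

# Central finite differences of the loss with respect to the pre-activation
# y_l, by injecting an additive bump at that layer in a re-implemented
# forward pass.
finite_diff_preact_grad <- function(params, x, target, layer, h = 1e-5) {
  forward_bumped <- function(bump) {
    a <- x
    for (l in seq_along(params$weights)) {
      y <- drop(params$weights[[l]] %*% a)
      if (l == layer) y <- y + bump
      a <- apply_activation(params$specs[[l]]$activation, y)
    }
    -log(sum(softmax_ref(a) * target))
  }
  width <- params$specs[[layer]]$fan_out
  vapply(seq_len(width), function(i) {
    bump <- numeric(width)
    bump[i] <- h; up <- forward_bumped(bump)
    bump[i] <- -h; dn <- forward_bumped(bump)
    (up - dn) / (2 * h)
  }, numeric(1))
}

# A random small architecture (depth <= 3, widths <= 6) with smooth
# activations, suitable for finite-difference checks.
random_small_specs <- function(seed) {
  withr::with_seed(seed, {
    depth <- sample(1:3, 1)
    widths <- sample(2:6, depth + 1, replace = TRUE)
    network_spec(widths, hidden = sample(c("tanh", "sigmoid"), 1))
  })
}

random_one_hot <- function(k, seed) {
  withr::with_seed(seed, {
    t <- numeric(k)
    t[sample.int(k, 1)] <- 1
    t
  })
}

# Nearest-class-mean classification accuracy on the test split of a cluster
# task (uses the generator's stored means, not the trainer).
nearest_mean_accuracy <- function(task) {
  means <- task$meta$class_means
  X <- task$features[task$test_idx, , drop = FALSE]
  truth <- max.col(task$labels[task$test_idx, , drop = FALSE])
  d2 <- outer(rowSums(X^2), rowSums(means^2), "+") - 2 * X %*% t(means)
  mean(max.col(-d2) == truth)
}

# Tiny IDX fixture writers (big-endian MNIST container format).
write_idx_images <- function(path, images) {
  # images: list of equal-size integer matrices with values 0..255
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- dim(images[[1]])
  writeBin(c(2051L, length(images), dims[1], dims[2]), con, size = 4,
           endian = "big")
  for (img in images) {
    writeBin(as.raw(as.vector(t(img))), con)
  }
  invisible(path)
}

write_idx_labels <- function(path, labels) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(2049L, length(labels)), con, size = 4, endian = "big")
  writeBin(as.raw(labels), con)
  invisible(path)
}
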