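#' One-hot encode integer class labels
#'
#' @param labels Integer vector of class indices in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return An `n x n_classes` 0/1 matrix with a single 1 per row.
#' @export
one_hot <- function(labels, n_classes) {
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > n_classes)) {
    stop("labels out of range 1..n_classes", call. = FALSE)
  }
  Y <- matrix(0, nrow = length(labels), ncol = n_classes)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

new_task <- function(features, labels, train_idx, test_idx, meta) {
  structure(
    list(features = features, labels = labels, train_idx = train_idx,
         test_idx = test_idx, meta = meta),
    class = "synthetic_task"
  )
}

#' @export
print.synthetic_task <- function(x, ...) {
  cat(sprintf("<synthetic_task> %s: %d samples x %d features, %d classes (%d train / %d test)\n",
              x$meta$kind, nrow(x$features), ncol(x$features),
              ncol(x$labels), length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

split_task <- function(n, train_fraction) {
  if (train_fraction <= 0 || train_fraction > 1) {
    stop("train_fraction must lie in (0, 1]", call. = FALSE)
  }
  idx <- sample.int(n)
  n_train <- max(1L, floor(n * train_fraction))
  list(train = sort(idx[seq_len(n_train)]),
       test = if (n_train < n) sort(idx[seq(n_train + 1L, n)]) else integer(0))
}

#' Gaussian-cluster classification task
#'
#' Places `n_classes` class means at mutually separated points (scaled
#' orthonormal directions) and draws each sample as its class mean plus
#' isotropic Gaussian noise of scale `noise_scale`. Class labels are
#' balanced within one sample. `margin` is the distance from each class mean
#' to its nearest midpoint decision boundary, so pairwise mean distances are
#' `2 * margin` and all exceed `margin`. The difficulty is governed by the
#' margin-to-noise ratio: the noise projected on any inter-mean direction
#' has standard deviation `noise_scale`, so at a ratio of 6 a sample sits 6
#' noise standard deviations from the nearest boundary and the task is
#' linearly separable for practical purposes.
#'
#' @param n_samples Total samples (train + test).
#' @param n_features Feature dimension; must be at least `n_classes` so that
#'   mutually separated means exist.
#' @param n_classes Number of classes, at least 2.
#' @param margin Distance from each class mean to the nearest decision
#'   boundary (half the pairwise mean distance), positive.
#' @param noise_scale Isotropic noise standard deviation, nonnegative.
#' @param seed Integer seed; the task is a pure function of its arguments.
#' @param train_fraction Fraction of samples in the training split
#'   (default 5/6, a 5:1 split).
#' @return A `synthetic_task`: `features` (matrix), `labels` (one-hot
#'   matrix), `train_idx`, `test_idx`, and generator metadata.
#' @examples
#' task <- make_cluster_task(120, 20, 4, margin = 6, noise_scale = 1, seed = 1)
#' table(max.col(task$labels))
#' @export
make_cluster_task <- function(n_samples, n_features, n_classes, margin,
                              noise_scale, seed,
                              train_fraction = 5 / 6) {
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (margin <= 0) stop("margin must be positive", call. = FALSE)
  if (noise_scale < 0) stop("noise_scale must be nonnegative", call. = FALSE)
  if (n_features < n_classes) {
    stop(sprintf(
      "cannot pack %d mutually separated class means in %d dimensions",
      n_classes, n_features), call. = FALSE)
  }
  if (n_samples < n_classes) stop("need at least one sample per class",
                                  call. = FALSE)
  out <- withr::with_seed(as.integer(seed), {
    # Orthonormal directions scaled so every pairwise mean distance is
    # 2 * margin, putting each mean `margin` away from the midpoint boundary.
    Q <- qr.Q(qr(matrix(stats::rnorm(n_features * n_classes), n_features,
                        n_classes)))
    means <- t(Q) * (margin * sqrt(2))
    y <- sample(rep_len(seq_len(n_classes), n_samples))
    X <- means[y, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * n_features, sd = noise_scale),
             n_samples, n_features)
    sp <- split_task(n_samples, train_fraction)
    list(X = X, y = y, split = sp, means = means)
  })
  new_task(out$X, one_hot(out$y, n_classes), out$split$train, out$split$test,
           meta = list(kind = "clusters", class_count = n_classes,
                       feature_count = n_features, margin = margin,
                       noise_scale = noise_scale, seed = as.integer(seed),
                       class_means = out$means))
}

#' Teacher-network classification task
#'
#' Labels uniform random inputs on `[-1, 1]^d` by the argmax output of a
#' frozen, randomly initialized teacher network, so the decision boundary is
#' exactly realizable by a student of the teacher's architecture. If the
#' teacher is degenerate (some class never wins the argmax) the inputs are
#' resampled, up to `max_retries` times, before failing.
#'
#' @param teacher_specs A [network_spec()] for the teacher.
#' @param n_samples Total samples.
#' @param seed Integer seed (controls teacher weights and inputs).
#' @param train_fraction Fraction of samples in the training split.
#' @param max_retries Input resampling attempts before erroring on a
#'   degenerate teacher.
#' @return A `synthetic_task`; `meta$teacher` holds the frozen teacher
#'   parameters.
#' @export
make_teacher_task <- function(teacher_specs, n_samples, seed,
                              train_fraction = 5 / 6, max_retries = 20L) {
  specs <- validate_specs(teacher_specs)
  d <- specs[[1]]$fan_in
  n_classes <- specs[[length(specs)]]$fan_out
  teacher <- init_weights(specs, seed = as.integer(seed))
  for (attempt in seq_len(max_retries)) {
    out <- withr::with_seed(as.integer(seed) + attempt, {
      X <- matrix(stats::runif(n_samples * d, min = -1, max = 1), n_samples, d)
      scores <- forward_batch(teacher, X)$activations[[length(specs)]]
      y <- max.col(scores, ties.method = "first")
      list(X = X, y = y, split = split_task(n_samples, train_fraction))
    })
    if (length(unique(out$y)) == n_classes) {
      return(new_task(out$X, one_hot(out$y, n_classes), out$split$train,
                      out$split$test,
                      meta = list(kind = "teacher", class_count = n_classes,
                                  feature_count = d, seed = as.integer(seed),
                                  teacher = teacher)))
    }
  }
  stop(sprintf(
    "degenerate teacher: some class never wins the argmax after %d input resamples",
    max_retries), call. = FALSE)
}

read_idx_header <- function(con, path, expected_magic) {
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (length(magic) != 1L || is.na(magic) || magic != expected_magic) {
    stop(sprintf("%s: bad IDX magic number (expected %d, got %s)", path,
                 expected_magic,
                 if (length(magic)) format(magic) else "EOF"), call. = FALSE)
  }
  n_dims <- expected_magic %% 256L
  dims <- readBin(con, "integer", n = n_dims, size = 4, endian = "big")
  if (length(dims) != n_dims || any(is.na(dims)) || any(dims < 0)) {
    stop(sprintf("%s: truncated IDX dimension header", path), call. = FALSE)
  }
  dims
}

#' Read an MNIST-style IDX image/label file pair
#'
#' Parses the big-endian IDX binary format (magic 0x00000803 = 2051 for
#' unsigned-byte image tensors, 0x00000801 = 2049 for label vectors),
#' flattens each image to a feature vector scaled to `[0, 1]` (byte / 255),
#' and one-hot encodes the labels. Image and label counts must agree.
#'
#' @param images_path Path to the images file.
#' @param labels_path Path to the labels file.
#' @param n_classes Number of classes for one-hot encoding (default 10).
#' @param train_fraction Fraction of samples assigned to the training split.
#' @param seed Seed for the train/test split.
#' @return A `synthetic_task` with `meta$kind == "idx"`.
#' @export
read_idx <- function(images_path, labels_path, n_classes = 10L,
                     train_fraction = 5 / 6, seed = 1L) {
  con <- file(images_path, "rb"); on.exit(close(con), add = TRUE)
  dims <- read_idx_header(con, images_path, 2051L)
  if (length(dims) < 2L) {
    stop(sprintf("%s: image file must have at least 2 dimensions", images_path),
         call. = FALSE)
  }
  n <- dims[1]
  px <- prod(dims[-1])
  raw_px <- readBin(con, "integer", n = n * px, size = 1, signed = FALSE)
  if (length(raw_px) != n * px) {
    stop(sprintf("%s: truncated IDX payload (expected %d bytes, got %d)",
                 images_path, n * px, length(raw_px)), call. = FALSE)
  }
  con2 <- file(labels_path, "rb"); on.exit(close(con2), add = TRUE)
  ldims <- read_idx_header(con2, labels_path, 2049L)
  if (ldims[1] != n) {
    stop(sprintf("%s: label count %d does not match image count %d",
                 labels_path, ldims[1], n), call. = FALSE)
  }
  raw_lab <- readBin(con2, "integer", n = n, size = 1, signed = FALSE)
  if (length(raw_lab) != n) {
    stop(sprintf("%s: truncated IDX payload (expected %d labels, got %d)",
                 labels_path, n, length(raw_lab)), call. = FALSE)
  }
  if (any(raw_lab >= n_classes)) {
    stop(sprintf("%s: label byte exceeds n_classes - 1", labels_path),
         call. = FALSE)
  }
  X <- matrix(raw_px / 255, nrow = n, ncol = px, byrow = TRUE)
  sp <- withr::with_seed(as.integer(seed), split_task(n, train_fraction))
  new_task(X, one_hot(raw_lab + 1L, n_classes), sp$train, sp$test,
           meta = list(kind = "idx", class_count = as.integer(n_classes),
                       feature_count = px, images_path = images_path,
                       labels_path = labels_path, seed = as.integer(seed)))
}
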