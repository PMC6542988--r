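#' Describe one fully connected layer
#'
#' @param fan_in Positive integer, input width.
#' @param fan_out Positive integer, output width (number of neurons).
#' @param activation Activation kind, see [ACTIVATION_KINDS].
#' @return An object of class `layer_spec`.
#' @examples
#' layer_spec(784, 400, "tanh")
#' @export
layer_spec <- function(fan_in, fan_out, activation = "tanh") {
  if (!is.numeric(fan_in) || length(fan_in) != 1L || is.na(fan_in) ||
      fan_in != round(fan_in) || fan_in <= 0) {
    stop("fan_in must be a positive integer, got ", format(fan_in),
         call. = FALSE)
  }
  if (!is.numeric(fan_out) || length(fan_out) != 1L || is.na(fan_out) ||
      fan_out != round(fan_out) || fan_out <= 0) {
    stop("fan_out must be a positive integer, got ", format(fan_out),
         call. = FALSE)
  }
  structure(
    list(fan_in = as.integer(fan_in), fan_out = as.integer(fan_out),
         activation = check_activation(activation)),
    class = "layer_spec"
  )
}

#' @export
print.layer_spec <- function(x, ...) {
  cat(sprintf("<layer_spec> %d -> %d (%s)\n", x$fan_in, x$fan_out,
              x$activation))
  invisible(x)
}

#' Build a fully connected architecture from layer widths
#'
#' Convenience constructor: `network_spec(c(784, 400, 10))` is a 784-400-10
#' network with tanh hidden layers and a linear output layer (the softmax is
#' applied by the loss, see [output_error()]).
#'
#' @param sizes Integer vector of layer widths, length >= 2; the first entry
#'   is the input dimension, the last the number of classes.
#' @param hidden Activation kind for hidden layers.
#' @param output Activation kind for the output layer. The default `"linear"`
#'   pairs with softmax cross-entropy, so the output error is exactly
#'   `softmax(y_n) - target`.
#' @return A list of [layer_spec()] objects, class `network_spec`.
#' @examples
#' network_spec(c(784, 400, 10))
#' @export
network_spec <- function(sizes, hidden = "tanh", output = "linear") {
  if (length(sizes) < 2L) stop("need at least input and output widths",
                               call. = FALSE)
  n <- length(sizes) - 1L
  specs <- lapply(seq_len(n), function(l) {
    layer_spec(sizes[l], sizes[l + 1L],
               if (l < n) hidden else output)
  })
  structure(specs, class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  sizes <- c(x[[1]]$fan_in, vapply(x, function(s) s$fan_out, integer(1)))
  cat("<network_spec> ", paste(sizes, collapse = "-"), "\n", sep = "")
  for (s in x) print(s)
  invisible(x)
}

validate_specs <- function(specs) {
  if (inherits(specs, "layer_spec")) specs <- list(specs)
  if (!length(specs)) stop("empty architecture", call. = FALSE)
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "layer_spec")) {
      s <- layer_spec(s$fan_in, s$fan_out, s$activation)
    }
    s
  })
  for (l in seq_along(specs)[-1]) {
    if (specs[[l]]$fan_in != specs[[l - 1L]]$fan_out) {
      stop(sprintf(
        "layer specs do not chain: layer %d has fan_in %d but layer %d has fan_out %d",
        l, specs[[l]]$fan_in, l - 1L, specs[[l - 1L]]$fan_out), call. = FALSE)
    }
  }
  specs
}

#' Uniform initialization bound for a layer
#'
#' Half-width `c` of the uniform initialization interval `[-c, c]` as a
#' function of the layer fan-out. Two rules are built in: the scaled
#' `1/sqrt(fan_out)` (default) and the literal `1/fan_out`.
#'
#' @param fan_out Positive integer.
#' @param init `"inv_sqrt_fan_out"` or `"inv_fan_out"`.
#' @return A positive scalar.
#' @export
init_bound <- function(fan_out, init = c("inv_sqrt_fan_out", "inv_fan_out")) {
  init <- match.arg(init)
  switch(init,
    inv_sqrt_fan_out = 1 / sqrt(fan_out),
    inv_fan_out      = 1 / fan_out
  )
}

#' Initialize forward weights
#'
#' Each weight matrix `W_l` (shape `fan_out x fan_in`) is drawn i.i.d. uniform
#' on `[-c_l, c_l]` with `c_l` given by [init_bound()] applied to the layer's
#' fan-out. The draw is a pure function of `seed`.
#'
#' @param specs A [network_spec()] or list of [layer_spec()]s that chain.
#' @param seed Integer seed fixing the random stream.
#' @param init Initialization rule, see [init_bound()].
#' @return An object of class `network_params` holding `weights` (a list of
#'   matrices) and the validated `specs`.
#' @examples
#' p <- init_weights(network_spec(c(4, 3, 2)), seed = 1)
#' sapply(p$weights, dim)
#' @export
init_weights <- function(specs, seed,
                         init = c("inv_sqrt_fan_out", "inv_fan_out")) {
  specs <- validate_specs(specs)
  init <- match.arg(init)
  weights <- withr::with_seed(as.integer(seed), {
    lapply(specs, function(s) {
      b <- init_bound(s$fan_out, init)
      matrix(stats::runif(s$fan_out * s$fan_in, min = -b, max = b),
             nrow = s$fan_out, ncol = s$fan_in)
    })
  })
  structure(
    list(weights = weights, specs = specs, init = init,
         seed = as.integer(seed)),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  sizes <- c(x$specs[[1]]$fan_in,
             vapply(x$specs, function(s) s$fan_out, integer(1)))
  cat("<network_params> ", paste(sizes, collapse = "-"),
      ", ", sum(vapply(x$weights, length, numeric(1))), " weights\n", sep = "")
  invisible(x)
}

n_layers <- function(params) length(params$weights)

#' Forward pass of a fully connected network
#'
#' Computes `y_l = W_l a_{l-1}` (with `a_0 = x`) and `a_l = f(y_l)` for every
#' layer, retaining all intermediates for the backward pass.
#'
#' @param params A [init_weights()] result (or any `network_params`).
#' @param x Numeric input vector of length equal to the first layer's fan-in.
#' @return An object of class `forward_trace` with fields `input`,
#'   `preactivations` (list of `y_l`), `activations` (list of `a_l`) and
#'   `specs`.
#' @examples
#' p <- init_weights(network_spec(c(4, 3, 2)), seed = 1)
#' tr <- forward(p, c(1, 0, -1, 0.5))
#' tr$activations[[2]]
#' @export
forward <- function(params, x) {
  stopifnot(inherits(params, "network_params"))
  x <- as.numeric(x)
  if (length(x) != params$specs[[1]]$fan_in) {
    stop(sprintf("input length %d does not match fan_in %d", length(x),
                 params$specs[[1]]$fan_in), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite input", call. = FALSE)
  n <- n_layers(params)
  preacts <- vector("list", n)
  acts <- vector("list", n)
  a_prev <- x
  for (l in seq_len(n)) {
    y <- drop(params$weights[[l]] %*% a_prev)
    a <- apply_activation(params$specs[[l]]$activation, y)
    preacts[[l]] <- y
    acts[[l]] <- a
    a_prev <- a
  }
  structure(
    list(input = x, preactivations = preacts, activations = acts,
         specs = params$specs),
    class = "forward_trace"
  )
}

#' @export
print.forward_trace <- function(x, ...) {
  widths <- vapply(x$activations, length, integer(1))
  cat("<forward_trace> input length ", length(x$input), ", layer widths ",
      paste(widths, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Batched forward pass over a matrix of row-vector inputs (internal fast path
# for training). Returns lists of n_obs x width matrices; element [[0+l]]
# corresponds to layer l.
forward_batch <- function(params, X) {
  n <- n_layers(params)
  preacts <- vector("list", n)
  acts <- vector("list", n)
  A <- X
  for (l in seq_len(n)) {
    Y <- A %*% t(params$weights[[l]])
    A <- apply_activation(params$specs[[l]]$activation, Y)
    preacts[[l]] <- Y
    acts[[l]] <- A
  }
  list(preactivations = preacts, activations = acts)
}
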