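#' Credit-assignment rules
#'
#' `"BP"` backpropagates errors through transposed forward weights; `"DFA"`
#' feeds the output error directly to every hidden layer through a fixed dense
#' random matrix; `"SDFA"` does the same through a sparse feedback matrix
#' (SSDFA is the extreme case of one nonzero per row). SDFA with a fully
#' dense feedback matrix reproduces DFA exactly.
#'
#' @format A character vector of rule names.
#' @export
CREDIT_RULES <- c("BP", "DFA", "SDFA")

# Numerically stable softmax over a vector, or rowwise over a matrix.
softmax <- function(z) {
  if (is.matrix(z)) {
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    ez / rowSums(ez)
  } else {
    z <- z - max(z)
    ez <- exp(z)
    ez / sum(ez)
  }
}

check_one_hot <- function(target) {
  target <- as.numeric(target)
  if (any(!target %in% c(0, 1)) || sum(target) != 1) {
    stop("target must be a one-hot vector", call. = FALSE)
  }
  target
}

#' Output-layer error under softmax cross-entropy
#'
#' The classification error at the last layer is
#' `e = softmax(a_n) - target`, which is exactly the gradient of
#' softmax cross-entropy with respect to the output pre-activations when the
#' output layer is linear. No activation-derivative gate is applied at the
#' output layer; all three credit rules set the last-layer error signal to
#' `e` verbatim.
#'
#' @param a_n Numeric vector of output-layer activations (logits under the
#'   default linear output layer).
#' @param target One-hot numeric vector of the same length.
#' @return Numeric error vector `e`; its components sum to zero.
#' @examples
#' output_error(c(0, 0, 0), c(0, 1, 0))
#' @export
output_error <- function(a_n, target) {
  a_n <- as.numeric(a_n)
  target <- check_one_hot(target)
  if (length(a_n) != length(target)) {
    stop("output and target lengths differ", call. = FALSE)
  }
  softmax(a_n) - target
}

new_error_signals <- function(deltas, e) {
  structure(list(deltas = deltas, output_error = e), class = "error_signals")
}

#' @export
print.error_signals <- function(x, ...) {
  widths <- vapply(x$deltas, length, integer(1))
  cat("<error_signals> layer widths ", paste(widths, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Backpropagated error signals
#'
#' Computes `delta_n = e` and, recursing towards the input,
#' `delta_l = W_{l+1}^T delta_{l+1} * f'(a_l)` — each hidden layer needs the
#' transposed weights of the layer immediately downstream (the weight
#' transport problem). The resulting `delta_l` is the gradient of the loss
#' with respect to the layer's pre-activation `y_l`.
#'
#' @param params `network_params` used in the forward pass.
#' @param trace The [forward()] trace.
#' @param e Output error from [output_error()].
#' @return An `error_signals` object: `deltas` (list, one vector per layer)
#'   and `output_error`.
#' @export
bp_errors <- function(params, trace, e) {
  stopifnot(inherits(params, "network_params"), inherits(trace, "forward_trace"))
  n <- n_layers(params)
  e <- as.numeric(e)
  if (length(e) != params$specs[[n]]$fan_out) {
    stop("output error length does not match output width", call. = FALSE)
  }
  deltas <- vector("list", n)
  deltas[[n]] <- e
  if (n > 1L) {
    for (l in seq(n - 1L, 1L)) {
      fp <- activation_derivative_from_output(params$specs[[l]]$activation,
                                              trace$activations[[l]])
      deltas[[l]] <- drop(crossprod(params$weights[[l + 1L]],
                                    deltas[[l + 1L]])) * fp
    }
  }
  new_error_signals(deltas, e)
}

#' Direct-feedback-alignment error signals
#'
#' Computes `delta_n = e` and, for every hidden layer independently,
#' `delta_l = B_l e * f'(a_l)`. No forward weight and no other layer's error
#' signal is read: the signature takes only the fixed feedback matrices, so
#' each hidden layer's error depends on `B_l`, `e` and its own activations
#' alone. The same routine serves SDFA; sparsity lives in `B_l`.
#'
#' @param feedbacks List of feedback matrices (or [generate_feedback()]
#'   results), one per hidden layer, each of shape `width_l x length(e)`.
#' @param trace The [forward()] trace.
#' @param e Output error vector.
#' @return An `error_signals` object.
#' @export
dfa_errors <- function(feedbacks, trace, e) {
  stopifnot(inherits(trace, "forward_trace"))
  n <- length(trace$activations)
  e <- as.numeric(e)
  if (length(e) != length(trace$activations[[n]])) {
    stop("output error length does not match output width", call. = FALSE)
  }
  if (n > 1L && (is.null(feedbacks) || length(feedbacks) < n - 1L)) {
    stop("missing feedback matrix for a hidden layer", call. = FALSE)
  }
  deltas <- vector("list", n)
  deltas[[n]] <- e
  if (n > 1L) {
    for (l in seq_len(n - 1L)) {
      B <- feedback_values(feedbacks[[l]])
      if (is.null(B)) {
        stop(sprintf("missing feedback matrix for hidden layer %d", l),
             call. = FALSE)
      }
      if (ncol(B) != length(e) || nrow(B) != length(trace$activations[[l]])) {
        stop(sprintf("feedback matrix for layer %d has shape %dx%d, expected %dx%d",
                     l, nrow(B), ncol(B), length(trace$activations[[l]]),
                     length(e)), call. = FALSE)
      }
      fp <- activation_derivative_from_output(trace$specs[[l]]$activation,
                                              trace$activations[[l]])
      deltas[[l]] <- drop(B %*% e) * fp
    }
  }
  new_error_signals(deltas, e)
}

#' Per-neuron error under sparse direct feedback
#'
#' For neuron `i` of hidden layer `l` the error is
#' `(b_row . e) * f'(a_li)`. When the row holds a single nonzero `B_lij`
#' this collapses to the product of three scalars `B_lij * e_j * f'(a_li)`,
#' and the computation touches only `e_j`. The sparse path iterates over the
#' structural nonzeros only; the returned scalar carries an attribute
#' `"macs"` recording one multiply-accumulate per nonzero (the final gate
#' multiply is reported separately as attribute `"extra_mults"` = 1).
#'
#' @param b_row Numeric feedback row (mostly zeros).
#' @param e Output error vector of the same length.
#' @param a_li Scalar activation output of the neuron.
#' @param kind Activation kind of the layer.
#' @return Scalar error with attributes `macs` (= number of nonzeros in
#'   `b_row`) and `extra_mults` (= 1).
#' @examples
#' sdfa_neuron_error(c(0, 0.5, 0), c(0.1, -0.2, 0.3), a_li = 0.7, kind = "linear")
#' @export
sdfa_neuron_error <- function(b_row, e, a_li, kind) {
  b_row <- as.numeric(b_row)
  e <- as.numeric(e)
  if (length(b_row) != length(e)) {
    stop("feedback row and error vector lengths differ", call. = FALSE)
  }
  nz <- which(b_row != 0)
  acc <- 0
  for (j in nz) acc <- acc + b_row[j] * e[j]
  out <- acc * activation_derivative_from_output(kind, a_li)
  attr(out, "macs") <- length(nz)
  attr(out, "extra_mults") <- 1L
  out
}

#' Weight gradients from error signals
#'
#' Assembles the outer-product gradient `dW_l = delta_l %o% a_{l-1}` (with
#' `a_0 = x`) for every layer. Under BP error signals this is the full
#' gradient of the softmax cross-entropy loss with respect to the weights.
#'
#' @param trace The [forward()] trace.
#' @param errors An `error_signals` object.
#' @return List of gradient matrices shaped like the weight matrices.
#' @export
weight_gradients <- function(trace, errors) {
  stopifnot(inherits(trace, "forward_trace"), inherits(errors, "error_signals"))
  n <- length(trace$activations)
  if (length(errors$deltas) != n) {
    stop("error signals do not match trace depth", call. = FALSE)
  }
  lapply(seq_len(n), function(l) {
    a_prev <- if (l == 1L) trace$input else trace$activations[[l - 1L]]
    if (length(errors$deltas[[l]]) != length(trace$preactivations[[l]])) {
      stop(sprintf("delta for layer %d has wrong length", l), call. = FALSE)
    }
    tcrossprod(errors$deltas[[l]], a_prev)
  })
}

#' SGD update configuration
#'
#' @param learning_rate Positive step size.
#' @param decay Multiplicative per-epoch decay factor in `(0, 1]`; the
#'   effective rate after `k` epochs is `learning_rate * decay^k`.
#' @param seed Integer seed for any stochastic component of training.
#' @return An object of class `update_config`.
#' @export
update_config <- function(learning_rate, decay = 1, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be positive", call. = FALSE)
  }
  if (!is.numeric(decay) || decay <= 0 || decay > 1) {
    stop("decay must lie in (0, 1]", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, decay = decay,
                 seed = as.integer(seed)),
            class = "update_config")
}

#' One SGD step
#'
#' Applies `W_l <- W_l - learning_rate * decay^epoch * dW_l` to the forward
#' weights. Feedback matrices are never touched: feedback is fixed for the
#' life of the network.
#'
#' @param params `network_params` to update.
#' @param grads List of gradient matrices from [weight_gradients()].
#' @param cfg An [update_config()].
#' @param epoch Nonnegative integer epoch index (0 = no decay applied).
#' @return Updated `network_params`.
#' @export
sgd_step <- function(params, grads, cfg, epoch = 0L) {
  stopifnot(inherits(params, "network_params"), inherits(cfg, "update_config"))
  if (length(grads) != n_layers(params)) {
    stop("gradient list does not match layer count", call. = FALSE)
  }
  rate <- cfg$learning_rate * cfg$decay^epoch
  for (l in seq_along(grads)) {
    g <- grads[[l]]
    if (any(!is.finite(g))) {
      stop(sprintf("non-finite gradient at layer %d", l), call. = FALSE)
    }
    if (!all(dim(g) == dim(params$weights[[l]]))) {
      stop(sprintf("gradient shape mismatch at layer %d", l), call. = FALSE)
    }
    params$weights[[l]] <- params$weights[[l]] - rate * g
  }
  params
}
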