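#' Supported activation functions
#'
#' The four elementwise activations available for network layers. Each kind
#' provides both the forward map `f` and a derivative expressed as a function
#' of the activation *output* `a` (not the pre-activation), which is the form
#' the backward passes consume.
#'
#' @format A character vector of activation names.
#' @export
ACTIVATION_KINDS <- c("tanh", "relu", "sigmoid", "linear")

check_activation <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L || is.na(kind) ||
      !kind %in% ACTIVATION_KINDS) {
    stop("unknown activation kind: ", paste(format(kind), collapse = ", "),
         "; must be one of ", paste(ACTIVATION_KINDS, collapse = ", "),
         call. = FALSE)
  }
  kind
}

#' Apply an activation function elementwise
#'
#' @param kind One of `"tanh"`, `"relu"`, `"sigmoid"`, `"linear"`.
#' @param y Numeric vector or matrix of pre-activations.
#' @return `f(y)`, same shape as `y`.
#' @examples
#' apply_activation("relu", c(-1, 0, 2))
#' @export
apply_activation <- function(kind, y) {
  switch(check_activation(kind),
    tanh    = tanh(y),
    relu    = pmax(y, 0),
    sigmoid = 1 / (1 + exp(-y)),
    linear  = y
  )
}

#' Activation derivative evaluated from the activation output
#'
#' Returns `f'` expressed as a function of `a = f(y)`: for tanh `1 - a^2`,
#' for sigmoid `a (1 - a)`, for relu `1` where `a > 0` and `0` elsewhere
#' (the derivative at exactly 0 is defined as 0), and `1` for linear.
#' All backward rules gate error signals with this quantity.
#'
#' @param kind One of `"tanh"`, `"relu"`, `"sigmoid"`, `"linear"`.
#' @param a Numeric vector or matrix of activation outputs.
#' @return `f'(a)`, same shape as `a`.
#' @examples
#' activation_derivative_from_output("tanh", 0)      # 1
#' activation_derivative_from_output("sigmoid", 0.5) # 0.25
#' @export
activation_derivative_from_output <- function(kind, a) {
  switch(check_activation(kind),
    tanh    = 1 - a^2,
    relu    = (a > 0) + 0,
    sigmoid = a * (1 - a),
    linear  = a * 0 + 1
  )
}
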