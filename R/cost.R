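#' Per-layer architecture counts for the cost model
#'
#' Derives, for a fully connected architecture, the word counts the cost
#' model consumes: `weight_count` |W|, `neuron_count` |A|, dense feedback
#' size `feedback_count` |B|, sparse feedback nonzeros `feedback_nnz` |b|,
#' the output error width `error_count` |E|, the per-neuron reduced error
#' count `reduced_error_count` |e| under sparse feedback, and the width of
#' the error vector arriving from downstream `downstream_error_count`
#' (the next layer's width, or |E| for the output layer). Hidden layers
#' carry a feedback matrix; the output layer receives the error directly, so
#' its |B| and |b| are 0. Under sparse feedback every neuron receives
#' `feedback_nnz_per_row` error words (so dense `nnz = |E|` reproduces the
#' DFA accounting exactly, and `nnz = 1` is the single-error extreme). Conv or
#' other layer types can be costed by supplying a counts table of the same
#' shape directly to [layer_costs()].
#'
#' @param specs A [network_spec()] or chaining list of [layer_spec()]s.
#' @param feedback_nnz_per_row Structural nonzeros per feedback row under
#'   SDFA (1 = SSDFA). Dense DFA always uses the full `error_count`.
#' @return A tibble with one row per layer.
#' @examples
#' architecture_counts(network_spec(c(784, 100, 10)))
#' @export
architecture_counts <- function(specs, feedback_nnz_per_row = 1L) {
  specs <- validate_specs(specs)
  nnz <- as.integer(feedback_nnz_per_row)
  if (nnz < 1L) stop("feedback_nnz_per_row must be >= 1", call. = FALSE)
  n <- length(specs)
  E <- specs[[n]]$fan_out
  if (nnz > E) stop("feedback_nnz_per_row cannot exceed the error count",
                    call. = FALSE)
  tibble::tibble(
    layer = seq_len(n),
    weight_count = vapply(specs, function(s) as.numeric(s$fan_in) * s$fan_out,
                          numeric(1)),
    neuron_count = vapply(specs, function(s) as.numeric(s$fan_out), numeric(1)),
    feedback_count = ifelse(seq_len(n) < n,
                            vapply(specs, function(s) as.numeric(s$fan_out),
                                   numeric(1)) * E, 0),
    feedback_nnz = ifelse(seq_len(n) < n,
                          vapply(specs, function(s) as.numeric(s$fan_out),
                                 numeric(1)) * nnz, 0),
    error_count = E,
    reduced_error_count = nnz,
    downstream_error_count = c(vapply(specs, function(s) as.numeric(s$fan_out),
                                      numeric(1))[-1], E)
  )
}

check_counts <- function(counts) {
  needed <- c("weight_count", "neuron_count", "feedback_count", "feedback_nnz",
              "error_count", "reduced_error_count", "downstream_error_count")
  missing <- setdiff(needed, names(counts))
  if (length(missing)) {
    stop("counts table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) {
    v <- counts[[col]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("counts column '%s' must be nonnegative and finite", col),
           call. = FALSE)
    }
  }
  counts
}

#' Per-layer cost of one training example under a credit rule
#'
#' Applies the per-layer accounting of reads, writes, multiply-accumulates
#' and data movement (words a neuron must send or receive per weight update):
#'
#' * BP:   reads `|W|+|A|`, writes `|W|`, MACs `2|W|`,
#'   movement `|W|+|A|+|E_downstream|` (weights and activations shuttle to
#'   and from main memory in a von Neumann realization).
#' * DFA:  reads `|W|+|B|`, writes `|W|`, MACs `|W|+|B|`,
#'   movement `|E|` words received per neuron, totalling `|A| * |E|`.
#' * SDFA: reads `|W|+|b|`, writes `|W|`, MACs `|W|+|b|`,
#'   movement `|e|` words per neuron, totalling `|A| * |e|`.
#'
#' @param counts A per-layer counts table from [architecture_counts()] (or a
#'   hand-built one for non-FC layers).
#' @param rule One of `"BP"`, `"DFA"`, `"SDFA"`.
#' @return A `cost_report` tibble: per-layer `reads`, `writes`, `macs`,
#'   `movement` plus the `rule`. Use [cost_totals()] to collapse it.
#' @examples
#' layer_costs(architecture_counts(network_spec(c(784, 100, 10))), "BP")
#' @export
layer_costs <- function(counts, rule = c("BP", "DFA", "SDFA")) {
  rule <- match.arg(rule)
  counts <- check_counts(tibble::as_tibble(counts))
  out <- switch(rule,
    BP = dplyr::mutate(counts,
      reads = .data$weight_count + .data$neuron_count,
      writes = .data$weight_count,
      macs = 2 * .data$weight_count,
      movement = .data$weight_count + .data$neuron_count +
        .data$downstream_error_count),
    DFA = dplyr::mutate(counts,
      reads = .data$weight_count + .data$feedback_count,
      writes = .data$weight_count,
      macs = .data$weight_count + .data$feedback_count,
      movement = .data$neuron_count * .data$error_count),
    SDFA = dplyr::mutate(counts,
      reads = .data$weight_count + .data$feedback_nnz,
      writes = .data$weight_count,
      macs = .data$weight_count + .data$feedback_nnz,
      movement = .data$neuron_count * .data$reduced_error_count)
  )
  out <- dplyr::mutate(out, rule = rule)
  class(out) <- c("cost_report", class(out))
  out
}

#' Total training-example cost for a fully connected architecture
#'
#' Derives [architecture_counts()] from the layer dimensions and sums
#' [layer_costs()] over layers.
#'
#' @inheritParams architecture_counts
#' @param rule One of `"BP"`, `"DFA"`, `"SDFA"`.
#' @return A `cost_report` tibble (per-layer rows; see [cost_totals()]).
#' @examples
#' cost_totals(network_costs(network_spec(c(9216, 4096, 4096, 1000)), "SDFA"))
#' @export
network_costs <- function(specs, rule = c("BP", "DFA", "SDFA"),
                          feedback_nnz_per_row = 1L) {
  layer_costs(architecture_counts(specs, feedback_nnz_per_row),
              match.arg(rule))
}

#' Collapse a per-layer cost report to totals
#'
#' @param report A `cost_report` from [layer_costs()] or [network_costs()].
#' @return One-row tibble with `rule` and summed `reads`, `writes`, `macs`,
#'   `movement`.
#' @export
cost_totals <- function(report) {
  stopifnot(inherits(report, "cost_report"))
  dplyr::summarise(tibble::as_tibble(report),
    rule = .data$rule[1],
    reads = sum(.data$reads), writes = sum(.data$writes),
    macs = sum(.data$macs), movement = sum(.data$movement)
  )
}

#' Reduction factor between two cost reports
#'
#' The ratio `total(a) / total(b)` for one cost field — e.g. BP movement over
#' SSDFA movement. `format_reduction()` renders it at two significant
#' figures, the precision at which headline factors such as "6,400x" are
#' quoted.
#'
#' @param a,b `cost_report`s (numerator and denominator).
#' @param field One of `"reads"`, `"writes"`, `"macs"`, `"movement"`.
#' @return A positive real ratio.
#' @examples
#' arch <- network_spec(c(9216, 4096, 4096, 1000))
#' reduction_factor(network_costs(arch, "BP"), network_costs(arch, "SDFA"),
#'                  "movement")
#' @export
reduction_factor <- function(a, b,
                             field = c("movement", "macs", "reads", "writes")) {
  field <- match.arg(field)
  num <- cost_totals(a)[[field]]
  den <- cost_totals(b)[[field]]
  if (den == 0) stop(sprintf("reduction factor undefined: denominator %s is 0",
                             field), call. = FALSE)
  num / den
}

#' @rdname reduction_factor
#' @param x A numeric ratio.
#' @export
format_reduction <- function(x) {
  paste0(format(signif(x, 2), big.mark = ",", scientific = FALSE), "x")
}
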