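# Rowwise softmax cross-entropy loss and accuracy for a batch of logits.
evaluate_metrics <- function(params, X, Y) {
  Z <- forward_batch(params, X)$activations[[n_layers(params)]]
  Zs <- Z - apply(Z, 1, max)
  logp <- Zs - log(rowSums(exp(Zs)))
  list(
    accuracy = mean(max.col(Z, ties.method = "first") ==
                      max.col(Y, ties.method = "first")),
    loss = -mean(rowSums(Y * logp))
  )
}

hidden_angles <- function(params, feedbacks) {
  n <- n_layers(params)
  if (n < 2L || is.null(feedbacks)) return(numeric(0))
  vapply(seq_len(n - 1L), function(l) {
    alignment_angle(feedbacks[[l]], params$weights[seq(l + 1L, n)])
  }, numeric(1))
}

default_feedbacks <- function(specs, rule, seed) {
  n <- length(specs)
  if (rule == "BP" || n < 2L) return(NULL)
  M <- specs[[n]]$fan_out
  lapply(seq_len(n - 1L), function(l) {
    N <- specs[[l]]$fan_out
    if (rule == "DFA") {
      generate_feedback(feedback_spec(N, M, rank = min(N, M), sparsity = 0,
                                      seed = seed + l))
    } else {
      generate_ssdfa(N, M, seed = seed + l)
    }
  })
}

#' Train a fully connected network under BP, DFA or SDFA
#'
#' Runs mini-batch SGD with softmax cross-entropy. The forward pass is the
#' same under every rule; the error signals are backpropagated through
#' transposed forward weights (BP) or delivered directly through fixed random
#' feedback matrices (DFA dense, SDFA sparse). Per-example weight gradients
#' are averaged over each mini-batch, and the learning rate decays
#' multiplicatively per epoch. The run is a pure function of its arguments:
#' the same configuration and seed reproduce the metric stream exactly.
#'
#' @param task A `synthetic_task` (see [make_cluster_task()],
#'   [make_teacher_task()], [read_idx()]).
#' @param specs A [network_spec()]; the first fan-in must equal the task's
#'   feature count and the last fan-out its class count.
#' @param rule `"BP"`, `"DFA"` or `"SDFA"`.
#' @param feedbacks Optional list of feedback matrices (one per hidden
#'   layer). If `NULL`, DFA gets dense full-rank matrices and SDFA gets
#'   single-connection (SSDFA) matrices, both seeded from `seed`.
#' @param cfg An [update_config()] (learning rate, decay).
#' @param epochs Number of full passes over the training split. `epochs = 0`
#'   records only the initial evaluation.
#' @param batch_size Mini-batch size.
#' @param seed Integer root seed for initialization, feedback generation and
#'   shuffling.
#' @param init Weight-initialization rule, see [init_bound()].
#' @param track_angles Record the alignment angle of each hidden layer's
#'   feedback against its downstream weight product each epoch (only
#'   meaningful for DFA/SDFA).
#' @return An object of class `sdfa_fit`: final `params`, the `feedbacks`,
#'   a `history` tibble (one row per epoch including epoch 0, with columns
#'   `epoch`, `train_accuracy`, `test_accuracy`, `train_loss`, `mean_angle`
#'   and per-layer `angle_<l>` columns), and the resolved configuration.
#' @examples
#' task <- make_cluster_task(240, 20, 4, margin = 6, noise_scale = 1, seed = 1)
#' fit <- train_network(task, network_spec(c(20, 16, 4)), rule = "SDFA",
#'                      cfg = update_config(0.1), epochs = 3, seed = 1)
#' glance(fit)
#' @export
train_network <- function(task, specs, rule = c("BP", "DFA", "SDFA"),
                          feedbacks = NULL, cfg = update_config(0.05),
                          epochs = 10L, batch_size = 50L, seed = 1L,
                          init = c("inv_sqrt_fan_out", "inv_fan_out"),
                          track_angles = TRUE) {
  rule <- match.arg(rule)
  init <- match.arg(init)
  stopifnot(inherits(task, "synthetic_task"), inherits(cfg, "update_config"))
  specs <- validate_specs(specs)
  n <- length(specs)
  if (specs[[1]]$fan_in != ncol(task$features)) {
    stop("first layer fan_in does not match the task feature count",
         call. = FALSE)
  }
  if (specs[[n]]$fan_out != ncol(task$labels)) {
    stop("output width does not match the task class count", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.null(feedbacks)) feedbacks <- default_feedbacks(specs, rule, seed + 1L)
  if (rule != "BP" && n > 1L) {
    if (length(feedbacks) != n - 1L) {
      stop("need one feedback matrix per hidden layer", call. = FALSE)
    }
    for (l in seq_len(n - 1L)) {
      B <- feedback_values(feedbacks[[l]])
      if (nrow(B) != specs[[l]]$fan_out || ncol(B) != specs[[n]]$fan_out) {
        stop(sprintf("feedback matrix %d has shape %dx%d, expected %dx%d", l,
                     nrow(B), ncol(B), specs[[l]]$fan_out, specs[[n]]$fan_out),
             call. = FALSE)
      }
      uncovered <- which(colSums(B != 0) == 0L)
      if (length(uncovered)) {
        warning(sprintf(
          "feedback matrix %d leaves error column(s) %s unconnected; those errors will never be propagated backwards",
          l, paste(uncovered, collapse = ", ")), call. = FALSE)
      }
    }
  }

  params <- init_weights(specs, seed = seed, init = init)
  Xtr <- task$features[task$train_idx, , drop = FALSE]
  Ytr <- task$labels[task$train_idx, , drop = FALSE]
  has_test <- length(task$test_idx) > 0L
  Xte <- task$features[task$test_idx, , drop = FALSE]
  Yte <- task$labels[task$test_idx, , drop = FALSE]
  ntr <- nrow(Xtr)
  B_list <- if (rule != "BP") lapply(feedbacks, feedback_values)

  record <- function(epoch) {
    tr <- evaluate_metrics(params, Xtr, Ytr)
    te <- if (has_test) evaluate_metrics(params, Xte, Yte) else
      list(accuracy = NA_real_, loss = NA_real_)
    ang <- if (track_angles && rule != "BP") hidden_angles(params, feedbacks)
    else numeric(0)
    row <- tibble::tibble(epoch = epoch, train_accuracy = tr$accuracy,
                          test_accuracy = te$accuracy, train_loss = tr$loss,
                          mean_angle = if (length(ang)) mean(ang) else NA_real_)
    if (length(ang)) {
      for (l in seq_along(ang)) row[[paste0("angle_", l)]] <- ang[l]
    }
    row
  }

  history <- list(record(0L))
  if (epochs > 0L) {
    withr::with_seed(seed + 2L, {
      for (epoch in seq_len(epochs)) {
        rate <- cfg$learning_rate * cfg$decay^(epoch - 1L)
        ord <- sample.int(ntr)
        starts <- seq(1L, ntr, by = batch_size)
        for (s in starts) {
          idx <- ord[s:min(s + batch_size - 1L, ntr)]
          Xb <- Xtr[idx, , drop = FALSE]
          Yb <- Ytr[idx, , drop = FALSE]
          fb <- forward_batch(params, Xb)
          A <- fb$activations
          E <- softmax(A[[n]]) - Yb
          D <- vector("list", n)
          D[[n]] <- E
          if (n > 1L) {
            for (l in seq(n - 1L, 1L)) {
              fp <- activation_derivative_from_output(
                specs[[l]]$activation, A[[l]])
              D[[l]] <- if (rule == "BP") {
                (D[[l + 1L]] %*% params$weights[[l + 1L]]) * fp
              } else {
                (E %*% t(B_list[[l]])) * fp
              }
            }
          }
          nb <- length(idx)
          for (l in seq_len(n)) {
            A_prev <- if (l == 1L) Xb else A[[l - 1L]]
            G <- crossprod(D[[l]], A_prev) / nb
            if (any(!is.finite(G))) {
              stop(sprintf("training diverged: non-finite gradient at epoch %d, layer %d",
                           epoch, l), call. = FALSE)
            }
            params$weights[[l]] <- params$weights[[l]] - rate * G
          }
        }
        history[[epoch + 1L]] <- record(epoch)
      }
    })
  }

  structure(
    list(params = params, feedbacks = feedbacks, rule = rule,
         history = dplyr::bind_rows(history),
         config = list(rule = rule, learning_rate = cfg$learning_rate,
                       decay = cfg$decay, epochs = as.integer(epochs),
                       batch_size = as.integer(batch_size), seed = seed,
                       init = init,
                       sizes = c(specs[[1]]$fan_in,
                                 vapply(specs, function(s) s$fan_out,
                                        integer(1))))),
    class = "sdfa_fit"
  )
}

#' @export
print.sdfa_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<sdfa_fit> %s, %s net, %d epochs\n", x$rule,
              paste(x$config$sizes, collapse = "-"), x$config$epochs))
  cat(sprintf("  final train accuracy %.3f, test accuracy %.3f\n",
              last$train_accuracy, last$test_accuracy))
  if (!is.na(last$mean_angle)) {
    cat(sprintf("  mean alignment angle %.1f degrees\n", last$mean_angle))
  }
  invisible(x)
}

#' Predict classes or probabilities from a trained network
#'
#' @param object An `sdfa_fit`.
#' @param newdata Feature matrix (rows = samples).
#' @param type `"class"` (integer class indices) or `"prob"` (softmax
#'   probabilities).
#' @param ... Unused.
#' @return Integer vector or probability matrix.
#' @export
predict.sdfa_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Z <- forward_batch(object$params,
                     as.matrix(newdata))$activations[[n_layers(object$params)]]
  if (type == "class") max.col(Z, ties.method = "first") else softmax(Z)
}

#' @rdname sdfa_fit_tidiers
#' @export
tidy.sdfa_fit <- function(x, ...) x$history

#' Tidiers for trained networks
#'
#' `tidy()` returns the per-epoch metrics history; `glance()` a one-row
#' summary of the final state.
#'
#' @param x An `sdfa_fit`.
#' @param ... Unused.
#' @name sdfa_fit_tidiers
#' @export
glance.sdfa_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    rule = x$rule, epochs = x$config$epochs,
    train_accuracy = last$train_accuracy,
    test_accuracy = last$test_accuracy,
    train_loss = last$train_loss,
    mean_angle = last$mean_angle,
    n_parameters = sum(vapply(x$params$weights, length, numeric(1)))
  )
}

#' Plot a training history
#'
#' Accuracy (train and test) against epoch; when alignment angles were
#' tracked, a second panel shows the mean angle trajectory.
#'
#' @param object An `sdfa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdfa_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           cols = c("train_accuracy", "test_accuracy"),
                           names_to = "split", values_to = "accuracy")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$accuracy,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("%s training", object$rule),
                  x = "epoch", y = "accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Rank/sparsity sweep over feedback-matrix constraints
#'
#' Trains one SDFA network per feasible `(rank, sparsity, repeat)` cell, all
#' from deterministically enumerated seeds, and records the final test
#' accuracy and alignment angles. Infeasible cells
#' (`rank * (1 - sparsity) < 1`, or a per-row support that rounds to zero)
#' are recorded as skipped with the reason and are never trained.
#'
#' @param task A `synthetic_task`.
#' @param specs A [network_spec()].
#' @param ranks Integer vector of feedback ranks to sweep.
#' @param sparsities Numeric vector of sparsity fractions in `[0, 1)`.
#' @param repeats Simulations per cell (seeds enumerate from `seed`).
#' @param cfg An [update_config()].
#' @param epochs,batch_size Passed to [train_network()].
#' @param seed Root seed.
#' @return A tibble of class `sdfa_sweep`, one row per cell per repeat:
#'   `rank`, `sparsity`, `seed`, `feasible`, `reason`,
#'   `final_test_accuracy`, `mean_angle`. Aggregate with
#'   [aggregate_sweep()].
#' @export
sweep_rank_sparsity <- function(task, specs, ranks, sparsities, repeats = 3L,
                                cfg = update_config(0.05), epochs = 5L,
                                batch_size = 50L, seed = 1L) {
  stopifnot(length(ranks) > 0L, length(sparsities) > 0L, repeats >= 1L)
  specs <- validate_specs(specs)
  n <- length(specs)
  M <- specs[[n]]$fan_out
  grid <- expand.grid(rank = ranks, sparsity = sparsities,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  any_feasible <- FALSE
  for (cell in seq_len(nrow(grid))) {
    R <- as.integer(grid$rank[cell]); S <- grid$sparsity[cell]
    fspec <- tryCatch(
      feedback_spec(specs[[1]]$fan_out, M, rank = R, sparsity = S,
                    seed = seed),
      error = function(e) conditionMessage(e))
    if (is.character(fspec)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rank = R, sparsity = S, seed = NA_integer_, feasible = FALSE,
        reason = fspec, final_test_accuracy = NA_real_,
        mean_angle = NA_real_)
      next
    }
    any_feasible <- TRUE
    for (rep in seq_len(repeats)) {
      cell_seed <- as.integer(seed) + 97L * cell + rep
      feedbacks <- lapply(seq_len(n - 1L), function(l) {
        generate_feedback(feedback_spec(specs[[l]]$fan_out, M, rank = R,
                                        sparsity = S, seed = cell_seed + 7L * l))
      })
      fit <- train_network(task, specs, rule = "SDFA", feedbacks = feedbacks,
                           cfg = cfg, epochs = epochs, batch_size = batch_size,
                           seed = cell_seed)
      last <- fit$history[nrow(fit$history), ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rank = R, sparsity = S, seed = cell_seed, feasible = TRUE,
        reason = NA_character_,
        final_test_accuracy = last$test_accuracy,
        mean_angle = last$mean_angle)
    }
  }
  if (!any_feasible) {
    stop("all rank/sparsity cells are infeasible", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sdfa_sweep", class(out))
  out
}

#' Aggregate a sweep to per-cell means and standard deviations
#'
#' @param records An `sdfa_sweep` tibble.
#' @return Tibble with one row per feasible `(rank, sparsity)` cell:
#'   mean/sd of final test accuracy and mean alignment angle, and the number
#'   of simulations.
#' @export
aggregate_sweep <- function(records) {
  records |>
    dplyr::filter(.data$feasible) |>
    dplyr::group_by(.data$rank, .data$sparsity) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_accuracy = mean(.data$final_test_accuracy),
      sd_accuracy = stats::sd(.data$final_test_accuracy),
      mean_angle = mean(.data$mean_angle),
      sd_angle = stats::sd(.data$mean_angle),
      .groups = "drop"
    )
}

#' Plot sweep results
#'
#' Mean final test accuracy against feedback rank, one line per sparsity
#' level, with one-standard-deviation error bars.
#'
#' @param object An `sdfa_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdfa_sweep <- function(object, ...) {
  agg <- aggregate_sweep(object)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$rank, y = .data$mean_accuracy,
                                    colour = factor(.data$sparsity))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), width = 0.2) +
    ggplot2::labs(x = "feedback rank", y = "final test accuracy",
                  colour = "sparsity") +
    ggplot2::theme_minimal()
}

#' Cost comparison across credit rules for one architecture
#'
#' Emits the BP, DFA and SDFA cost totals for a fully connected architecture
#' together with all pairwise reduction factors for every cost field.
#'
#' @inheritParams architecture_counts
#' @return A list of class `cost_comparison`: `costs` (one row per rule) and
#'   `reductions` (one row per rule pair and field, with the ratio and its
#'   two-significant-figure rendering).
#' @examples
#' report_costs(network_spec(c(784, 100, 10)))
#' @export
report_costs <- function(specs, feedback_nnz_per_row = 1L) {
  reports <- lapply(stats::setNames(CREDIT_RULES, CREDIT_RULES), function(r) {
    network_costs(specs, r, feedback_nnz_per_row)
  })
  costs <- dplyr::bind_rows(lapply(reports, cost_totals))
  pairs <- expand.grid(from = CREDIT_RULES, to = CREDIT_RULES,
                       field = c("reads", "writes", "macs", "movement"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  reductions <- purrr::pmap_dfr(pairs, function(from, to, field) {
    ratio <- reduction_factor(reports[[from]], reports[[to]], field)
    tibble::tibble(from = from, to = to, field = field, ratio = ratio,
                   label = format_reduction(ratio))
  })
  structure(list(costs = costs, reductions = reductions),
            class = "cost_comparison")
}

#' @export
print.cost_comparison <- function(x, ...) {
  cat("Per-example cost totals (words):\n")
  print(x$costs)
  cat("\nKey reductions:\n")
  key <- dplyr::filter(x$reductions,
                       (.data$from == "BP" | .data$from == "DFA") &
                         .data$to == "SDFA" &
                         .data$field %in% c("macs", "movement"))
  print(key)
  invisible(x)
}

#' Plot a cost comparison
#'
#' MACs and data movement per training example by credit rule, on a log
#' scale.
#'
#' @param object A `cost_comparison` from [report_costs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cost_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$costs, cols = c("macs", "movement"),
                              names_to = "metric", values_to = "words")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rule, y = .data$words,
                                     fill = .data$rule)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "words per training example") +
    ggplot2::theme_minimal()
}
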