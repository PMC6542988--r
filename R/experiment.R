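#' Build a validated experiment configuration
#'
#' Collects everything a training run or sweep needs — architecture, task
#' generator, credit rule, feedback constraints, optimizer settings — into
#' one validated list. All seeds used downstream enumerate deterministically
#' from the single root `seed`, and the feasibility of the feedback
#' constraints is checked here, before any training starts.
#'
#' @param sizes Integer vector of layer widths (input first, classes last).
#' @param rule `"BP"`, `"DFA"` or `"SDFA"`.
#' @param task List describing the task: `kind` (`"clusters"` or
#'   `"teacher"`) plus the generator's parameters (for clusters:
#'   `n_samples`, `n_features`, `n_classes`, `margin`, `noise_scale`).
#' @param learning_rate,decay Optimizer settings, see [update_config()].
#' @param epochs,batch_size Training-loop settings.
#' @param feedback List with optional `rank`, `sparsity` (defaults: full
#'   rank, SSDFA-level sparsity for SDFA, dense for DFA).
#' @param repeats Number of repeated runs (seeds per cell) for sweeps.
#' @param seed Root seed.
#' @param hidden Hidden-layer activation kind.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(sizes, rule = "BP",
                              task = list(kind = "clusters", n_samples = 600,
                                          n_features = sizes[1],
                                          n_classes = sizes[length(sizes)],
                                          margin = 6, noise_scale = 1),
                              learning_rate = 0.05, decay = 1,
                              epochs = 5L, batch_size = 50L,
                              feedback = list(), repeats = 3L, seed = 1L,
                              hidden = "tanh") {
  if (!rule %in% CREDIT_RULES) {
    stop("rule must be one of ", paste(CREDIT_RULES, collapse = ", "),
         call. = FALSE)
  }
  specs <- network_spec(as.integer(sizes), hidden = hidden)
  cfg <- update_config(learning_rate, decay, seed)
  if (!is.list(task) || is.null(task$kind) ||
      !task$kind %in% c("clusters", "teacher")) {
    stop("task$kind must be 'clusters' or 'teacher'", call. = FALSE)
  }
  M <- sizes[length(sizes)]
  if (rule == "SDFA" && length(sizes) > 2L) {
    R <- feedback$rank %||% M
    S <- feedback$sparsity %||% ((M - 1) / M)
    # Raises on infeasibility before any training starts.
    for (l in seq_len(length(sizes) - 2L)) {
      feedback_spec(sizes[l + 1L], M, rank = R, sparsity = S, seed = seed)
    }
    feedback <- list(rank = R, sparsity = S)
  }
  structure(
    list(sizes = as.integer(sizes), hidden = hidden, rule = rule, task = task,
         learning_rate = learning_rate, decay = decay,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         feedback = feedback, repeats = as.integer(repeats),
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' The file's keys mirror the arguments of [experiment_config()]; unknown
#' keys are rejected so that typos fail loudly.
#'
#' @param path Path to a YAML configuration file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("sizes", "hidden", "rule", "task", "learning_rate", "decay",
               "epochs", "batch_size", "feedback", "repeats", "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(experiment_config, raw)
}

#' Write an experiment configuration as YAML
#'
#' @param config An `experiment_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

build_task <- function(config) {
  t <- config$task
  if (t$kind == "clusters") {
    make_cluster_task(t$n_samples, t$n_features, t$n_classes,
                      margin = t$margin, noise_scale = t$noise_scale,
                      seed = t$seed %||% config$seed)
  } else {
    make_teacher_task(network_spec(as.integer(t$teacher_sizes)),
                      n_samples = t$n_samples,
                      seed = t$seed %||% config$seed)
  }
}

run_seeds <- function(config) config$seed + 1000L * seq_len(config$repeats)

#' Run a configured experiment and write tidy outputs
#'
#' Builds the task, trains `repeats` networks from deterministically
#' enumerated seeds, and (optionally) writes `metrics.csv` (one row per
#' epoch per repeat) plus a resolved copy of the configuration
#' (`config.yaml`) next to it for provenance. Outputs contain no timestamps,
#' so re-running the same configuration reproduces the files byte for byte.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if needed); `NULL`
#'   skips writing.
#' @return Invisibly, a list with `fits` (the trained models) and `metrics`
#'   (the combined history tibble with a `seed` column).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  task <- build_task(config)
  specs <- network_spec(config$sizes, hidden = config$hidden)
  cfg <- update_config(config$learning_rate, config$decay, config$seed)
  M <- config$sizes[length(config$sizes)]
  fits <- lapply(run_seeds(config), function(s) {
    feedbacks <- NULL
    if (config$rule == "SDFA" && length(config$sizes) > 2L &&
        length(config$feedback)) {
      feedbacks <- lapply(seq_len(length(config$sizes) - 2L), function(l) {
        generate_feedback(feedback_spec(
          config$sizes[l + 1L], M, rank = config$feedback$rank,
          sparsity = config$feedback$sparsity, seed = s + 7L * l))
      })
    }
    train_network(task, specs, rule = config$rule, feedbacks = feedbacks,
                  cfg = cfg, epochs = config$epochs,
                  batch_size = config$batch_size, seed = s)
  })
  metrics <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    dplyr::mutate(fits[[i]]$history, seed = run_seeds(config)[i],
                  rule = config$rule)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    write_experiment_config(config, file.path(out_dir, "config.yaml"))
  }
  invisible(list(fits = fits, metrics = metrics))
}
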