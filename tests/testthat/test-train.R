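small_task <- function(seed = 1) {
  make_cluster_task(360, 12, 4, margin = 6, noise_scale = 1, seed = seed)
}

test_that("epochs = 0 records only the initial evaluation", {
  fit <- train_network(small_task(), network_spec(c(12, 8, 4)), rule = "BP",
                       epochs = 0, seed = 1)
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$history$epoch, 0)
  expect_identical(fit$params$weights,
                   init_weights(network_spec(c(12, 8, 4)), seed = 1)$weights)
})

test_that("training is reproducible from its configuration", {
  task <- small_task()
  specs <- network_spec(c(12, 8, 4))
  f1 <- train_network(task, specs, rule = "SDFA", cfg = update_config(0.1),
                      epochs = 4, seed = 3)
  f2 <- train_network(task, specs, rule = "SDFA", cfg = update_config(0.1),
                      epochs = 4, seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params$weights, f2$params$weights)
})

test_that("mismatched task and architecture are rejected up front", {
  task <- small_task()
  expect_error(train_network(task, network_spec(c(10, 8, 4))), "fan_in")
  expect_error(train_network(task, network_spec(c(12, 8, 5))), "class count")
  expect_error(
    train_network(task, network_spec(c(12, 8, 4)), rule = "SDFA",
                  feedbacks = list(matrix(1, 3, 3))),
    "shape")
})

test_that("an unconnected error column triggers a warning before training", {
  task <- small_task()
  B <- matrix(rnorm(8 * 4), 8, 4)
  B[, 2] <- 0
  expect_warning(
    train_network(task, network_spec(c(12, 8, 4)), rule = "SDFA",
                  feedbacks = list(B), epochs = 1, seed = 1),
    "unconnected")
})

test_that("fit accessors, tidiers and plots expose the history", {
  fit <- train_network(small_task(), network_spec(c(12, 8, 4)), rule = "DFA",
                       cfg = update_config(0.1), epochs = 3, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_true(all(c("epoch", "train_accuracy", "test_accuracy", "train_loss",
                    "mean_angle", "angle_1") %in% names(td)))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_parameters, 12 * 8 + 8 * 4)
  expect_s3_class(autoplot(fit), "ggplot")

  pred <- predict(fit, small_task()$features)
  expect_true(all(pred %in% 1:4))
  prob <- predict(fit, small_task()$features, type = "prob")
  expect_equal(rowSums(prob), rep(1, 360), tolerance = 1e-12)
})

test_that("sweeps enumerate exactly the feasible cells", {
  task <- small_task()
  specs <- network_spec(c(12, 8, 4))
  # single feasible cell: full rank at the single-connection sparsity
  sw <- sweep_rank_sparsity(task, specs, ranks = 4, sparsities = 0.75,
                            repeats = 2, epochs = 1, batch_size = 30, seed = 1)
  expect_equal(sum(sw$feasible), 2)

  # an infeasible cell is recorded as skipped, never trained
  sw2 <- sweep_rank_sparsity(task, specs, ranks = c(1, 4),
                             sparsities = 0.5, repeats = 1, epochs = 1,
                             batch_size = 30, seed = 1)
  skipped <- sw2[!sw2$feasible, ]
  expect_equal(skipped$rank, 1)
  expect_match(skipped$reason, "infeasible")
  expect_true(all(is.na(skipped$final_test_accuracy)))

  expect_error(
    sweep_rank_sparsity(task, specs, ranks = 1, sparsities = 0.5,
                        repeats = 1),
    "all rank/sparsity cells are infeasible")

  # feasible-cell count matches brute-force enumeration over a full grid
  ranks <- 1:4; sparsities <- c(0, 0.25, 0.5, 0.75)
  sw3 <- sweep_rank_sparsity(task, specs, ranks = ranks,
                             sparsities = sparsities, repeats = 1,
                             epochs = 0, batch_size = 30, seed = 1)
  brute <- sum(outer(ranks, 1 - sparsities) >= 1 - 1e-9)
  expect_equal(sum(sw3$feasible), brute)
  agg <- aggregate_sweep(sw3)
  expect_equal(nrow(agg), brute)
  expect_s3_class(autoplot(sw3), "ggplot")
})

test_that("accuracy increases with feedback rank and is insensitive to sparsity", {
  task <- make_cluster_task(600, 16, 10, margin = 6, noise_scale = 1, seed = 6)
  specs <- network_spec(c(16, 20, 10))
  sw <- sweep_rank_sparsity(task, specs, ranks = c(1, 3, 10), sparsities = 0,
                            repeats = 5, cfg = update_config(0.1),
                            epochs = 6, batch_size = 30, seed = 2)
  agg <- aggregate_sweep(sw)
  rho <- cor(agg$rank, agg$mean_accuracy, method = "spearman")
  expect_gt(rho, 0)

  # at full rank, the densest and sparsest feasible levels agree within
  # two pooled standard deviations
  sw2 <- sweep_rank_sparsity(task, specs, ranks = 10, sparsities = c(0, 0.9),
                             repeats = 5, cfg = update_config(0.1),
                             epochs = 6, batch_size = 30, seed = 3)
  agg2 <- aggregate_sweep(sw2)
  gap <- abs(diff(agg2$mean_accuracy))
  pooled_sd <- sqrt(mean(agg2$sd_accuracy^2))
  expect_lte(gap, 2 * pooled_sd + 1e-8)
})

test_that("experiment configs validate, serialize and rerun identically", {
  cfg <- experiment_config(
    sizes = c(12, 8, 4), rule = "SDFA",
    task = list(kind = "clusters", n_samples = 360, n_features = 12,
                n_classes = 4, margin = 6, noise_scale = 1),
    learning_rate = 0.1, epochs = 2, batch_size = 30, repeats = 2, seed = 5)

  expect_error(
    experiment_config(sizes = c(12, 8, 4), rule = "SDFA",
                      feedback = list(rank = 1, sparsity = 0.9)),
    "infeasible")
  expect_error(experiment_config(sizes = c(12, 8, 4), rule = "XX"), "rule")

  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  cfg2 <- read_experiment_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  run_experiment(cfg, dir1)
  run_experiment(cfg, dir2)
  m1 <- readBin(file.path(dir1, "metrics.csv"), "raw",
                n = file.size(file.path(dir1, "metrics.csv")))
  m2 <- readBin(file.path(dir2, "metrics.csv"), "raw",
                n = file.size(file.path(dir2, "metrics.csv")))
  expect_identical(m1, m2)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("sizes: [12, 8, 4]\nbogus_key: 1", bad)
  expect_error(read_experiment_config(bad), "unknown config keys")
})
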