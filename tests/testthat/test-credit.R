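test_that("output error is softmax minus one-hot and sums to zero", {
  # saturated logit: softmax output exactly equals the target in floats
  expect_equal(output_error(c(1000, 0, 0), c(1, 0, 0)), rep(0, 3))
  # uniform 10-class softmax against class 3
  e <- output_error(rep(1.7, 10), replace(numeric(10), 3, 1))
  expect_equal(e, replace(rep(0.1, 10), 3, 0.1 - 1), tolerance = 1e-12)
  for (seed in 1:5) {
    z <- withr::with_seed(seed, rnorm(10, sd = 3))
    expect_lt(abs(sum(output_error(z, replace(numeric(10), 1, 1)))), 1e-12)
  }
  expect_error(output_error(c(0, 0), c(0.5, 0.5)), "one-hot")
  expect_error(output_error(c(0, 0), c(1, 1)), "one-hot")
})

test_that("backpropagated errors match hand cases and the preactivation oracle", {
  # single hidden linear layer: delta_1 = W2^T e
  specs <- network_spec(c(3, 4, 2), hidden = "linear")
  p <- init_weights(specs, seed = 2)
  tr <- forward(p, c(1, -1, 0.5))
  e <- c(0.3, -0.3)
  sig <- bp_errors(p, tr, e)
  expect_equal(sig$deltas[[2]], e)
  expect_equal(sig$deltas[[1]], drop(t(p$weights[[2]]) %*% e))

  # homogeneity in e
  sig0 <- bp_errors(p, tr, c(0, 0))
  expect_true(all(vapply(sig0$deltas, function(d) all(d == 0), logical(1))))

  # 2-3-2 tanh network: delta_1 equals the finite-difference gradient of the
  # loss with respect to y_1
  specs2 <- network_spec(c(2, 3, 2), hidden = "tanh")
  p2 <- init_weights(specs2, seed = 9)
  x <- c(0.4, -1.1); target <- c(0, 1)
  tr2 <- forward(p2, x)
  e2 <- output_error(tr2$activations[[2]], target)
  sig2 <- bp_errors(p2, tr2, e2)
  expect_equal(sig2$deltas[[1]],
               finite_diff_preact_grad(p2, x, target, layer = 1),
               tolerance = 1e-6)
})

test_that("direct feedback reproduces BP in the one-hidden-layer limit", {
  specs <- network_spec(c(4, 5, 3), hidden = "tanh")
  p <- init_weights(specs, seed = 11)
  tr <- forward(p, c(1, 0, -1, 0.5))
  e <- output_error(tr$activations[[2]], c(0, 0, 1))
  bp <- bp_errors(p, tr, e)
  dfa <- dfa_errors(list(t(p$weights[[2]])), tr, e)
  expect_equal(dfa$deltas[[1]], bp$deltas[[1]], tolerance = 1e-12)
  expect_identical(dfa$deltas[[2]], e)

  # homogeneity and annihilation
  dfa0 <- dfa_errors(list(t(p$weights[[2]])), tr, numeric(3))
  expect_true(all(dfa0$deltas[[1]] == 0))
  dfaz <- dfa_errors(list(matrix(0, 5, 3)), tr, e)
  expect_true(all(dfaz$deltas[[1]] == 0))
  expect_identical(dfaz$deltas[[2]], e)

  expect_error(dfa_errors(list(), tr, e), "missing feedback")
  expect_error(dfa_errors(list(matrix(0, 2, 3)), tr, e), "shape")
})

test_that("hidden-layer errors under direct feedback are local", {
  # delta_l must depend only on B_l, e and the layer's own activations:
  # perturbing any other layer's feedback or activations leaves it unchanged
  specs <- network_spec(c(4, 6, 5, 3), hidden = "tanh")
  p <- init_weights(specs, seed = 21)
  tr <- forward(p, c(0.2, -0.4, 1, 0.1))
  e <- output_error(tr$activations[[3]], c(1, 0, 0))
  fbs <- list(matrix(rnorm(18), 6, 3), matrix(rnorm(15), 5, 3))
  base <- dfa_errors(fbs, tr, e)

  fbs2 <- fbs; fbs2[[2]] <- fbs2[[2]] * 100
  tr2 <- tr; tr2$activations[[2]] <- tr2$activations[[2]] * 0.5
  expect_identical(dfa_errors(fbs2, tr2, e)$deltas[[1]], base$deltas[[1]])

  fbs3 <- fbs; fbs3[[1]] <- fbs3[[1]] * -7
  tr3 <- tr; tr3$activations[[1]] <- tr3$activations[[1]] * 0.1
  expect_identical(dfa_errors(fbs3, tr3, e)$deltas[[2]], base$deltas[[2]])
})

test_that("the per-neuron sparse error is a product of three scalars", {
  v <- sdfa_neuron_error(c(0, 0.5, 0), c(0.4, -0.2, 9), a_li = 0.3,
                         kind = "linear")
  expect_equal(as.numeric(v), -0.1)
  expect_identical(attr(v, "macs"), 1L)

  # dense row reproduces the corresponding dfa_errors component
  specs <- network_spec(c(3, 4, 2), hidden = "sigmoid")
  p <- init_weights(specs, seed = 4)
  tr <- forward(p, c(0.1, 0.9, -0.4))
  e <- output_error(tr$activations[[2]], c(1, 0))
  B <- matrix(rnorm(8), 4, 2)
  dfa <- dfa_errors(list(B), tr, e)
  for (i in 1:4) {
    v <- sdfa_neuron_error(B[i, ], e, tr$activations[[1]][i], "sigmoid")
    expect_equal(as.numeric(v), dfa$deltas[[1]][i], tolerance = 1e-12)
    expect_identical(attr(v, "macs"), 2L)
  }
  expect_error(sdfa_neuron_error(c(1, 2), c(1, 2, 3), 0, "linear"), "length")
})

test_that("sparse rows agree with their densified evaluation, MACs = nnz", {
  for (seed in 1:10) {
    row <- withr::with_seed(seed, {
      r <- numeric(10)
      nnz <- sample(1:10, 1)
      r[sample.int(10, nnz)] <- runif(nnz, -1, 1)
      r
    })
    e <- withr::with_seed(seed + 100, rnorm(10))
    v <- sdfa_neuron_error(row, e, a_li = 0.7, kind = "tanh")
    dense <- sum(row * e) * (1 - 0.7^2)
    expect_equal(as.numeric(v), dense, tolerance = 1e-12)
    expect_identical(attr(v, "macs"), sum(row != 0))
  }
})

test_that("weight gradients assemble outer products and pass the full oracle", {
  specs <- network_spec(c(2, 2, 2), hidden = "tanh")
  p <- init_weights(specs, seed = 6)
  x <- c(0.5, -0.25); target <- c(1, 0)
  tr <- forward(p, x)
  e <- output_error(tr$activations[[2]], target)
  sig <- bp_errors(p, tr, e)
  grads <- weight_gradients(tr, sig)
  expect_equal(grads[[2]], sig$deltas[[2]] %o% tr$activations[[1]])
  expect_equal(grads[[1]], sig$deltas[[1]] %o% x)

  # zero deltas give zero gradients
  sig0 <- bp_errors(p, tr, c(0, 0))
  expect_true(all(vapply(weight_gradients(tr, sig0),
                         function(g) all(g == 0), logical(1))))

  # full-parameter check on a 3-4-2 tanh network
  specs2 <- network_spec(c(3, 4, 2), hidden = "tanh")
  p2 <- init_weights(specs2, seed = 13)
  x2 <- c(0.3, -0.6, 1.2); t2 <- c(0, 1)
  tr2 <- forward(p2, x2)
  sig2 <- bp_errors(p2, tr2, output_error(tr2$activations[[2]], t2))
  g2 <- weight_gradients(tr2, sig2)
  fd <- finite_diff_grads(p2, x2, t2)
  for (l in 1:2) {
    expect_lt(max(abs(g2[[l]] - fd[[l]])), 1e-6)
  }
})

test_that("SGD updates follow the decayed learning rate and never touch feedback", {
  specs <- network_spec(c(2, 2), output = "linear")
  p <- init_weights(specs, seed = 1)
  W0 <- p$weights[[1]]
  cfg <- update_config(0.1, decay = 1)

  expect_identical(sgd_step(p, list(matrix(0, 2, 2)), cfg)$weights[[1]], W0)
  p1 <- sgd_step(p, list(diag(2)), cfg)
  expect_equal(p1$weights[[1]], W0 - 0.1 * diag(2))

  cfg2 <- update_config(0.1, decay = 0.5)
  p2 <- sgd_step(p, list(diag(2)), cfg2, epoch = 2)
  expect_equal(p2$weights[[1]], W0 - 0.025 * diag(2))

  expect_error(sgd_step(p, list(matrix(NaN, 2, 2)), cfg), "layer 1")
  expect_error(update_config(-1), "positive")
  expect_error(update_config(0.1, decay = 0), "decay")
})

test_that("BP gradients match finite differences on random small networks", {
  for (seed in 1:6) {
    specs <- random_small_specs(seed)
    p <- init_weights(specs, seed = seed + 50)
    d <- specs[[1]]$fan_in
    k <- specs[[length(specs)]]$fan_out
    x <- withr::with_seed(seed + 200, rnorm(d))
    target <- random_one_hot(k, seed + 300)
    tr <- forward(p, x)
    sig <- bp_errors(p, tr, output_error(tr$activations[[length(specs)]],
                                         target))
    g <- weight_gradients(tr, sig)
    fd <- finite_diff_grads(p, x, target)
    for (l in seq_along(g)) expect_lt(max(abs(g[[l]] - fd[[l]])), 1e-6)
  }
})

test_that("all three rules learn a linearly separable task", {
  task <- make_cluster_task(480, 16, 4, margin = 6, noise_scale = 1, seed = 5)
  specs <- network_spec(c(16, 24, 4))
  rates <- c(0.05, 0.2)
  for (rule in CREDIT_RULES) {
    passes <- vapply(1:5, function(seed) {
      best <- max(vapply(rates, function(lr) {
        fit <- train_network(task, specs, rule = rule,
                             cfg = update_config(lr), epochs = 8,
                             batch_size = 20, seed = seed)
        fit$history$train_accuracy[nrow(fit$history)]
      }, numeric(1)))
      best >= 0.95
    }, logical(1))
    expect_gte(sum(passes), 3)
  }
})
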