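test_that("the architecture grid enumerates in the documented order", {
  grid <- enumerate_architectures(2:10, 2)
  expect_length(grid, 90L)
  expect_equal(vapply(grid[1:9], function(a) a$hidden_sizes, integer(1)), 2:10)
  expect_equal(grid[[10]]$hidden_sizes, c(2L, 2L))
  expect_equal(grid[[11]]$hidden_sizes, c(2L, 3L))
  expect_equal(grid[[90]]$hidden_sizes, c(10L, 10L))
  expect_length(enumerate_architectures(2:10, 1), 9L)
  expect_length(enumerate_architectures(2:3, 2), 6L)
})

test_that("initialization gives uniform [-1, 1] weights, unit biases, exact shapes", {
  arch <- architecture(c(8, 10), input_size = 5, output_size = 2)
  m <- init_model(arch, seed = 42)
  expect_equal(lapply(m$weights, dim),
               list(c(5L, 8L), c(8L, 10L), c(10L, 2L)))
  expect_equal(lapply(m$biases, length), list(8L, 10L, 2L))
  expect_true(all(unlist(m$biases) == 1))
  w <- unlist(m$weights)
  expect_true(all(w >= -1 & w <= 1))
  expect_identical(init_model(arch, seed = 42)$weights, m$weights)
  expect_false(identical(init_model(arch, seed = 43)$weights, m$weights))
})

test_that("the forward pass produces normalized, shift-invariant probabilities", {
  arch <- architecture(3, input_size = 5)
  m <- init_model(arch, seed = 1)
  ## all-zero weights with unit biases: symmetric logits -> [0.5, 0.5]
  m0 <- m
  m0$weights <- lapply(m0$weights, function(w) w * 0)
  p0 <- mlp_forward(m0, matrix(runif(10 * 5), ncol = 5))
  expect_equal(unname(p0), matrix(0.5, 10, 2), tolerance = 1e-15)

  x <- matrix(runif(20 * 5), ncol = 5)
  p <- mlp_forward(m, x)
  expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))

  ## adding a constant to both output logits leaves probabilities unchanged
  shifted <- m
  shifted$biases[[2]] <- shifted$biases[[2]] + 7.3
  expect_equal(mlp_forward(shifted, x), p, tolerance = 1e-12)
})

test_that("the R and compiled forward passes agree", {
  set.seed(3)
  x <- matrix(runif(12 * 5), ncol = 5)
  y <- rep(0:1, 6)
  for (hidden in list(4L, c(8L, 10L))) {
    m <- init_model(architecture(hidden), seed = 5)
    g <- coremarker:::mlp_gradient(m, x, y)
    expect_equal(g$loss, coremarker:::mlp_loss(m, x, y), tolerance = 1e-12)
  }
})

test_that("backprop gradients match central finite differences", {
  set.seed(11)
  for (hidden in list(2L, c(3L, 5L), c(10L, 2L))) {
    m <- init_model(architecture(hidden, input_size = 5), seed = 7)
    ## scale weights down to stay clear of relu kinks under perturbation
    m$weights <- lapply(m$weights, function(w) w * 0.5)
    x <- matrix(runif(8 * 5), ncol = 5)
    y <- rep(0:1, 4)
    got <- coremarker:::mlp_gradient(m, x, y)
    want <- fd_gradient(m, x, y)
    for (l in seq_along(m$weights)) {
      denom <- pmax(abs(want$grad_weights[[l]]), 1e-3)
      expect_lt(max(abs(got$grad_weights[[l]] - want$grad_weights[[l]]) / denom),
                1e-5)
      denom_b <- pmax(abs(want$grad_biases[[l]]), 1e-3)
      expect_lt(max(abs(got$grad_biases[[l]] - want$grad_biases[[l]]) / denom_b),
                1e-5)
    }
  }
})

test_that("training is deterministic, finite, and a zero learning rate is a no-op", {
  set.seed(21)
  x <- matrix(runif(40 * 5), ncol = 5)
  y <- rep(c("tumor", "normal"), 20)
  cfg <- run_config(epochs = 15, seed = 2)
  m <- init_model(architecture(4), seed = 9)

  fit1 <- train_mlp(m, x, y, cfg, seed = 33)
  fit2 <- train_mlp(m, x, y, cfg, seed = 33)
  expect_identical(fit1$model$weights, fit2$model$weights)
  expect_equal(length(fit1$record$loss), 15L)
  expect_true(all(is.finite(fit1$record$loss)))
  expect_false(identical(fit1$model$weights, m$weights))

  cfg0 <- run_config(learning_rate = 0, epochs = 5)
  fit0 <- train_mlp(m, x, y, cfg0, seed = 33)
  expect_identical(fit0$model$weights, m$weights)
  expect_identical(fit0$model$biases, m$biases)
})

test_that("a separable problem is learned to high training accuracy", {
  set.seed(8)
  n <- 60
  y <- rep(c(1L, 0L), each = n / 2)
  ## tumors high on all five features, normals low
  x <- matrix(runif(n * 5, 0, 0.35), ncol = 5) + 0.6 * y
  cfg <- run_config(epochs = 100)
  m <- init_model(architecture(c(8, 10)), seed = 3)
  fit <- train_mlp(m, x, y, cfg, seed = 3)
  expect_gte(fit$record$train_accuracy, 0.95)
})

test_that("the degenerate two-architecture search picks the better trainer", {
  set.seed(14)
  x <- matrix(runif(50 * 5, 0, 0.6), ncol = 5)
  x[1:25, ] <- x[1:25, ] + 0.4
  y <- rep(c("tumor", "normal"), each = 25)
  cfg <- run_config(hidden_node_range = 2:3, max_hidden_layers = 1,
                    repetitions = 1, epochs = 30, seed = 5)
  s <- architecture_search(x, cfg, labels = y)
  expect_equal(nrow(s$table), 2L)
  expect_equal(s$winner_index, which.max(s$table$mean_train_acc))
  expect_equal(s$train_accuracy, s$table$best_train_acc[s$winner_index])
})

test_that("predictions are deterministic with ties broken toward normal", {
  m <- init_model(architecture(3), seed = 2)
  sym <- m
  sym$weights <- lapply(sym$weights, function(w) w * 0)
  x <- matrix(runif(6 * 5), ncol = 5)
  p <- predict(sym, x)
  expect_true(all(p$label == "normal"))  # exact 0.5/0.5 ties

  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)
  expect_true(all(p1$probability > 0 & p1$probability < 1))
  expect_true(all(p1$probability >= 0.5))

  ## marker bookkeeping on rescaled input
  m$markers <- sprintf("g%d", 1:5)
  r <- rescaled_matrix(matrix(runif(4 * 3), nrow = 4,
                              dimnames = list(sprintf("g%d", 1:4), NULL)),
                       rep(c("tumor", "normal"), c(2, 1)), rep("S", 3))
  expect_error(predict(m, r), "g5")
})
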