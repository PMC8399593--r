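test_that("pixel cross-entropy matches closed forms and hand computations", {
  H <- 4; W <- 5
  truth <- matrix(rbinom(H * W, 1, 0.5), H, W)
  perfect <- array(0, c(H, W, 2))
  perfect[, , 1] <- 1 - truth; perfect[, , 2] <- truth
  expect_equal(pixel_cross_entropy(perfect, truth), 0, tolerance = 1e-10)

  uniform <- array(0.5, c(H, W, 2))
  expect_equal(pixel_cross_entropy(uniform, truth), log(2), tolerance = 1e-12)

  # 2 x 1 toy raster with p = 0.9 and 0.8 on the true classes
  toy <- array(0, c(2, 1, 2))
  t2 <- matrix(c(1, 0), 2, 1)
  toy[1, 1, ] <- c(0.1, 0.9)
  toy[2, 1, ] <- c(0.8, 0.2)
  expect_equal(pixel_cross_entropy(toy, t2), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-12)

  # class weights scale each pixel's contribution
  expect_equal(pixel_cross_entropy(uniform, truth, class_weights = c(2, 2)),
               2 * log(2), tolerance = 1e-12)
  expect_error(pixel_cross_entropy(uniform, matrix(0, 2, 2)), "aligned")
})

test_that("SGDM follows the velocity recursion exactly", {
  # two steps on a scalar: v1 = -0.1, p1 = -0.1; v2 = -0.19, p2 = -0.29
  s1 <- sgdm_step(0, 1, 0, learning_rate = 0.1, momentum = 0.9)
  expect_equal(s1$velocity, -0.1)
  expect_equal(s1$parameters, -0.1)
  s2 <- sgdm_step(s1$parameters, 1, s1$velocity, 0.1, 0.9)
  expect_equal(s2$velocity, -0.19)
  expect_equal(s2$parameters, -0.29)

  # momentum 0 reduces to plain gradient descent
  g <- matrix(rnorm(6), 2, 3)
  p <- matrix(0, 2, 3)
  s <- sgdm_step(p, g, p * 0, 0.5, 0)
  expect_equal(s$parameters, -0.5 * g)

  # zero gradient, zero velocity: parameters unchanged
  s0 <- sgdm_step(p, p * 0, p * 0, 0.5, 0.9)
  expect_equal(s0$parameters, p)

  # nested parameter lists update recursively; extra state passes through
  params <- list(a = list(w = c(1, 2), b = 0, running_mean = 5))
  grads <- list(a = list(w = c(1, 1), b = 2))
  vel <- zero_velocity(params)
  r <- sgdm_step(params, grads, vel, 0.1, 0)
  expect_equal(r$parameters$a$w, c(0.9, 1.9))
  expect_equal(r$parameters$a$running_mean, 5)
})

test_that("the patience counter counts at-or-above-minimum evaluations since the best", {
  tr <- early_stopping_trace(c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9), patience = 4)
  expect_true(tr$stopped)
  expect_equal(tr$stop_iteration, 6)   # four non-improvements after the minimum
  expect_equal(tr$best_iteration, 2)

  # equality with the minimum counts against patience
  tr2 <- early_stopping_trace(c(0.5, 0.5), patience = 1)
  expect_equal(tr2$stop_iteration, 2)

  # non-record improvements do not reset the counter
  tr3 <- early_stopping_trace(c(1.0, 0.8, 0.95, 0.9, 0.93, 0.91), patience = 4)
  expect_true(tr3$stopped)
  expect_equal(tr3$stop_iteration, 6)
  expect_equal(tr3$best_iteration, 2)

  # monotonically decreasing: never stops, best is the last
  tr4 <- early_stopping_trace(seq(1, 0.1, by = -0.1), patience = 3)
  expect_false(tr4$stopped)
  expect_equal(tr4$best_iteration, 10)
})

test_that("training stops by patience or epochs and restores the best weights", {
  spec <- build_reference_spec(16, 16)
  set.seed(12)
  xs <- replicate(6, matrix(runif(256, 0, 255), 16, 16), simplify = FALSE)
  ys <- replicate(6, matrix(rbinom(256, 1, 0.2), 16, 16), simplify = FALSE)
  data <- list(train_x = xs[1:4], train_y = ys[1:4],
               val_x = xs[5:6], val_y = ys[5:6])

  model <- init_network(spec, seed = 3)
  cfg <- training_config(mini_batch_size = 2, max_epochs = 3,
                         validation_patience = Inf, seed = 5)
  r <- train_network(model, data, cfg)
  # patience never triggered: max_epochs * ceil(n/batch) iterations
  expect_equal(attr(r$history, "stop_reason"), "max_epochs")
  expect_equal(max(r$history$iteration), 3 * ceiling(4 / 2))
  # returned parameters correspond to the minimum recorded validation loss
  best_it <- attr(r$history, "best_iteration")
  expect_equal(r$history$val_loss[r$history$iteration == best_it],
               min(r$history$val_loss))
  expect_equal(neovaseg:::validation_loss(r$model, data$val_x, data$val_y, c(1, 1)),
               min(r$history$val_loss), tolerance = 1e-9)

  # reproducible run-to-run under a fixed seed
  r2 <- train_network(init_network(spec, seed = 3), data, cfg)
  expect_equal(r$history, r2$history)

  # a tiny patience stops early
  cfg2 <- training_config(mini_batch_size = 2, max_epochs = 10,
                          validation_patience = 2, seed = 5)
  r3 <- train_network(init_network(spec, seed = 3), data, cfg2)
  if (attr(r3$history, "stop_reason") == "patience_exhausted") {
    expect_equal(tail(r3$history$patience_counter, 1), 2)
  }
  expect_error(train_network(model, list(train_x = list(), train_y = list(),
                                         val_x = xs[5:6], val_y = ys[5:6]), cfg),
               "non-empty")
})
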