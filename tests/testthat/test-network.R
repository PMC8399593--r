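test_that("the reference plan has 42 layers honoring the architectural contract", {
  spec <- build_reference_spec(80, 296)
  plan <- spec$layer_plan
  expect_length(plan, 42)
  kinds <- vapply(plan, `[[`, character(1), "kind")
  # exactly one depth concatenation, one pool, two residual additions
  expect_equal(sum(kinds == "concat"), 1L)
  expect_equal(sum(kinds == "maxpool"), 1L)
  expect_equal(sum(kinds == "add"), 2L)
  expect_equal(sum(kinds == "tconv"), 3L)           # three x2 upsampling stages
  expect_equal(plan$softmax$in_channels, 2L)        # two classes: Neo / NotNeo
  # stem is 7x7; mid layers 3x3; lowest-resolution bottleneck 1x1
  expect_equal(plan$stem_conv$kernel, c(7L, 7L))
  expect_equal(plan$rb1_conv1$kernel, c(3L, 3L))
  expect_equal(plan$bott_conv$kernel, c(1L, 1L))
  # skip connections of the downsampling blocks hold 1x1 stride-2 convolutions
  expect_equal(plan$rb1_skip_conv$kernel, c(1L, 1L))
  expect_equal(plan$rb1_skip_conv$stride, 2L)
  # concat joins the last upsampling with the stem activation: 32 + 32 -> 64
  expect_equal(plan$concat$inputs, c("up3_tconv", "stem_relu"))
  expect_equal(plan$up3_tconv$out_channels + plan$stem_relu$out_channels, 64L)
  expect_error(build_reference_spec(81, 296), "divisible")
})

test_that("parameter counting is closed-form, size-independent and reproducible", {
  spec <- build_reference_spec(80, 296)
  # stem: 7*7*1*32 weights + 32 biases
  expect_equal(7 * 7 * 1 * 32 + 32, 1600)
  # count matches the actual number of initialized parameter values
  m <- init_network(spec, seed = 1)
  n_actual <- sum(vapply(m$params, function(p) {
    length(p[["w"]]) + length(p[["b"]]) + length(p[["gamma"]]) + length(p[["beta"]])
  }, numeric(1)))
  expect_equal(count_parameters(spec), n_actual)
  # independent of input size; identical across builds
  expect_equal(count_parameters(build_reference_spec(160, 160)),
               count_parameters(spec))
  expect_equal(count_parameters(build_reference_spec(80, 296)),
               count_parameters(spec))
})

test_that("compiled convolutions match a per-pixel summation oracle", {
  set.seed(2)
  x <- array(rnorm(6 * 8 * 3 * 2), c(6, 8, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  for (cfg in list(c(1, 1), c(2, 1))) {
    got <- neovaseg:::cpp_conv2d_fwd(x, w, b, cfg[1], cfg[2])
    expect_equal(got, naive_conv2d(x, w, b, cfg[1], cfg[2]),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("1x1 fast path agrees with the oracle", {
  set.seed(3)
  x <- array(rnorm(6 * 8 * 3 * 2), c(6, 8, 3, 2))
  w1 <- array(rnorm(1 * 1 * 3 * 5), c(1, 1, 3, 5))
  b1 <- rnorm(5)
  expect_equal(neovaseg:::cpp_conv2d_fwd(x, w1, b1, 1L, 0L),
               naive_conv2d(x, w1, b1, 1, 0), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("residual blocks add element-wise and downsample consistently", {
  # stride 1, zero main-path weights, identity skip: output = relu(x)
  spec1 <- residual_block_spec(3, 3, stride = 1)
  p0 <- init_residual_block(spec1, seed = 1, init = "zero")
  set.seed(5)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  expect_equal(residual_block_forward(x, spec1, p0), pmax(x, 0),
               ignore_attr = TRUE)

  # stride 2 halves the spatial dimensions
  spec2 <- residual_block_spec(3, 6, stride = 2)
  p2 <- init_residual_block(spec2, seed = 2)
  y <- residual_block_forward(array(rnorm(64 * 64 * 3), c(64, 64, 3, 1)), spec2, p2)
  expect_equal(dim(y), c(32, 32, 6, 1))

  # the addition is a per-element sum: check against an explicit loop on a
  # 4x4x2 toy tensor by rebuilding the block by hand
  spec3 <- residual_block_spec(2, 2, stride = 1)
  p3 <- init_residual_block(spec3, seed = 3)
  x3 <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  main <- neovaseg:::conv_forward(x3, p3$conv1, c(3L, 3L), 1L)
  main <- neovaseg:::bn_forward(main, p3$bn1, FALSE)$y
  main <- pmax(main, 0)
  main <- neovaseg:::conv_forward(main, p3$conv2, c(3L, 3L), 1L)
  main <- neovaseg:::bn_forward(main, p3$bn2, FALSE)$y
  summed <- array(0, dim(main))
  for (i in seq_along(main)) summed[i] <- main[i] + x3[i]
  expect_equal(residual_block_forward(x3, spec3, p3), pmax(summed, 0),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("the forward pass fulfils the semantic-segmentation shape contract", {
  spec <- build_reference_spec(80, 296)
  m <- init_network(spec, seed = 4)
  x <- matrix(runif(80 * 296, 0, 255), 80, 296)
  p <- forward(m, x)
  expect_equal(dim(p), c(80, 296, 2))
  expect_true(all(p >= 0))
  expect_lt(max(abs(p[, , 1] + p[, , 2] - 1)), 1e-6)

  # fully-convolutional: doubling the input doubles the output
  m2 <- m
  m2$spec <- build_reference_spec(160, 592)
  p2 <- forward(m2, matrix(runif(160 * 592, 0, 255), 160, 592))
  expect_equal(dim(p2), c(160, 592, 2))

  # symmetric zero initialization: both classes exactly 0.5 everywhere
  m0 <- init_network(spec, init = "zero")
  p0 <- forward(m0, x)
  expect_true(all(p0 == 0.5))

  expect_error(forward(m, matrix(0, 81, 296)), "divisible")
})

test_that("encoder resolutions step full -> 1/2 -> 1/4 -> 1/8 and decoder restores them", {
  spec <- build_reference_spec(80, 296)
  m <- init_network(spec, seed = 6)
  fwd <- neovaseg:::net_forward(m, matrix(runif(80 * 296, 0, 255), 80, 296),
                                keep_cache = TRUE)
  dims <- function(nm) dim(fwd$outs[[nm]])[1:2]
  expect_equal(dims("stem_relu"), c(80, 296))
  expect_equal(dims("pool"), c(40, 148))
  expect_equal(dims("rb1_relu2"), c(20, 74))
  expect_equal(dims("rb2_relu2"), c(10, 37))
  expect_equal(dims("up1_relu"), c(20, 74))
  expect_equal(dims("up2_relu"), c(40, 148))
  expect_equal(dims("up3_tconv"), c(80, 296))
  expect_equal(dim(fwd$outs[["concat"]])[3], 64)
  expect_equal(dims("softmax"), c(80, 296))
})

test_that("backpropagated gradients match central finite differences", {
  spec <- build_reference_spec(8, 16)
  m <- init_network(spec, seed = 9)
  set.seed(10)
  x <- array(runif(8 * 16 * 2, 0, 255), c(8, 16, 1, 2))
  y <- array(rbinom(8 * 16 * 2, 1, 0.3), c(8, 16, 2))
  loss_at <- function(model) {
    fwd <- neovaseg:::net_forward(model, x, training = TRUE, keep_cache = TRUE)
    neovaseg:::softmax_ce(fwd$logits, y)$loss
  }
  fwd <- neovaseg:::net_forward(m, x, training = TRUE, keep_cache = TRUE)
  ce <- neovaseg:::softmax_ce(fwd$logits, y)
  grads <- neovaseg:::net_backward(m, fwd, ce$dlogits)

  eps <- 1e-4
  # probe a spread of layers and parameter kinds
  probes <- list(c("stem_conv", "w"), c("stem_bn", "gamma"),
                 c("rb1_conv1", "w"), c("rb1_skip_conv", "w"),
                 c("bott_conv", "b"), c("up1_tconv", "w"),
                 c("up2_bn", "beta"), c("head1_conv", "w"),
                 c("final_conv", "w"))
  for (pr in probes) {
    layer <- pr[1]; slot <- pr[2]
    k <- with_seed(sum(utf8ToInt(layer)),
                   sample(length(m$params[[layer]][[slot]]), 1))
    mp <- m; mp$params[[layer]][[slot]][k] <- mp$params[[layer]][[slot]][k] + eps
    mm <- m; mm$params[[layer]][[slot]][k] <- mm$params[[layer]][[slot]][k] - eps
    fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    an <- grads[[layer]][[slot]][k]
    expect_equal(an, fd, tolerance = 5e-2,
                 label = sprintf("analytic gradient for %s$%s", layer, slot))
  }
})
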