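test_that("conv_output_size covers the valid and padded conventions", {
  expect_equal(conv_output_size(5, 3, 1, 0), 3)   # l - m + 1
  expect_equal(conv_output_size(224, 7, 2, 3), 112)
  expect_equal(conv_output_size(17, 1, 1, 0), 17)  # identity kernel
  expect_error(conv_output_size(4, 7, 1, 0), "kernel")
})

test_that("maxpool_size_literal is the literal element-count formula", {
  expect_equal(maxpool_size_literal(112, 112, 1, 3, 2), 3025.0)  # (110*110)/4
  expect_equal(maxpool_size_literal(6, 6, 3, 6, 1), 3)           # whole-map filter
  expect_equal(maxpool_size_literal(4, 4, 2, 2, 1), 18.0)
  # closed form on random inputs
  set.seed(5)
  for (rep in 1:50) {
    nh <- sample(4:64, 1); nw <- sample(4:64, 1)
    nc <- sample(1:8, 1); f <- sample(1:min(nh, nw), 1); s <- sample(1:3, 1)
    expect_equal(maxpool_size_literal(nh, nw, nc, f, s),
                 nc * (nh - f + 1) * (nw - f + 1) / s^2)
  }
  expect_error(maxpool_size_literal(4, 4, 1, 5, 1), "filter")
})

test_that("sgd_update applies phi - lr * grad elementwise", {
  expect_equal(sgd_update(1.0, 0.5, 0.1), 0.95)
  expect_equal(sgd_update(c(1, 2), c(1, -1), 0.5), c(0.5, 2.5))
  expect_equal(sgd_update(3.3, 0, 0.7), 3.3)
  m <- matrix(1:4, 2)
  expect_equal(sgd_update(m, m, 1), m * 0)
  expect_error(sgd_update(1, NaN, 0.1), "finite")
  # one step on a quadratic reduces the loss
  phi <- 2
  loss <- function(p) (p - 1)^2
  phi2 <- sgd_update(phi, 2 * (phi - 1), 0.1)
  expect_lt(loss(phi2), loss(phi))
})

test_that("build_layer_plan reproduces the canonical 224 tensor-size column", {
  plan <- build_layer_plan(c(224, 224, 3), 5)
  expect_s3_class(plan, "layer_plan")
  expect_equal(plan$layers$out_spatial,
               c(112, 56, 56, 28, 28, 14, 14, 7, 7, 1))
  expect_identical(nrow(plan$layers), 10L)
  expect_equal(plan$layers$out_spatial[1], 112)       # stem convolution
  expect_equal(plan$layers$out_spatial[9], 7)         # fourth dense block
  expect_identical(plan$layers$kind[10], "classification")
  expect_identical(plan$layers$activation[10], "softmax")
  expect_true(all(plan$layers$activation[-10] == "relu"))
  expect_true(all(plan$layers$dropout[plan$layers$kind == "dense_block"]
                  == 0.2))
  expect_true(all(plan$layers$stride[plan$layers$kind %in%
                                       c("convolution", "maxpool",
                                         "transition")] == 2))
  expect_true(all(diff(plan$layers$out_spatial) <= 0))
})

test_that("layer plan rescales with input size and rejects bad input", {
  p128 <- build_layer_plan(c(128, 128, 3), 5)
  p64 <- build_layer_plan(c(64, 64, 3), 5)
  expect_equal(p64$layers$out_spatial[-10] * 2,
               p128$layers$out_spatial[-10])
  expect_equal(p64$layers$out_spatial[10], 1)
  expect_error(build_layer_plan(c(224, 200, 3), 5), "square")
  expect_error(build_layer_plan(c(100, 100, 3), 5), "divisible")
  # 112 is not divisible by 32: the halving chain would reach 3.5 pixels
  expect_error(build_layer_plan(c(112, 112, 3), 5), "divisible")
})

test_that("plan serializes to JSON and back", {
  plan <- build_layer_plan(c(64, 64, 3), 2)
  path <- tempfile(fileext = ".json")
  plan_to_json(plan, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$layers$out_spatial, plan$layers$out_spatial)
  expect_equal(back$num_classes, 2)
})

test_that("instantiated model matches the plan's shape column (reduced, 64px)", {
  plan <- build_layer_plan(c(64, 64, 3), 2)
  m <- tiny_model(2)
  expect_equal(shape_probe(m), plan$layers$out_spatial)
})

test_that("instantiation is deterministic per seed and softmax normalizes", {
  m1 <- tiny_model(3, seed = 5)
  m2 <- tiny_model(3, seed = 5)
  m3 <- tiny_model(3, seed = 6)
  expect_identical(koadapt:::model_params(m1), koadapt:::model_params(m2))
  expect_false(identical(koadapt:::model_params(m1),
                         koadapt:::model_params(m3)))
  set.seed(1)
  x <- array(stats::runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p <- predict_probs(m1, x)
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
})

test_that("analytic gradients match finite differences across layer types", {
  set.seed(9)
  plan <- build_layer_plan(c(32, 32, 1), 3)
  m <- instantiate_network(plan, 3, growth = 3L, init_channels = 4L,
                           block_layers = c(1L, 1L, 1L, 1L),
                           bottleneck = TRUE, dropout = 0)
  x <- array(stats::rnorm(32 * 32 * 2), c(32, 32, 1, 2))
  y <- c(1L, 3L)
  lossf <- function(mm) {
    p <- koadapt:::model_forward(mm, x, train = TRUE, keep = FALSE)$probs
    -mean(log(p[cbind(y, 1:2)]))
  }
  fw <- koadapt:::model_forward(m, x, train = TRUE, keep = TRUE)
  Y <- matrix(0, 3, 2); Y[cbind(y, 1:2)] <- 1
  gr <- koadapt:::model_backward(m, fw$caches, (fw$probs - Y) / 2)
  h <- 1e-5
  check <- function(get, set, gv, k = 4) {
    W <- get(m)
    for (i in sample(length(W), min(k, length(W)))) {
      Wp <- W; Wp[i] <- Wp[i] + h
      Wm <- W; Wm[i] <- Wm[i] - h
      num <- (lossf(set(m, Wp)) - lossf(set(m, Wm))) / (2 * h)
      expect_equal(gv[i], num, tolerance = 2e-4)
    }
  }
  check(function(m) m$stages[[1]]$ly$W,
        function(m, W) { m$stages[[1]]$ly$W <- W; m }, gr[[1]]$dW)
  check(function(m) m$stages[[1]]$ly$bn$gamma,
        function(m, v) { m$stages[[1]]$ly$bn$gamma <- v; m },
        gr[[1]]$bng$dgamma, 2)
  check(function(m) m$stages[[3]]$ly$comps[[1]]$bn_conv$W,
        function(m, W) { m$stages[[3]]$ly$comps[[1]]$bn_conv$W <- W; m },
        gr[[3]][[1]]$bn$dW)
  check(function(m) m$stages[[3]]$ly$comps[[1]]$conv3$W,
        function(m, W) { m$stages[[3]]$ly$comps[[1]]$conv3$W <- W; m },
        gr[[3]][[1]]$c3$dW)
  check(function(m) m$stages[[4]]$ly$W,
        function(m, W) { m$stages[[4]]$ly$W <- W; m }, gr[[4]]$dW)
  check(function(m) m$stages[[10]]$ly$W,
        function(m, W) { m$stages[[10]]$ly$W <- W; m }, gr[[10]]$dW)
})

test_that("checkpoints round-trip and refuse mismatched fingerprints", {
  m <- tiny_model(2, seed = 2)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- tiny_model(2, seed = 99)     # same config, different weights
  m2 <- load_checkpoint(m2, path)
  expect_identical(koadapt:::model_params(m2), koadapt:::model_params(m))
  m3 <- tiny_model(3, seed = 2)      # different head
  expect_error(load_checkpoint(m3, path), "fingerprint")
})
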