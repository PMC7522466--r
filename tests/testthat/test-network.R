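test_that("shape trace of the default architecture matches the layer table", {
  tr <- shape_trace(network_config())
  expect_equal(tr$size,
               c("640 x 2",
                 "(1, 630, 2, 25)", "(1, 630, 1, 25)", "(1, 210, 1, 25)",
                 "(1, 200, 1, 50)", "(1, 66, 1, 50)", "(1, 56, 1, 100)",
                 "(1, 18, 1, 100)", "(1, 8, 1, 200)", "(1, 4, 1, 200)",
                 "800", "4"))
})

test_that("spatial convolution collapses the electrode axis and exact-fit kernels give length 1", {
  tr <- shape_trace(network_config())
  expect_equal(tr$shape[[2]][3], 2L)   # conv1 keeps both electrodes
  expect_equal(tr$shape[[3]][3], 1L)   # conv2 collapses them
  cfg <- network_config(input_shape = c(11L, 1L), layers = list(
    list(kind = "conv", kernel = c(11L, 1L, 1L, 2L),
         stride = c(1L, 1L, 1L, 1L), post = "activation"),
    list(kind = "flatten"), list(kind = "fc")))
  expect_equal(shape_trace(cfg)$shape[[2]], c(1L, 1L, 1L, 2L))
})

test_that("convolution forward equals a nested-loop evaluation of the sum", {
  set.seed(42)
  for (rep in 1:5) {
    x <- array(rnorm(2 * 20 * 2 * 1), c(2, 20, 2, 1))
    w <- array(rnorm(7 * 2 * 1 * 3), c(7, 2, 1, 3))
    b <- rnorm(3)
    got <- conv2d_valid(x, w, b)
    for (s in 1:2) {
      xi <- array(x[s, , , ], c(20, 2, 1))
      expect_equal(drop(got[s, , , , drop = FALSE]), drop(oracle_conv(xi, w, b)),
                   tolerance = 1e-6)
    }
  }
  # multi-channel input
  x <- array(rnorm(1 * 12 * 1 * 4), c(1, 12, 1, 4))
  w <- array(rnorm(5 * 1 * 4 * 2), c(5, 1, 4, 2))
  b <- rnorm(2)
  expect_equal(conv2d_valid(x, w, b)[1, , , ],
               oracle_conv(array(x[1, , , ], c(12, 1, 4)), w, b)[, 1, ],
               tolerance = 1e-6)
})

test_that("identity kernel reproduces the input and output lengths follow the VALID formula", {
  x <- array(rnorm(3 * 640 * 2 * 1), c(3, 640, 2, 1))
  w <- array(1, c(1, 1, 1, 1))
  expect_equal(conv2d_valid(x, w, 0)[, , , 1], x[, , , 1])
  w11 <- array(rnorm(11), c(11, 1, 1, 25))
  expect_equal(dim(conv2d_valid(x, w11, numeric(25)))[2], 630L)
})

test_that("leaky ReLU follows both branches and the boundary", {
  expect_equal(leaky_relu(3.5), 3.5)
  expect_equal(leaky_relu(-1), -0.01)
  expect_equal(leaky_relu(0), 0)
  x <- matrix(c(-2, -0.5, 0, 0.5, 2, -10), 2)
  expect_equal(leaky_relu(x), ifelse(x > 0, x, 0.01 * x))
})

test_that("max pooling matches the VALID length arithmetic", {
  x <- array(rnorm(2 * 630 * 1 * 3), c(2, 630, 1, 3))
  expect_equal(dim(max_pool(x, 3))[2], 210L)
  x8 <- array(rnorm(2 * 8 * 1 * 2), c(2, 8, 1, 2))
  expect_equal(dim(max_pool(x8, 2))[2], 4L)
  expect_equal(max_pool(x8, 1), x8)
  # values: window max by hand
  v <- array(c(1, 5, 3, 2, 8, 4), c(1, 6, 1, 1))
  expect_equal(as.vector(max_pool(v, 3)), c(5, 8))
  # VALID truncation of the remainder
  v7 <- array(1:7, c(1, 7, 1, 1))
  expect_equal(as.vector(max_pool(v7, 3)), c(3, 6))
})

test_that("softmax is shift-invariant, normalized, and ties break to the lowest index", {
  r <- softmax_predict(c(0, 0, 0, 0))
  expect_equal(r$probs, rep(0.25, 4))
  expect_equal(r$label, 1L)
  z <- c(1, 2, 3, 4)
  expect_equal(softmax_predict(z)$probs, softmax_predict(z + 17)$probs)
  expect_equal(softmax_predict(z)$probs, exp(z) / sum(exp(z)),
               tolerance = 1e-12)
  expect_equal(softmax_predict(z)$label, 4L)
})

test_that("spatial dropout zeroes whole maps, rescales survivors, and is identity at inference", {
  x <- array(1, c(200, 4, 1, 50))
  expect_identical(spatial_dropout(x, 0.5, training = FALSE), x)
  expect_identical(spatial_dropout(x, 0, training = TRUE), x)
  set.seed(9)
  y <- spatial_dropout(x, 0.5, training = TRUE)
  per_map <- apply(y, c(1, 4), function(v) unique(v))
  expect_true(all(per_map %in% c(0, 2)))           # whole maps, scaled 1/(1-p)
  keep_rate <- mean(per_map == 2)
  expect_lt(abs(keep_rate - 0.5), 0.02)            # 10,000 masked maps
  expect_lt(abs(mean(y) - mean(x)), 0.05)          # expectation preserved
})

test_that("batch normalization standardizes per channel and the affine/limit cases hold", {
  set.seed(4)
  x <- array(rnorm(64 * 10 * 1 * 5, mean = 3, sd = 2), c(64, 10, 1, 5))
  y <- batch_norm(x, gamma = rep(1, 5), beta = rep(0, 5))
  m <- matrix(y, 64 * 10, 5)
  expect_true(all(abs(colMeans(m)) < 1e-5))
  expect_true(all(abs(apply(m, 2, function(v) mean(v^2)) - 1) < 1e-3))
  # gamma/beta shift the standardized moments to (beta, gamma^2)
  y2 <- batch_norm(x, gamma = rep(2, 5), beta = rep(3, 5))
  m2 <- matrix(y2, 64 * 10, 5)
  expect_true(all(abs(colMeans(m2) - 3) < 1e-4))
  expect_true(all(abs(apply(m2, 2, stats::var) - 4) < 0.05))
  # constant channel collapses to beta under the eps guard
  xc <- array(7, c(8, 4, 1, 2))
  yc <- batch_norm(xc, gamma = c(1, 1), beta = c(0.5, -0.5))
  expect_equal(unique(as.vector(yc[, , , 1])), 0.5, tolerance = 1e-6)
  expect_equal(unique(as.vector(yc[, , , 2])), -0.5, tolerance = 1e-6)
  # training on a batch of one is undefined
  expect_error(batch_norm(array(1, c(1, 4, 1, 2)), c(1, 1), c(0, 0)),
               "at least 2")
  # inference uses the supplied running moments
  yi <- batch_norm(x, rep(1, 5), rep(0, 5), training = FALSE,
                   running_mean = rep(3, 5), running_var = rep(4, 5))
  expect_equal(as.vector(yi), as.vector((x - 3) / sqrt(4 + 1e-5)),
               tolerance = 1e-5)
})

test_that("parameter counts match hand arithmetic per layer and in total", {
  cfg <- network_config()
  # conv1: 11*1*1*25 + 25; fc: 800*4 + 4; full tally per layer
  per_layer <- c(conv1 = 11 * 25 + 25, conv2 = 2 * 25 * 25 + 25,
                 conv3 = 11 * 25 * 50 + 50, conv4 = 11 * 50 * 100 + 100,
                 conv5 = 11 * 100 * 200 + 200, fc = 800 * 4 + 4,
                 bn = 2 * (25 + 100 + 200))
  expect_equal(count_parameters(cfg), sum(per_layer))
  expect_equal(per_layer[["conv1"]], 300)
  expect_equal(per_layer[["fc"]], 3204)
})

test_that("forward pass yields probability rows, is deterministic in eval mode, and engines agree", {
  cfg <- network_config()
  p <- init_params(cfg, seed = 3)
  x <- matrix(rnorm(6 * 1280), 6, 1280)
  pr1 <- net_forward(cfg, p, x)
  expect_equal(rowSums(pr1), rep(1, 6), tolerance = 1e-6)
  expect_identical(pr1, net_forward(cfg, p, x))            # bitwise repeat
  pr_ref <- net_forward(cfg, p, x, engine = "reference")
  expect_equal(pr1, pr_ref, tolerance = 1e-4)              # float32 vs double
  expect_error(net_forward(cfg, p, matrix(0, 2, 100)), "feature")
})

test_that("flatten feeds the output layer 800 features", {
  tr <- shape_trace(network_config())
  expect_equal(tr$shape[[which(tr$layer == "flatten")]], 800L)
})

test_that("backpropagated gradients match central finite differences", {
  cfg <- toy_config()
  net <- paircnn:::compile_network(cfg)
  set.seed(3)
  X <- matrix(rnorm(6 * 40), 6, 40)
  y <- sample(1:4, 6, TRUE)
  p <- init_params(cfg, 2)
  lg <- paircnn:::net_loss_grad_ref(net, p, X, y, training = TRUE,
                                    ablation = "no_dropout")
  eps <- 1e-4
  set.seed(11)
  for (site in names(lg$grads)) {
    for (leaf in names(lg$grads[[site]])) {
      g <- lg$grads[[site]][[leaf]]
      for (i in sample(length(g), min(length(g), 4))) {
        p2 <- p; p2[[site]][[leaf]][i] <- p2[[site]][[leaf]][i] + eps
        p3 <- p; p3[[site]][[leaf]][i] <- p3[[site]][[leaf]][i] - eps
        l2 <- paircnn:::net_loss_grad_ref(net, p2, X, y, training = TRUE,
                                          ablation = "no_dropout")$loss
        l3 <- paircnn:::net_loss_grad_ref(net, p3, X, y, training = TRUE,
                                          ablation = "no_dropout")$loss
        num <- (l2 - l3) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-6), 1e-3)
      }
    }
  }
})

test_that("fused training engine reproduces the reference loss and gradients", {
  cfg <- network_config()
  net <- paircnn:::compile_network(cfg)
  p <- init_params(cfg, 5)
  set.seed(21)
  X <- matrix(rnorm(8 * 1280), 8, 1280)
  y <- sample(1:4, 8, TRUE)
  set.seed(77)
  fast <- paircnn:::net_loss_grad(net, p, X, y, ablation = "no_dropout")
  set.seed(77)
  ref <- paircnn:::net_loss_grad_ref(net, p, X, y, ablation = "no_dropout")
  expect_equal(fast$loss, ref$loss, tolerance = 1e-5)
  for (site in names(ref$grads)) {
    for (leaf in names(ref$grads[[site]])) {
      expect_equal(fast$grads[[site]][[leaf]], ref$grads[[site]][[leaf]],
                   tolerance = 1e-3, ignore_attr = TRUE)
    }
  }
})

test_that("kernels larger than their input are rejected with a shape error", {
  expect_error(conv2d_valid(array(0, c(1, 5, 1, 1)),
                            array(0, c(6, 1, 1, 1)), 0), "larger")
  cfg <- network_config(input_shape = c(5L, 2L))
  expect_error(shape_trace(cfg), "larger")
})
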