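test_that("cross-entropy has its closed forms and matches direct summation", {
  onehot <- diag(4)[c(1, 2, 3), ]
  expect_equal(cross_entropy_loss(onehot, c(1, 2, 3)), 0, tolerance = 1e-10)
  expect_equal(cross_entropy_loss(matrix(0.25, 5, 4), c(1, 3, 2, 4, 1)),
               log(4))
  set.seed(31)
  probs <- matrix(runif(40), 10, 4)
  probs <- probs / rowSums(probs)
  y <- sample(1:4, 10, TRUE)
  hand <- -mean(vapply(1:10, function(i) log(probs[i, y[i]]), numeric(1)))
  expect_equal(cross_entropy_loss(probs, y), hand)
})

test_that("Adam updates: zero gradient, one-step closed form, determinism", {
  tc <- train_config(learning_rate = 0.1)
  params <- list(site = list(W = matrix(c(1, 2), 1), b = 0.5))
  zero <- list(site = list(W = matrix(0, 1, 2), b = 0))
  u <- adam_update(params, zero, NULL, 1, tc)
  expect_equal(u$params, params)
  # constant gradient from zero state: step = -lr * g/(|g| + eps) ~ -lr*sign(g)
  g <- list(site = list(W = matrix(c(0.3, -0.2), 1), b = 4))
  u2 <- adam_update(params, g, NULL, 1, tc)
  expect_equal(u2$params$site$W[1, 1], 1 - 0.1 * (0.3 / (0.3 + 1e-8)),
               tolerance = 1e-6)
  expect_equal(u2$params$site$W[1, 2], 2 + 0.1 * (0.2 / (0.2 + 1e-8)),
               tolerance = 1e-6)
  u3 <- adam_update(params, g, NULL, 1, tc)
  expect_identical(u2, u3)
})

test_that("a small network learns a separable toy problem and training is seed-reproducible", {
  # two well-separated classes of 20 x 2 patterns
  set.seed(50)
  n <- 120
  y <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * 40, sd = 0.5), n, 40)
  x[y == 1, 1:20] <- x[y == 1, 1:20] + 2
  x[y == 2, 21:40] <- x[y == 2, 21:40] + 2
  cfg <- network_config(input_shape = c(20L, 2L), n_classes = 2L,
                        dropout_p = 0, layers = list(
    list(kind = "conv", kernel = c(5L, 2L, 1L, 4L),
         stride = c(1L, 1L, 1L, 1L), post = c("batch_norm", "activation")),
    list(kind = "maxpool", window = 2L, stride = 2L),
    list(kind = "flatten"), list(kind = "fc")))
  tc <- train_config(learning_rate = 1e-3, iterations = 200L,
                     batch_size = 32L, seed = 7, checkpoint_every = 0L)
  fit <- train_network(cfg, list(x = x, y = y), tconf = tc)
  expect_lt(mean(utils::tail(fit$history$train_loss, 20)),
            mean(utils::head(fit$history$train_loss, 20)))
  fit2 <- train_network(cfg, list(x = x, y = y), tconf = tc)
  expect_identical(fit$history, fit2$history)
  expect_equal(fit$params$fc$W, fit2$params$fc$W)
})

test_that("smoothed training loss is non-increasing overall on a learnable task", {
  spec <- synthetic_spec()
  ds <- generate_dataset(spec, n_per_class = 30, seed = 77)
  ns <- normalize_split(ds$samples)
  tc <- train_config(iterations = 120L, seed = 5, checkpoint_every = 0L)
  fit <- train_network(toy_config_640(), ns$train, tconf = tc)
  sm <- stats::filter(fit$history$train_loss, rep(1 / 40, 40), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lte(utils::tail(sm, 1), sm[1] + 0.02)
})

test_that("cross-validation keeps folds disjoint, never splits a trial, and averages per-fold accuracy", {
  spec <- synthetic_spec()
  ds <- generate_dataset(spec, n_per_class = 8, seed = 13,
                         pairs = electrode_pairs()[c(2, 5), ])
  plan <- make_fold_plan(ds$trials, k = 2, seed = 4)
  tc <- train_config(iterations = 30L, seed = 9, checkpoint_every = 0L,
                     batch_size = 16L)
  cv <- run_cross_validation(ds$samples, plan, toy_config_640(), tconf = tc)
  expect_length(cv$reports, 2)
  # disjoint test trials whose union is the full trial set
  test_keys <- lapply(1:2, function(f) {
    unique(paste(plan$subject_id, plan$trial_index)[plan$fold == f])
  })
  expect_length(intersect(test_keys[[1]], test_keys[[2]]), 0)
  expect_setequal(unlist(test_keys),
                  paste(ds$trials$subject_id, ds$trials$trial_index))
  # both pair-samples of any test trial were evaluated together
  expect_equal(cv$reports[[1]]$n_samples %% 2, 0)
  expect_equal(cv$summary$global_accuracy,
               mean(vapply(cv$reports, `[[`, numeric(1), "global_accuracy")))
  # tidiers
  expect_equal(nrow(tidy(cv)), 2)
  expect_equal(glance(cv)$mean_accuracy, cv$summary$global_accuracy)
})

test_that("ablation flags remove their operators from the computation", {
  cfg <- network_config()
  p <- init_params(cfg, 1)
  # freshly initialized BN is a near-identity; give it non-trivial state
  p$bn1$run_mean <- runif(25, -1, 1)
  p$bn1$gamma <- runif(25, 0.5, 2)
  x <- matrix(rnorm(4 * 1280), 4, 1280)
  base <- net_forward(cfg, p, x)
  nobn <- net_forward(cfg, p, x, ablation = "no_batch_norm")
  expect_false(isTRUE(all.equal(base, nobn)))
  # dropout is inference-inert, so its ablation changes nothing at eval
  nodrop <- net_forward(cfg, p, x, ablation = "no_dropout")
  expect_equal(base, nodrop)
})

test_that("non-finite losses abort with a diagnostic naming the iteration", {
  cfg <- toy_config(dropout_p = 0)
  tc <- train_config(iterations = 50L, seed = 2, batch_size = 8L,
                     checkpoint_every = 0L)
  set.seed(1)
  x <- matrix(rnorm(16 * 40), 16, 40)
  x[3, 7] <- NaN
  y <- sample(1:4, 16, TRUE)
  expect_error(
    suppressWarnings(train_network(cfg, list(x = x, y = y), tconf = tc)),
    "diverged at iteration")
})
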