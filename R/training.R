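#' Mean cross-entropy of predicted class probabilities
#'
#' @param probs `n x k` matrix of class probabilities (rows summing to 1).
#' @param labels Integer class indices in `1..k`, or a factor.
#' @param eps Probability floor guarding `log(0)`.
#' @return Non-negative scalar, the mean negative log-probability assigned to
#'   the true class.
#' @examples
#' cross_entropy_loss(matrix(0.25, 3, 4), c(1, 2, 3))  # log(4)
#' @export
cross_entropy_loss <- function(probs, labels, eps = 1e-12) {
  if (is.factor(labels)) labels <- as.integer(labels)
  stopifnot(nrow(probs) == length(labels), all(labels >= 1),
            all(labels <= ncol(probs)))
  p_true <- probs[cbind(seq_along(labels), labels)]
  -mean(log(pmax(p_true, eps)))
}

#' Training configuration
#'
#' Defaults follow the study design the network was built for: Adam with a
#' learning rate of 1e-5 run for 2,000 mini-batch iterations.  The batch size
#' and the Adam moment constants are conventional choices.
#'
#' @param learning_rate Adam step size.
#' @param iterations Number of mini-batch gradient steps.
#' @param batch_size Samples per mini-batch.
#' @param beta1,beta2,epsilon Adam first/second-moment decays and stabilizer.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param ablation Character subset of `c("no_dropout", "no_batch_norm")`;
#'   the named operators become identities.
#' @param checkpoint_every Evaluate the held-out set every this many
#'   iterations (0 disables checkpoints).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, iterations = 2000L,
                         batch_size = 64L, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 1L,
                         ablation = character(), checkpoint_every = 20L) {
  stopifnot(learning_rate > 0, iterations > 0, batch_size >= 2,
            all(ablation %in% c("no_dropout", "no_batch_norm")))
  structure(list(learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed), ablation = ablation,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

# Trainable leaves per parameter site (running BN moments are state).
trainable_leaves <- function(site) intersect(names(site), c("W", "b", "gamma", "beta"))

adam_init_state <- function(params) {
  lapply(params, function(site) {
    st <- list()
    for (leaf in trainable_leaves(site)) {
      st[[leaf]] <- list(m = site[[leaf]] * 0, v = site[[leaf]] * 0)
    }
    st
  })
}

#' One Adam update step
#'
#' Standard bias-corrected first/second-moment adaptive update, applied to
#' every trainable leaf (convolution/FC weights and biases, batch-norm scale
#' and shift).  Deterministic given its inputs.
#'
#' @param params Parameter list (as from [init_params()]).
#' @param grads Gradient list with the same structure.
#' @param state Moment state from a previous call, or `NULL` to start at zero.
#' @param t Step counter (1-based) used for bias correction.
#' @param config A [train_config()].
#' @return List with updated `params` and `state`.
#' @export
adam_update <- function(params, grads, state, t, config) {
  if (is.null(state)) state <- adam_init_state(params)
  lr <- config$learning_rate; b1 <- config$beta1; b2 <- config$beta2
  eps <- config$epsilon
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (site in names(grads)) {
    for (leaf in names(grads[[site]])) {
      g <- grads[[site]][[leaf]]
      st <- state[[site]][[leaf]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g * g
      params[[site]][[leaf]] <- params[[site]][[leaf]] -
        lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      state[[site]][[leaf]] <- st
    }
  }
  list(params = params, state = state)
}

# Loss and gradients for one mini-batch through the fused compiled engine.
# Dropout masks are drawn here from R's RNG (one Bernoulli per sample and
# channel, prescaled by 1/(1-p)), matching the reference path's draw order.
net_loss_grad <- function(net, params, X, y, training = TRUE,
                          ablation = character()) {
  cfg <- net$config
  cp <- net_cprog(net, ablation)
  p <- cfg$dropout_p
  n <- nrow(X)
  masks <- lapply(cp$mask_sites, function(ms) {
    matrix((stats::runif(n * ms$C) >= p) / (1 - p), n, ms$C)
  })
  pf <- lapply(cp$param_sites, function(s) params[[s]])
  r <- cpp_net_run(cp$prog, pf, X, as.integer(y), masks, training, TRUE,
                   cfg$leaky_slope, cfg$bn_epsilon)
  grads <- r$grads
  names(grads) <- cp$param_sites
  if (training) {
    mom <- cfg$bn_momentum
    for (i in seq_along(cp$prog)) {
      st <- r$bn_stats[[i]]
      if (!is.null(st)) {
        site <- cp$param_sites[cp$prog[[i]]$pidx + 1L]
        params[[site]]$run_mean <- mom * params[[site]]$run_mean +
          (1 - mom) * st$mean
        params[[site]]$run_var <- mom * params[[site]]$run_var +
          (1 - mom) * st$var
      }
    }
  }
  list(loss = r$loss, grads = grads, params = params)
}

# Same computation through the layer-by-layer double-precision reference
# path; kept for validation and used by tests as the engine cross-check.
net_loss_grad_ref <- function(net, params, X, y, training = TRUE,
                              ablation = character()) {
  fw <- net_forward_flat(net, params, X, training = training,
                         ablation = ablation, with_cache = TRUE)
  probs <- softmax_rows(fw$logits)
  loss <- cross_entropy_loss(probs, y)
  onehot <- matrix(0, nrow(probs), ncol(probs))
  onehot[cbind(seq_along(y), as.integer(y))] <- 1
  dZ <- (probs - onehot) / nrow(probs)
  grads <- net_backward_flat(net, fw$params, fw$caches, dZ, ablation = ablation)
  list(loss = loss, grads = grads, params = fw$params)
}

#' Train the network on a set of pair samples
#'
#' Runs `iterations` Adam steps over a seeded, shuffled mini-batch stream
#' (reshuffled each epoch), optionally tracking held-out loss/accuracy at a
#' fixed checkpoint cadence.  Inputs are expected to be normalized already
#' (see [normalize_split()]).  Fully reproducible given the seed.
#'
#' @param config A [network_config()].
#' @param train_data Either a samples tibble (see [assemble_dataset()]) or a
#'   list with `x` (`n x features` matrix) and `y` (factor/integer labels).
#' @param test_data Optional held-out set in the same form.
#' @param tconf A [train_config()].
#' @return A `paircnn_fit` object: `params`, `history` tibble (iteration,
#'   train_loss, and at checkpoints test_loss/test_accuracy), the configs,
#'   and the task levels.
#' @export
train_network <- function(config, train_data, test_data = NULL,
                          tconf = train_config()) {
  net <- compile_network(config)
  tr <- as_xy(train_data, config)
  te <- if (!is.null(test_data)) as_xy(test_data, config) else NULL
  n <- nrow(tr$x)

  rs <- local_seed(tconf$seed)
  on.exit(restore_seed(rs), add = TRUE)
  params <- init_params(config, seed = tconf$seed)
  state <- NULL
  bs <- min(tconf$batch_size, n)

  perm <- sample.int(n)
  pos <- 1L
  hist_loss <- numeric(tconf$iterations)
  ck_it <- integer(0); ck_loss <- numeric(0); ck_acc <- numeric(0)

  for (t in seq_len(tconf$iterations)) {
    if (pos + bs - 1L > n) { perm <- sample.int(n); pos <- 1L }
    idx <- perm[pos:(pos + bs - 1L)]
    pos <- pos + bs
    lg <- net_loss_grad(net, params, tr$x[idx, , drop = FALSE], tr$y[idx],
                        training = TRUE, ablation = tconf$ablation)
    if (!is.finite(lg$loss)) {
      stop(sprintf("training diverged at iteration %d (loss = %g)", t, lg$loss),
           call. = FALSE)
    }
    params <- lg$params   # BN running moments updated during forward
    upd <- adam_update(params, lg$grads, state, t, tconf)
    params <- upd$params; state <- upd$state
    hist_loss[t] <- lg$loss

    if (!is.null(te) && tconf$checkpoint_every > 0L &&
        (t %% tconf$checkpoint_every == 0L || t == tconf$iterations)) {
      pr <- net_infer(net, params, te$x, ablation = tconf$ablation)
      ck_it <- c(ck_it, t)
      ck_loss <- c(ck_loss, cross_entropy_loss(pr, te$y))
      ck_acc <- c(ck_acc, mean(max.col(pr, ties.method = "first") ==
                                 as.integer(te$y)))
    }
  }

  history <- tibble::tibble(iteration = seq_len(tconf$iterations),
                            train_loss = hist_loss)
  if (length(ck_it)) {
    history <- dplyr::left_join(
      history,
      tibble::tibble(iteration = ck_it, test_loss = ck_loss,
                     test_accuracy = ck_acc),
      by = "iteration")
  }
  structure(list(params = params, history = history, config = config,
                 train_config = tconf, task_levels = tr$levels),
            class = "paircnn_fit")
}

#' @export
print.paircnn_fit <- function(x, ...) {
  cat("<paircnn_fit>", nrow(x$history), "iterations; final train loss",
      signif(utils::tail(x$history$train_loss, 1), 4), "\n")
  if ("test_accuracy" %in% names(x$history)) {
    acc <- utils::tail(stats::na.omit(x$history$test_accuracy), 1)
    cat("  last checkpoint held-out accuracy:", signif(acc, 4), "\n")
  }
  invisible(x)
}

#' Predict class probabilities from a trained fit
#'
#' @param object A `paircnn_fit`.
#' @param newdata Samples tibble or `list(x=, y=)` or bare feature matrix.
#' @param ... Unused.
#' @return `n x n_classes` probability matrix with task levels as colnames.
#' @export
predict.paircnn_fit <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else as_xy(newdata, object$config)$x
  pr <- net_forward(object$config, object$params, x, training = FALSE,
                    ablation = object$train_config$ablation)
  colnames(pr) <- object$task_levels
  pr
}

# Coerce a samples tibble or list(x, y) into the matrix form the net eats.
as_xy <- function(data, config) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$x)) {
    y <- data$y
    lev <- if (is.factor(y)) levels(y) else as.character(seq_len(config$n_classes))
    return(list(x = as.matrix(data$x),
                y = if (is.factor(y)) y else factor(lev[y], levels = lev),
                levels = lev))
  }
  if (is.data.frame(data)) {
    stopifnot(all(c("data", "task") %in% names(data)))
    D <- prod(config$input_shape)
    x <- matrix(0, nrow(data), D)
    dl <- data$data
    for (i in seq_len(nrow(data))) x[i, ] <- as.vector(dl[[i]])
    y <- data$task
    if (!is.factor(y)) y <- factor(y)
    return(list(x = x, y = y, levels = levels(y)))
  }
  stop("train/test data must be a samples tibble or list(x =, y =)", call. = FALSE)
}

#' Run trial-wise k-fold cross-validation
#'
#' Trains one independent model per fold (fresh initialization, fresh batch
#' stream, per-fold seed offset) on the training folds and evaluates on the
#' held-out fold.  Splitting is by whole trial — all pair-samples of a trial
#' stay on one side — and train/test are normalized with training-set
#' statistics only.
#'
#' @param samples Samples tibble from [assemble_dataset()].
#' @param fold_plan Fold plan from [make_fold_plan()].
#' @param config A [network_config()].
#' @param tconf A [train_config()]; fold `f` trains with seed
#'   `tconf$seed + f`.
#' @param folds Which folds to run (default: all in the plan).
#' @param track_test Evaluate held-out loss at checkpoints during training.
#' @return A `paircnn_cv` object: list of per-fold `metrics_report`s, the
#'   averaged report, and the per-fold fits' histories.
#' @export
run_cross_validation <- function(samples, fold_plan, config,
                                 tconf = train_config(), folds = NULL,
                                 track_test = FALSE) {
  stopifnot(all(c("subject_id", "trial_index") %in% names(fold_plan)))
  key <- paste(samples$subject_id, samples$trial_index)
  fold_of <- fold_plan$fold[match(key, paste(fold_plan$subject_id,
                                             fold_plan$trial_index))]
  if (anyNA(fold_of)) stop("some samples are missing from the fold plan",
                           call. = FALSE)
  all_folds <- sort(unique(fold_plan$fold))
  if (is.null(folds)) folds <- all_folds

  reports <- list(); histories <- list()
  for (f in folds) {
    train_s <- samples[fold_of != f, , drop = FALSE]
    test_s <- samples[fold_of == f, , drop = FALSE]
    if (nrow(test_s) == 0L) stop(sprintf("fold %d has an empty test set", f),
                                 call. = FALSE)
    ns <- normalize_split(train_s, test_s)
    fc <- tconf
    fc$seed <- tconf$seed + f
    fit <- train_network(config, ns$train,
                         test_data = if (track_test) ns$test else NULL,
                         tconf = fc)
    probs <- predict(fit, ns$test)
    rep <- metrics_report(ns$test$task, probs)
    rep$provenance <- list(fold = f, n_train = nrow(train_s),
                           n_test = nrow(test_s), seed = fc$seed)
    reports[[as.character(f)]] <- rep
    histories[[as.character(f)]] <- fit$history
  }
  structure(list(reports = reports,
                 summary = aggregate_reports(reports),
                 histories = histories, folds = folds),
            class = "paircnn_cv")
}

#' @export
print.paircnn_cv <- function(x, ...) {
  cat("<paircnn_cv>", length(x$reports), "folds; mean held-out accuracy",
      signif(x$summary$global_accuracy, 4), "\n")
  invisible(x)
}
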