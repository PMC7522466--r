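#' Default layer stack of the pair-sample network
#'
#' Five convolutions (four temporal, one spatial) interleaved with four
#' non-overlapping max poolings, a flatten, and a fully connected output
#' layer.  Each convolution lists its post-operations in the order they are
#' applied: the first (temporal) and third convolutions use activation then
#' spatial dropout; the second (spatial, which collapses the two-electrode
#' axis) and fifth use batch normalization then activation; the fourth uses
#' all three.
#'
#' Kernels are `[k_time, k_space, in_channels, out_channels]`; strides are
#' `[1, s_time, s_space, 1]`; all padding is VALID.
#'
#' @return A list of layer specifications consumed by [network_config()].
#' @export
default_layers <- function() {
  list(
    list(kind = "conv", kernel = c(11L, 1L, 1L, 25L), stride = c(1L, 1L, 1L, 1L),
         post = c("activation", "spatial_dropout")),
    list(kind = "conv", kernel = c(1L, 2L, 25L, 25L), stride = c(1L, 1L, 1L, 1L),
         post = c("batch_norm", "activation")),
    list(kind = "maxpool", window = 3L, stride = 3L),
    list(kind = "conv", kernel = c(11L, 1L, 25L, 50L), stride = c(1L, 1L, 1L, 1L),
         post = c("activation", "spatial_dropout")),
    list(kind = "maxpool", window = 3L, stride = 3L),
    list(kind = "conv", kernel = c(11L, 1L, 50L, 100L), stride = c(1L, 1L, 1L, 1L),
         post = c("batch_norm", "activation", "spatial_dropout")),
    list(kind = "maxpool", window = 3L, stride = 3L),
    list(kind = "conv", kernel = c(11L, 1L, 100L, 200L), stride = c(1L, 1L, 1L, 1L),
         post = c("batch_norm", "activation")),
    list(kind = "maxpool", window = 2L, stride = 2L),
    list(kind = "flatten"),
    list(kind = "fc")
  )
}

#' Network architecture configuration
#'
#' Describes the separated temporal/spatial convolutional network: the layer
#' stack, input shape (time samples x electrodes), number of output classes,
#' and the scalar hyperparameters of the activation, dropout and batch
#' normalization operators.
#'
#' @param input_shape Length-2 integer vector `c(time, electrodes)`; the
#'   default `c(640, 2)` is one 4 s epoch at 160 Hz from one electrode pair.
#' @param n_classes Number of output classes (4 motor-imagery tasks).
#' @param leaky_slope Negative-branch slope of the leaky ReLU.
#' @param dropout_p Spatial-dropout drop probability (0.5 = "50% dropout").
#' @param bn_epsilon Batch-normalization variance floor.
#' @param bn_momentum Exponential momentum of the BN running moments.
#' @param init Weight initialization: `"fixed"` draws all convolution/FC
#'   weights from a centered Gaussian with standard deviation `init_sd` (the
#'   small-constant-scale convention this architecture family traditionally
#'   uses; batch normalization makes the forward pass insensitive to the
#'   conv-weight scale, and the small scale is what makes the slow fixed
#'   learning-rate schedule effective).  `"he"` scales by `sqrt(2/fan_in)`.
#' @param init_sd Standard deviation for `init = "fixed"`.
#' @param layers Layer stack; defaults to [default_layers()].
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_shape = c(640L, 2L), n_classes = 4L,
                           leaky_slope = 0.01, dropout_p = 0.5,
                           bn_epsilon = 1e-5, bn_momentum = 0.9,
                           init = c("fixed", "he"), init_sd = 0.01,
                           layers = default_layers()) {
  stopifnot(length(input_shape) == 2L, all(input_shape >= 1L), n_classes >= 2L,
            dropout_p >= 0, dropout_p < 1, bn_epsilon > 0, init_sd > 0)
  structure(
    list(input_shape = as.integer(input_shape), n_classes = as.integer(n_classes),
         leaky_slope = leaky_slope, dropout_p = dropout_p,
         bn_epsilon = bn_epsilon, bn_momentum = bn_momentum,
         init = match.arg(init), init_sd = init_sd,
         layers = layers, plan_cache = new.env(parent = emptyenv())),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  tr <- shape_trace(x)
  cat("<network_config> input", paste(x$input_shape, collapse = " x "),
      "->", x$n_classes, "classes;", sum(tr$type == "conv"), "conv,",
      sum(tr$type == "maxpool"), "maxpool;",
      format(count_parameters(x), big.mark = ","), "parameters\n")
  print(tr, n = Inf)
  invisible(x)
}

#' Symbolic shape trace of a network configuration
#'
#' Propagates the input shape through every layer without allocating any
#' tensors, reporting the `(1, time, space, channels)` size after each layer
#' exactly as an architecture table would list it.
#'
#' @param config A [network_config()].
#' @return A tibble with columns `layer`, `type`, `shape` (list of integer
#'   vectors) and `size` (the printed form).  The first row is the input; the
#'   flatten and fully connected rows report flat feature counts.
#' @export
shape_trace <- function(config) {
  stopifnot(inherits(config, "network_config"))
  shp <- c(config$input_shape, 1L)   # (T, S, C)
  rows <- list(tibble::tibble(layer = "input", type = "input",
                              shape = list(config$input_shape),
                              size = paste(config$input_shape, collapse = " x ")))
  n_conv <- 0L; n_pool <- 0L
  for (ly in config$layers) {
    if (ly$kind == "conv") {
      n_conv <- n_conv + 1L
      pl <- conv_plan(shp, ly$kernel, ly$stride)
      shp <- pl$out_shape
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = paste0("conv", n_conv), type = "conv",
        shape = list(c(1L, shp)),
        size = sprintf("(1, %d, %d, %d)", shp[1], shp[2], shp[3]))
    } else if (ly$kind == "maxpool") {
      n_pool <- n_pool + 1L
      pl <- pool_plan(shp, ly$window, ly$stride)
      shp <- pl$out_shape
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = paste0("maxpool", n_pool), type = "maxpool",
        shape = list(c(1L, shp)),
        size = sprintf("(1, %d, %d, %d)", shp[1], shp[2], shp[3]))
    } else if (ly$kind == "flatten") {
      flat <- prod(shp)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = "flatten", type = "flatten", shape = list(flat),
        size = as.character(flat))
      shp <- c(flat, 1L, 1L)
    } else if (ly$kind == "fc") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = "fc", type = "fc", shape = list(config$n_classes),
        size = as.character(config$n_classes))
      shp <- c(config$n_classes, 1L, 1L)
    } else {
      stop("unknown layer kind: ", ly$kind, call. = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

#' Count learnable parameters of a configuration
#'
#' Sums kernel volume x output channels plus biases for every convolution,
#' the weight matrix and bias of the fully connected layer, and the
#' per-channel scale and shift of every batch-normalization site (running
#' moments are state, not parameters).
#'
#' @param config A [network_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  net <- compile_network(config)
  tot <- 0L
  for (op in net$ops) {
    if (op$op == "conv") tot <- tot + op$plan$K * op$plan$cout + op$plan$cout
    if (op$op == "bn") tot <- tot + 2L * op$C
    if (op$op == "fc") tot <- tot + op$n_in * op$n_out + op$n_out
  }
  tot
}

# Compile a network_config into a flat list of primitive ops with gather
# plans precomputed.  Cached in the config's environment (plans depend only
# on feature shapes, not on batch size).
compile_network <- function(config) {
  cache <- config$plan_cache
  if (!is.null(cache$net)) return(cache$net)
  shp <- c(config$input_shape, 1L)
  ops <- list()
  n_conv <- 0L; n_bn <- 0L
  add <- function(op) ops[[length(ops) + 1L]] <<- op
  for (ly in config$layers) {
    if (ly$kind == "conv") {
      n_conv <- n_conv + 1L
      pl <- conv_plan(shp, ly$kernel, ly$stride)
      add(list(op = "conv", plan = pl, param = paste0("conv", n_conv)))
      shp <- pl$out_shape
      for (po in ly$post) {
        if (po == "batch_norm") {
          n_bn <- n_bn + 1L
          add(list(op = "bn", TS = shp[1] * shp[2], C = shp[3],
                   param = paste0("bn", n_bn)))
        } else if (po == "activation") {
          add(list(op = "act"))
        } else if (po == "spatial_dropout") {
          add(list(op = "sdrop", TS = shp[1] * shp[2], C = shp[3]))
        } else stop("unknown post-op: ", po, call. = FALSE)
      }
    } else if (ly$kind == "maxpool") {
      pl <- pool_plan(shp, ly$window, ly$stride)
      add(list(op = "pool", plan = pl))
      shp <- pl$out_shape
    } else if (ly$kind == "flatten") {
      # activations are already flat matrices; nothing to do
    } else if (ly$kind == "fc") {
      add(list(op = "fc", n_in = prod(shp), n_out = config$n_classes,
               param = "fc"))
      shp <- c(config$n_classes, 1L, 1L)
    }
  }
  net <- list(ops = ops, input_dim = prod(config$input_shape),
              n_classes = config$n_classes, config = config)
  cache$net <- net
  net
}

# Build the C++ op program for the fused engine, honouring ablations.
# Cached per (config, ablation) in the config environment.
net_cprog <- function(net, ablation = character()) {
  cfg <- net$config
  no_drop <- "no_dropout" %in% ablation || cfg$dropout_p == 0
  use_bn <- !("no_batch_norm" %in% ablation)
  key <- paste0("prog_", as.integer(no_drop), as.integer(use_bn))
  cache <- cfg$plan_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  prog <- list(); param_sites <- character(0); mask_sites <- list()
  add <- function(x) prog[[length(prog) + 1L]] <<- x
  for (op in net$ops) {
    if (op$op == "conv") {
      param_sites <- c(param_sites, op$param)
      add(list(kind = 0L, gi = op$plan$gi0, K = op$plan$K, P = op$plan$P,
               D = op$plan$in_dim, pidx = length(param_sites) - 1L))
    } else if (op$op == "bn") {
      if (use_bn) {
        param_sites <- c(param_sites, op$param)
        add(list(kind = 1L, TS = op$TS, C = op$C,
                 pidx = length(param_sites) - 1L))
      }
    } else if (op$op == "act") {
      add(list(kind = 2L))
    } else if (op$op == "sdrop") {
      m <- -1L
      if (!no_drop) {
        mask_sites[[length(mask_sites) + 1L]] <- list(TS = op$TS, C = op$C)
        m <- length(mask_sites) - 1L
      }
      add(list(kind = 3L, TS = op$TS, C = op$C, midx = m))
    } else if (op$op == "pool") {
      add(list(kind = 4L, gi = op$plan$gi0, K = op$plan$K, P = op$plan$P,
               D = op$plan$in_dim))
    } else if (op$op == "fc") {
      param_sites <- c(param_sites, op$param)
      add(list(kind = 5L, pidx = length(param_sites) - 1L))
    }
  }
  out <- list(prog = prog, param_sites = param_sites, mask_sites = mask_sites)
  cache[[key]] <- out
  out
}

# Inference through the fused engine, chunked to bound the im2col workspace.
net_infer <- function(net, params, X, ablation = character(), chunk = 256L) {
  cp <- net_cprog(net, ablation)
  pf <- lapply(cp$param_sites, function(s) params[[s]])
  n <- nrow(X)
  out <- matrix(0, n, net$n_classes)
  for (start in seq.int(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    r <- cpp_net_run(cp$prog, pf, X[start:end, , drop = FALSE], integer(0),
                     list(), FALSE, FALSE, net$config$leaky_slope,
                     net$config$bn_epsilon)
    out[start:end, ] <- r$probs
  }
  out
}

#' Initialize network parameters
#'
#' Convolution and fully connected weights are drawn from a centered
#' Gaussian whose scale follows the configuration (`init` / `init_sd`, see
#' [network_config()]); biases are zero; batch-normalization sites start at
#' `gamma = 1, beta = 0` with running moments (0, 1).
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the draws.
#' @return A named list of parameter sites (`conv1` ... `fc`, `bn1` ...),
#'   class `network_params`.
#' @export
init_params <- function(config, seed = 1L) {
  net <- compile_network(config)
  params <- list()
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  fixed <- identical(config$init, "fixed")
  for (op in net$ops) {
    if (op$op == "conv") {
      sd <- if (fixed) config$init_sd else sqrt(2 / op$plan$K)
      params[[op$param]] <- list(
        W = matrix(stats::rnorm(op$plan$K * op$plan$cout, sd = sd),
                   op$plan$K, op$plan$cout),
        b = numeric(op$plan$cout))
    } else if (op$op == "bn") {
      params[[op$param]] <- list(gamma = rep(1, op$C), beta = numeric(op$C),
                                 run_mean = numeric(op$C), run_var = rep(1, op$C))
    } else if (op$op == "fc") {
      sd <- if (fixed) config$init_sd else sqrt(2 / op$n_in)
      params[[op$param]] <- list(
        W = matrix(stats::rnorm(op$n_in * op$n_out, sd = sd), op$n_in, op$n_out),
        b = numeric(op$n_out))
    }
  }
  structure(params, class = "network_params")
}

# Save/restore the global RNG so seeded helpers do not disturb callers.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Forward pass on flat n x D input.  training = TRUE draws dropout masks from
# the current RNG stream and updates BN running moments (returned in $params).
# with_cache = TRUE retains everything backprop needs.
net_forward_flat <- function(net, params, X, training = FALSE,
                             ablation = character(), with_cache = FALSE) {
  if (ncol(X) != net$input_dim) {
    stop(sprintf("input has %d features, network expects %d", ncol(X),
                 net$input_dim), call. = FALSE)
  }
  cfg <- net$config
  drop_p <- if ("no_dropout" %in% ablation) 0 else cfg$dropout_p
  use_bn <- !("no_batch_norm" %in% ablation)
  caches <- vector("list", length(net$ops))
  n <- nrow(X)
  for (i in seq_along(net$ops)) {
    op <- net$ops[[i]]
    if (op$op == "conv") {
      pr <- params[[op$param]]
      r <- conv_forward(X, op$plan, pr$W, pr$b, cache = with_cache)
      if (with_cache) caches[[i]] <- list(Xc = r$Xc)
      X <- r$out
    } else if (op$op == "bn") {
      if (use_bn) {
        pr <- params[[op$param]]
        r <- bn_forward(X, op$TS, op$C, pr$gamma, pr$beta, cfg$bn_epsilon,
                        training, pr$run_mean, pr$run_var, cfg$bn_momentum,
                        cache = with_cache)
        if (training) {
          params[[op$param]]$run_mean <- r$run_mean
          params[[op$param]]$run_var <- r$run_var
        }
        if (with_cache) caches[[i]] <- list(Xhat = r$Xhat, istd = r$istd)
        X <- r$out
      }
    } else if (op$op == "act") {
      if (with_cache) caches[[i]] <- list(X_pre = X)
      X <- leaky_forward(X, cfg$leaky_slope)
    } else if (op$op == "sdrop") {
      r <- sdrop_forward(X, op$TS, op$C, drop_p, training)
      if (with_cache) caches[[i]] <- list(scale = r$scale)
      X <- r$out
    } else if (op$op == "pool") {
      r <- maxpool_forward(X, op$plan, cache = with_cache)
      if (with_cache) caches[[i]] <- list(amax = r$amax)
      X <- r$out
    } else if (op$op == "fc") {
      pr <- params[[op$param]]
      if (with_cache) caches[[i]] <- list(Xin = X)
      X <- X %*% pr$W + rep(pr$b, each = n)
    }
  }
  list(logits = X, caches = caches, params = params)
}

# Backward pass from d(loss)/d(logits).  Returns gradients for every
# trainable leaf, mirroring the params structure.
net_backward_flat <- function(net, params, caches, dZ,
                              ablation = character()) {
  cfg <- net$config
  use_bn <- !("no_batch_norm" %in% ablation)
  grads <- list()
  for (i in rev(seq_along(net$ops))) {
    op <- net$ops[[i]]
    if (op$op == "fc") {
      pr <- params[[op$param]]
      Xin <- caches[[i]]$Xin
      grads[[op$param]] <- list(W = crossprod(Xin, dZ), b = colSums(dZ))
      dZ <- tcrossprod(dZ, pr$W)
    } else if (op$op == "pool") {
      dZ <- maxpool_backward(dZ, op$plan, caches[[i]]$amax)
    } else if (op$op == "sdrop") {
      dZ <- sdrop_backward(dZ, op$TS, op$C, caches[[i]]$scale)
    } else if (op$op == "act") {
      dZ <- leaky_backward(dZ, caches[[i]]$X_pre, cfg$leaky_slope)
    } else if (op$op == "bn") {
      if (use_bn) {
        pr <- params[[op$param]]
        r <- bn_backward(dZ, op$TS, op$C, pr$gamma, caches[[i]]$Xhat,
                         caches[[i]]$istd)
        grads[[op$param]] <- list(gamma = r$dgamma, beta = r$dbeta)
        dZ <- r$dX
      }
    } else if (op$op == "conv") {
      pr <- params[[op$param]]
      # the input-layer convolution never needs a gradient w.r.t. the data
      r <- conv_backward(dZ, op$plan, pr$W, caches[[i]]$Xc, want_dx = i > 1L)
      grads[[op$param]] <- list(W = r$dW, b = r$db)
      if (i > 1L) dZ <- r$dX
    }
  }
  grads
}

#' Run the network forward on a batch of pair samples
#'
#' @param config A [network_config()].
#' @param params Parameters from [init_params()] or a trained fit.
#' @param batch Either an `[n, time, space]` array, an `[n, time, space,
#'   1]` array, or a pre-flattened `n x (time*space)` matrix.
#' @param training Training-mode flag: draws dropout masks and uses batch
#'   moments for batch normalization.  With `training = FALSE` the map is
#'   deterministic.
#' @param ablation Character subset of `c("no_dropout", "no_batch_norm")`.
#' @param engine `"fast"` runs the fused single-precision compiled engine the
#'   trainer uses; `"reference"` runs the layer-by-layer double-precision
#'   path.  The two agree to single-precision tolerance.
#' @return `n x n_classes` matrix of class probabilities (rows sum to 1).
#' @export
net_forward <- function(config, params, batch, training = FALSE,
                        ablation = character(),
                        engine = c("fast", "reference")) {
  engine <- match.arg(engine)
  net <- compile_network(config)
  X <- flatten_batch(batch, config$input_shape)
  if (engine == "fast" && !training) {
    return(net_infer(net, params, X, ablation = ablation))
  }
  out <- net_forward_flat(net, params, X, training = training,
                          ablation = ablation)
  softmax_rows(out$logits)
}

flatten_batch <- function(batch, input_shape) {
  d <- dim(batch)
  D <- prod(input_shape)
  if (is.null(d) || length(d) == 2L) {
    X <- as.matrix(batch)
    if (ncol(X) != D) stop("flattened batch has wrong feature count", call. = FALSE)
    X
  } else {
    if (!all(d[2:3] == input_shape) || (length(d) == 4L && d[4] != 1L)) {
      stop(sprintf("batch shape [%s] does not match input_shape [%s]",
                   paste(d[-1], collapse = ", "),
                   paste(input_shape, collapse = ", ")), call. = FALSE)
    }
    dim(batch) <- c(d[1], D)
    batch
  }
}
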