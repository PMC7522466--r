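# Independent reference implementations used as oracles.  These deliberately
# use plain nested loops / exhaustive counting, not the package's own code
# paths.

# Direct evaluation of the convolution sum: y[m,n,co] =
# sum_{i,j,ci} x[m+i, n+j, ci] * w[i, j, ci, co] + b[co], VALID, stride 1.
oracle_conv <- function(x, w, b) {
  # x: [T, S, C]; w: [kt, ks, cin, cout]
  dT <- dim(x)[1]; dS <- dim(x)[2]
  kt <- dim(w)[1]; ks <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  to <- dT - kt + 1L; so <- dS - ks + 1L
  y <- array(0, c(to, so, cout))
  for (m in seq_len(to)) for (n in seq_len(so)) for (co in seq_len(cout)) {
    acc <- b[co]
    for (i in seq_len(kt)) for (j in seq_len(ks)) for (ci in seq_len(cin)) {
      acc <- acc + x[m + i - 1L, n + j - 1L, ci] * w[i, j, ci, co]
    }
    y[m, n, co] <- acc
  }
  y
}

# AUC as the Mann-Whitney pair-counting probability that a positive
# outranks a negative, ties counted one half.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Small network configuration for fast exact tests.  He-scaled init keeps
# pre-activations away from the leaky-ReLU kink, so finite-difference
# probes of the gradient do not straddle the nondifferentiable point.
toy_config <- function(dropout_p = 0.5) {
  network_config(
    input_shape = c(20L, 2L), dropout_p = dropout_p, init = "he",
    layers = list(
      list(kind = "conv", kernel = c(5L, 1L, 1L, 3L),
           stride = c(1L, 1L, 1L, 1L),
           post = c("activation", "spatial_dropout")),
      list(kind = "conv", kernel = c(1L, 2L, 3L, 3L),
           stride = c(1L, 1L, 1L, 1L),
           post = c("batch_norm", "activation")),
      list(kind = "maxpool", window = 2L, stride = 2L),
      list(kind = "flatten"),
      list(kind = "fc")))
}

# Bandpower + multinomial logistic reference classifier (never the CNN).
oracle_bandpower_accuracy <- function(samples, train_frac = 0.75, seed = 1) {
  feats <- bandpower_features(samples$data)
  y <- samples$task
  set.seed(seed)
  idx <- sample(nrow(feats), round(train_frac * nrow(feats)))
  fit <- nnet::multinom(y ~ ., data = cbind(feats, y = y)[idx, ],
                        trace = FALSE)
  mean(predict(fit, feats[-idx, ]) == y[-idx])
}

# Slimmed-down stack for full-size 640 x 2 inputs: same operator types as
# the default architecture but far fewer channels, for fast pipeline tests.
toy_config_640 <- function(dropout_p = 0.5) {
  network_config(
    input_shape = c(640L, 2L), dropout_p = dropout_p,
    layers = list(
      list(kind = "conv", kernel = c(11L, 1L, 1L, 4L),
           stride = c(1L, 1L, 1L, 1L),
           post = c("activation", "spatial_dropout")),
      list(kind = "conv", kernel = c(1L, 2L, 4L, 4L),
           stride = c(1L, 1L, 1L, 1L),
           post = c("batch_norm", "activation")),
      list(kind = "maxpool", window = 9L, stride = 9L),
      list(kind = "conv", kernel = c(11L, 1L, 4L, 8L),
           stride = c(1L, 1L, 1L, 1L),
           post = c("batch_norm", "activation", "spatial_dropout")),
      list(kind = "maxpool", window = 6L, stride = 6L),
      list(kind = "flatten"),
      list(kind = "fc")))
}
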