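#' Valid-padding 2-D convolution over [batch, time, space, channel] tensors
#'
#' Applies a linear cross-correlation with no border padding: each output
#' position is the dot product of a kernel-sized patch of the input with the
#' kernel weights, plus a per-output-channel bias.  The activation function is
#' deliberately not applied here; it is a separate operator so post-convolution
#' operations (batch normalization, activation, spatial dropout) can be
#' composed in any order.
#'
#' @param x 4-D numeric array `[batch, time, space, in_channels]`.
#' @param w 4-D kernel array `[k_time, k_space, in_channels, out_channels]`.
#' @param b Numeric bias vector, one entry per output channel.
#' @param stride Length-4 stride `[1, s_time, s_space, 1]`.
#' @return 4-D array `[batch, t_out, s_out, out_channels]` with
#'   `t_out = floor((time - k_time)/s_time) + 1` and similarly for space.
#' @examples
#' x <- array(rnorm(2 * 20 * 2 * 1), c(2, 20, 2, 1))
#' w <- array(rnorm(11 * 1 * 1 * 4), c(11, 1, 1, 4))
#' dim(conv2d_valid(x, w, rep(0, 4)))  # 2 x 10 x 2 x 4
#' @export
conv2d_valid <- function(x, w, b, stride = c(1, 1, 1, 1)) {
  stopifnot(length(dim(x)) == 4L, length(dim(w)) == 4L)
  dx <- dim(x); dw <- dim(w)
  plan <- conv_plan(dx[2:4], dw, stride)
  X <- x
  dim(X) <- c(dx[1], prod(dx[2:4]))
  W <- w
  dim(W) <- c(prod(dw[1:3]), dw[4])
  Y <- conv_forward(X, plan, W, b)$out
  dim(Y) <- c(dx[1], plan$out_shape)
  Y
}

#' Leaky rectified linear activation
#'
#' Elementwise `f(x) = x` for `x > 0` and `f(x) = slope * x` otherwise.  The
#' small negative slope keeps gradients alive for inactive units, avoiding the
#' dying-ReLU / vanishing-gradient problem in deep stacks.
#'
#' @param x Numeric vector or array.
#' @param slope Negative-branch slope (default 0.01).
#' @return Object of the same shape as `x`.
#' @examples
#' leaky_relu(c(-1, 0, 3.5))
#' @export
leaky_relu <- function(x, slope = 0.01) {
  d <- dim(x)
  y <- leaky_forward(matrix(as.numeric(x), nrow = 1L), slope)
  y <- as.numeric(y)
  if (!is.null(d)) dim(y) <- d
  y
}

#' Spatial (channel-wise) dropout
#'
#' During training, zeroes entire feature maps — all time/space positions of a
#' channel within a sample — with probability `p`, and rescales survivors by
#' `1/(1-p)` (inverted dropout), so the inference-time pass is the identity.
#' Dropping whole maps rather than single elements decorrelates feature maps,
#' which element-wise dropout fails to do when neighbouring samples of a
#' signal are strongly correlated.
#'
#' @param x 4-D array `[batch, time, space, channels]`.
#' @param p Drop probability in `[0, 1)`.
#' @param training If `FALSE` the input is returned unchanged.
#' @return Array of the same shape as `x`.  Uses R's global random number
#'   generator; seed with [set.seed()] for reproducibility.
#' @export
spatial_dropout <- function(x, p, training = TRUE) {
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)
  X <- x
  dim(X) <- c(d[1], prod(d[2:4]))
  Y <- sdrop_forward(X, d[2] * d[3], d[4], p, training)$out
  dim(Y) <- d
  Y
}

#' Batch normalization over the channel axis
#'
#' In training mode, standardizes each channel by the mean and (1/N) variance
#' pooled over the batch and all time/space positions, then applies the
#' learned affine transform `gamma * x_hat + beta`.  Running moments, if
#' supplied, are updated with exponential momentum and used verbatim in
#' inference mode.
#'
#' @param x 4-D array `[batch, time, space, channels]` or a 2-D matrix
#'   `[batch, channels]`.
#' @param gamma,beta Per-channel scale and shift vectors.
#' @param eps Variance floor added before the square root.
#' @param training Use batch moments (`TRUE`) or running moments (`FALSE`).
#' @param running_mean,running_var Optional running moments; required when
#'   `training = FALSE`.
#' @param momentum Exponential decay for the running-moment update.
#' @return Array shaped like `x`, with updated running moments attached as
#'   attributes `running_mean` and `running_var`.
#' @export
batch_norm <- function(x, gamma, beta, eps = 1e-5, training = TRUE,
                       running_mean = NULL, running_var = NULL,
                       momentum = 0.9) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    X <- as.matrix(x); TS <- 1L; C <- ncol(X)
  } else {
    stopifnot(length(d) == 4L)
    X <- x
    dim(X) <- c(d[1], prod(d[2:4]))
    TS <- d[2] * d[3]; C <- d[4]
  }
  if (is.null(running_mean)) running_mean <- numeric(C)
  if (is.null(running_var)) running_var <- rep(1, C)
  if (!training && (length(running_mean) != C || length(running_var) != C)) {
    stop("inference mode requires running moments of length n_channels",
         call. = FALSE)
  }
  r <- bn_forward(X, TS, C, gamma, beta, eps, training,
                  running_mean, running_var, momentum)
  Y <- r$out
  if (!is.null(d)) dim(Y) <- d
  attr(Y, "running_mean") <- r$run_mean
  attr(Y, "running_var") <- r$run_var
  Y
}

#' Valid-padding max pooling over the time axis
#'
#' Takes the maximum over non-overlapping temporal windows, independently for
#' each (space, channel) lane.  A remainder shorter than the window is
#' truncated (VALID behaviour).
#'
#' @param x 4-D array `[batch, time, space, channels]`.
#' @param window Temporal window length (the `[1, w, 1, 1]` kernel's `w`).
#' @param stride Temporal stride; defaults to `window` (non-overlapping).
#' @return 4-D array with temporal length `floor((time - window)/stride) + 1`.
#' @export
max_pool <- function(x, window, stride = window) {
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)
  plan <- pool_plan(d[2:4], window, stride)
  X <- x
  dim(X) <- c(d[1], prod(d[2:4]))
  Y <- maxpool_forward(X, plan)$out
  dim(Y) <- c(d[1], plan$out_shape)
  Y
}

#' Softmax probabilities and argmax label
#'
#' Maps a score vector (or one row per sample) to the probability simplex and
#' returns the index of the most probable class, breaking ties towards the
#' lowest index.
#'
#' @param logits Numeric vector of class scores, or a matrix with one row per
#'   sample.
#' @return A list with `probs` (same shape as `logits`, rows summing to 1) and
#'   `label` (integer class index/indices).
#' @examples
#' softmax_predict(c(1, 2, 3, 4))
#' @export
softmax_predict <- function(logits) {
  vec <- is.null(dim(logits))
  Z <- if (vec) matrix(logits, nrow = 1L) else as.matrix(logits)
  P <- softmax_rows(Z)
  lab <- max.col(P, ties.method = "first")
  if (vec) list(probs = drop(P), label = lab[1L]) else list(probs = P, label = lab)
}
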