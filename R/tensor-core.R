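# Internal flat-tensor machinery.
#
# Activations live as n x (T*S*C) matrices: one row per sample, features
# flattened column-major over (time, space, channel), i.e. feature index
# = t + T*(s-1) + T*S*(c-1).  Convolution and pooling are expressed as a
# precomputed gather (im2col) followed by one BLAS matrix product; the
# gathers, GEMM glue and elementwise kernels are compiled (src/ops.cpp),
# while plans, orchestration and optimisation stay in R.

# Gather plan for a VALID convolution over a (T, S, C) input.
# kernel = c(kt, ks, cin, cout), stride = c(1, st, ss, 1).
conv_plan <- function(in_shape, kernel, stride) {
  T_in <- in_shape[1]; S_in <- in_shape[2]; C_in <- in_shape[3]
  kt <- kernel[1]; ks <- kernel[2]; cin <- kernel[3]; cout <- kernel[4]
  st <- stride[2]; ss <- stride[3]
  if (cin != C_in) {
    stop(sprintf("kernel expects %d input channels, input has %d", cin, C_in),
         call. = FALSE)
  }
  if (kt > T_in || ks > S_in) {
    stop(sprintf(
      "kernel [%d, %d] larger than input [%d, %d] under VALID padding",
      kt, ks, T_in, S_in), call. = FALSE)
  }
  t_out <- (T_in - kt) %/% st + 1L
  s_out <- (S_in - ks) %/% ss + 1L
  P <- t_out * s_out
  K <- kt * ks * C_in

  # output position p enumerates (t_out, s_out) column-major (time fastest)
  to <- rep(seq_len(t_out), times = s_out)
  so <- rep(seq_len(s_out), each = t_out)
  # patch element k enumerates (dt, ds, c) column-major, matching the
  # column-major flattening of a (kt, ks, cin) kernel array
  dt <- rep(seq_len(kt), times = ks * C_in)
  ds <- rep(rep(seq_len(ks), each = kt), times = C_in)
  ck <- rep(seq_len(C_in), each = kt * ks)

  tpos <- outer(dt, (to - 1L) * st, "+")             # K x P
  spos <- outer(ds, (so - 1L) * ss, "+")             # K x P
  gi <- as.vector(tpos + T_in * (spos - 1L) +
                    T_in * S_in * (ck - 1L))         # k fastest within p

  list(gi0 = as.integer(gi - 1L), K = K, P = P,
       in_shape = in_shape, in_dim = T_in * S_in * C_in,
       out_shape = c(t_out, s_out, cout), cout = cout)
}

# Gather plan for VALID max pooling over the time axis, applied
# independently per (space, channel) lane.  window/stride are scalars.
pool_plan <- function(in_shape, window, stride) {
  T_in <- in_shape[1]; S_in <- in_shape[2]; C_in <- in_shape[3]
  if (window > T_in) {
    stop(sprintf("pooling window %d larger than temporal length %d",
                 window, T_in), call. = FALSE)
  }
  t_out <- (T_in - window) %/% stride + 1L
  P <- t_out * S_in * C_in
  to <- rep(seq_len(t_out), times = S_in * C_in)
  sp <- rep(rep(seq_len(S_in), each = t_out), times = C_in)
  cp <- rep(seq_len(C_in), each = t_out * S_in)
  tpos <- outer(seq_len(window), (to - 1L) * stride, "+")     # w x P
  gi <- as.vector(tpos + T_in * rep(sp - 1L, each = window) +
                    T_in * S_in * rep(cp - 1L, each = window))
  list(gi0 = as.integer(gi - 1L), K = as.integer(window), P = P,
       in_shape = in_shape, in_dim = T_in * S_in * C_in,
       out_shape = c(t_out, S_in, C_in))
}

conv_forward <- function(X, plan, W, b, cache = FALSE) {
  cpp_conv_fwd(X, plan$gi0, W, b, plan$K, plan$P, cache)
}

conv_backward <- function(dY, plan, W, Xc, want_dx = TRUE) {
  cpp_conv_bwd(dY, Xc, W, plan$gi0, plan$K, plan$P, plan$in_dim, want_dx)
}

maxpool_forward <- function(X, plan, cache = FALSE) {
  cpp_pool_fwd(X, plan$gi0, plan$K, plan$P, cache)
}

maxpool_backward <- function(dY, plan, amax) {
  cpp_pool_bwd(dY, amax, plan$gi0, plan$K, plan$P, plan$in_dim)
}

# Batch normalization over the channel axis: statistics pooled over the
# batch and all (time, space) positions of each feature map.  TS is the
# number of positions per channel.  Variance uses the 1/N convention.
bn_forward <- function(X, TS, C, gamma, beta, eps, training,
                       run_mean, run_var, momentum, cache = FALSE) {
  if (training && nrow(X) < 2L) {
    stop("batch normalization needs a batch of at least 2 in training",
         call. = FALSE)
  }
  cpp_bn_fwd(X, TS, C, gamma, beta, eps, training, run_mean, run_var,
             momentum, cache)
}

bn_backward <- function(dY, TS, C, gamma, Xhat, istd) {
  cpp_bn_bwd(dY, Xhat, istd, gamma, TS, C)
}

# Spatial dropout: one Bernoulli draw per (sample, channel), zeroing the
# whole (time, space) feature map; survivors rescaled by 1/(1-p) so the
# inference pass needs no correction (inverted dropout).
sdrop_forward <- function(X, TS, C, p, training) {
  if (p < 0 || p >= 1) stop("dropout probability must be in [0, 1)", call. = FALSE)
  if (!training || p == 0) return(list(out = X, scale = NULL))
  n <- nrow(X)
  keep <- matrix(stats::runif(n * C) >= p, n, C)
  scale <- keep / (1 - p)
  list(out = cpp_scale_channels(X, scale, TS, C), scale = scale)
}

sdrop_backward <- function(dY, TS, C, scale) {
  if (is.null(scale)) return(dY)
  cpp_scale_channels(dY, scale, TS, C)
}

leaky_forward <- function(X, slope) cpp_leaky_fwd(as.matrix(X), slope)

leaky_backward <- function(dY, X_pre, slope) cpp_leaky_bwd(dY, X_pre, slope)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
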