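// Hot numerical kernels for the pair-sample network.
//
// Activations are n x (T*S*C) column-major matrices (one row per sample,
// features flattened over time, space, channel).  Convolution and pooling
// are an im2col gather (precomputed 0-based index vector gi, patch element
// fastest within output position) followed by a BLAS GEMM; backward passes
// are the exact adjoints.  All outputs are allocated as R matrices and
// computed in place through Armadillo views, so no extra copies are made.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat view(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// X (n x D) -> patch matrix (n*P) x K with out(i + n*p, k) = X(i, gi[k + K*p])
static void gather_into(const arma::mat& X, const arma::uvec& gi,
                        int K, int P, arma::mat& out) {
  const int n = X.n_rows;
  for (int k = 0; k < K; ++k) {
    double* oc = out.colptr(k);
    for (int p = 0; p < P; ++p) {
      std::memcpy(oc + (size_t)n * p,
                  X.colptr(gi[(size_t)k + (size_t)K * p]),
                  n * sizeof(double));
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_gather(NumericMatrix Xr, IntegerVector gi0, int K, int P) {
  arma::mat X = view(Xr);
  arma::uvec gi = as<arma::uvec>(gi0);
  NumericMatrix outr((int)X.n_rows * P, K);
  arma::mat out = view(outr);
  gather_into(X, gi, K, P, out);
  return outr;
}

// Adjoint of the gather: accumulate patch gradients back onto the input.
// [[Rcpp::export]]
NumericMatrix cpp_scatter(NumericMatrix dXc2r, IntegerVector gi0,
                          int K, int P, int D) {
  arma::mat dXc2 = view(dXc2r);
  arma::uvec gi = as<arma::uvec>(gi0);
  const int n = dXc2.n_rows / P;
  NumericMatrix dXr(n, D);
  arma::mat dX = view(dXr);
  for (int k = 0; k < K; ++k) {
    const double* oc = dXc2.colptr(k);
    for (int p = 0; p < P; ++p) {
      double* xc = dX.colptr(gi[(size_t)k + (size_t)K * p]);
      const double* src = oc + (size_t)n * p;
      for (int i = 0; i < n; ++i) xc[i] += src[i];
    }
  }
  return dXr;
}

// Convolution forward: gather, GEMM, bias.  Returns the n x (P*cout) output
// and (optionally) the patch matrix for the weight-gradient GEMM.
// [[Rcpp::export]]
List cpp_conv_fwd(NumericMatrix Xr, IntegerVector gi0, NumericMatrix Wr,
                  NumericVector br, int K, int P, bool keep_patches) {
  arma::mat X = view(Xr);
  arma::mat W = view(Wr);
  arma::uvec gi = as<arma::uvec>(gi0);
  const int n = X.n_rows, cout = W.n_cols;

  NumericMatrix Xcr(n * P, K);
  arma::mat Xc = view(Xcr);
  gather_into(X, gi, K, P, Xc);

  NumericMatrix Yr(n, P * cout);
  arma::mat Y(Yr.begin(), (size_t)n * P, cout, false, true);  // pre-reshape view
  Y = Xc * W;
  arma::rowvec b(br.begin(), cout, false, true);
  Y.each_row() += b;

  if (keep_patches) return List::create(_["out"] = Yr, _["Xc"] = Xcr);
  return List::create(_["out"] = Yr);
}

// Convolution backward: dW = Xc' dY2, db = colsums(dY2), and (optionally)
// dX scattered back from dY2 W'.
// [[Rcpp::export]]
List cpp_conv_bwd(NumericMatrix dYr, NumericMatrix Xcr, NumericMatrix Wr,
                  IntegerVector gi0, int K, int P, int D, bool want_dx) {
  arma::mat W = view(Wr);
  arma::mat Xc = view(Xcr);
  const int cout = W.n_cols;
  const int n = dYr.nrow();
  arma::mat dY2(dYr.begin(), (size_t)n * P, cout, false, true);

  NumericMatrix dWr(K, cout);
  arma::mat dW = view(dWr);
  dW = Xc.t() * dY2;
  NumericVector dbr(cout);
  arma::rowvec db(dbr.begin(), cout, false, true);
  db = arma::sum(dY2, 0);

  if (!want_dx) return List::create(_["dW"] = dWr, _["db"] = dbr);

  arma::mat dXc2 = dY2 * W.t();                 // (n*P) x K
  arma::uvec gi = as<arma::uvec>(gi0);
  NumericMatrix dXr(n, D);
  arma::mat dX = view(dXr);
  for (int k = 0; k < K; ++k) {
    const double* oc = dXc2.colptr(k);
    for (int p = 0; p < P; ++p) {
      double* xc = dX.colptr(gi[(size_t)k + (size_t)K * p]);
      const double* src = oc + (size_t)n * p;
      for (int i = 0; i < n; ++i) xc[i] += src[i];
    }
  }
  return List::create(_["dW"] = dWr, _["db"] = dbr, _["dX"] = dXr);
}

// Max pooling forward over precomputed windows; amax records the winning
// patch element (1-based) for the backward scatter.
// [[Rcpp::export]]
List cpp_pool_fwd(NumericMatrix Xr, IntegerVector gi0, int K, int P,
                  bool keep_argmax) {
  arma::mat X = view(Xr);
  arma::uvec gi = as<arma::uvec>(gi0);
  const int n = X.n_rows;
  NumericMatrix Yr(n, P);
  arma::mat Y = view(Yr);
  IntegerMatrix Ar(keep_argmax ? n : 0, keep_argmax ? P : 0);
  for (int p = 0; p < P; ++p) {
    double* yc = Y.colptr(p);
    const double* x0 = X.colptr(gi[(size_t)K * p]);
    std::memcpy(yc, x0, n * sizeof(double));
    int* ac = keep_argmax ? &Ar(0, p) : nullptr;
    if (keep_argmax) std::fill(ac, ac + n, 1);
    for (int k = 1; k < K; ++k) {
      const double* xc = X.colptr(gi[(size_t)k + (size_t)K * p]);
      for (int i = 0; i < n; ++i) {
        if (xc[i] > yc[i]) { yc[i] = xc[i]; if (ac) ac[i] = k + 1; }
      }
    }
  }
  if (keep_argmax) return List::create(_["out"] = Yr, _["amax"] = Ar);
  return List::create(_["out"] = Yr);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(NumericMatrix dYr, IntegerMatrix Ar,
                           IntegerVector gi0, int K, int P, int D) {
  arma::mat dY = view(dYr);
  arma::uvec gi = as<arma::uvec>(gi0);
  const int n = dY.n_rows;
  NumericMatrix dXr(n, D);
  arma::mat dX = view(dXr);
  for (int p = 0; p < P; ++p) {
    const double* dc = dY.colptr(p);
    const int* ac = &Ar(0, p);
    for (int i = 0; i < n; ++i) {
      dX(i, gi[(size_t)(ac[i] - 1) + (size_t)K * p]) += dc[i];
    }
  }
  return dXr;
}

// Batch normalization over the channel axis: X viewed as (n*TS) x C.
// Training uses batch moments (1/N variance); inference the running ones.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericMatrix Xr, int TS, int C, NumericVector gammar,
                NumericVector betar, double eps, bool training,
                NumericVector run_meanr, NumericVector run_varr,
                double momentum, bool keep_cache) {
  const int n = Xr.nrow();
  const size_t N = (size_t)n * TS;
  arma::mat M(Xr.begin(), N, C, false, true);
  arma::vec gamma(gammar.begin(), C, false, true);
  arma::vec beta(betar.begin(), C, false, true);

  arma::vec mu(C), va(C);
  NumericVector new_mean(C), new_var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      const double* x = M.colptr(c);
      double s = 0, s2 = 0;
      for (size_t i = 0; i < N; ++i) { s += x[i]; s2 += x[i] * x[i]; }
      mu[c] = s / N;
      va[c] = std::max(s2 / N - mu[c] * mu[c], 0.0);
      new_mean[c] = momentum * run_meanr[c] + (1 - momentum) * mu[c];
      new_var[c] = momentum * run_varr[c] + (1 - momentum) * va[c];
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = run_meanr[c];
      va[c] = run_varr[c];
      new_mean[c] = run_meanr[c];
      new_var[c] = run_varr[c];
    }
  }

  NumericMatrix Yr(n, TS * C);
  arma::mat Y(Yr.begin(), N, C, false, true);
  NumericMatrix Xhatr(keep_cache ? n : 0, keep_cache ? TS * C : 0);
  NumericVector istdr(C);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(va[c] + eps);
    istdr[c] = is;
    const double g = gamma[c], b = beta[c], m = mu[c];
    const double* x = M.colptr(c);
    double* y = Y.colptr(c);
    double* xh = keep_cache ? Xhatr.begin() + (size_t)c * N : nullptr;
    for (size_t i = 0; i < N; ++i) {
      const double z = (x[i] - m) * is;
      if (xh) xh[i] = z;
      y[i] = g * z + b;
    }
  }
  List out = List::create(_["out"] = Yr, _["run_mean"] = new_mean,
                          _["run_var"] = new_var, _["istd"] = istdr);
  if (keep_cache) out["Xhat"] = Xhatr;
  return out;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix dYr, NumericMatrix Xhatr, NumericVector istdr,
                NumericVector gammar, int TS, int C) {
  const int n = dYr.nrow();
  const size_t N = (size_t)n * TS;
  arma::mat dY(dYr.begin(), N, C, false, true);
  arma::mat Xhat(Xhatr.begin(), N, C, false, true);
  NumericMatrix dXr(n, TS * C);
  arma::mat dX(dXr.begin(), N, C, false, true);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.colptr(c);
    const double* xh = Xhat.colptr(c);
    double s_dy = 0, s_dyxh = 0;
    for (size_t i = 0; i < N; ++i) { s_dy += dy[i]; s_dyxh += dy[i] * xh[i]; }
    dgamma[c] = s_dyxh;
    dbeta[c] = s_dy;
    const double g = gammar[c], is = istdr[c];
    const double m1 = s_dy / N, m2 = s_dyxh / N;
    double* dx = dX.colptr(c);
    for (size_t i = 0; i < N; ++i) {
      dx[i] = g * is * (dy[i] - m1 - xh[i] * m2);
    }
  }
  return List::create(_["dX"] = dXr, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Leaky ReLU; backward recomputes the branch from the cached pre-activation.
// [[Rcpp::export]]
NumericMatrix cpp_leaky_fwd(NumericMatrix Xr, double slope) {
  NumericMatrix Yr(Xr.nrow(), Xr.ncol());
  const double* x = Xr.begin();
  double* y = Yr.begin();
  const size_t len = (size_t)Xr.nrow() * Xr.ncol();
  for (size_t i = 0; i < len; ++i) y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return Yr;
}

// [[Rcpp::export]]
NumericMatrix cpp_leaky_bwd(NumericMatrix dYr, NumericMatrix Xr, double slope) {
  NumericMatrix dXr(dYr.nrow(), dYr.ncol());
  const double* dy = dYr.begin();
  const double* x = Xr.begin();
  double* dx = dXr.begin();
  const size_t len = (size_t)dYr.nrow() * dYr.ncol();
  for (size_t i = 0; i < len; ++i) dx[i] = x[i] > 0 ? dy[i] : slope * dy[i];
  return dXr;
}

// Multiply each (sample, channel) feature map by a scalar: spatial dropout
// forward and backward share this.
// [[Rcpp::export]]
NumericMatrix cpp_scale_channels(NumericMatrix Xr, NumericMatrix scaler,
                                 int TS, int C) {
  const int n = Xr.nrow();
  NumericMatrix Yr(n, TS * C);
  for (int c = 0; c < C; ++c) {
    const double* sc = &scaler(0, c);
    for (int t = 0; t < TS; ++t) {
      const double* x = &Xr(0, c * TS + t);
      double* y = &Yr(0, c * TS + t);
      for (int i = 0; i < n; ++i) y[i] = x[i] * sc[i];
    }
  }
  return Yr;
}
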