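// Fused single-precision execution engine for the whole network.
//
// One .Call runs forward (and optionally backward) over the compiled op
// program, keeping every activation as an Armadillo float matrix and doing
// all elementwise work in place, so the pass is limited by GEMM throughput
// rather than by repeated R-level memory traffic.  Parameters arrive and
// gradients leave as doubles; batch-norm statistics are accumulated in
// double.  Dropout masks are drawn on the R side (R's RNG owns all
// randomness) and passed in with the 1/(1-p) rescale already applied.
//
// Op kinds: 0 conv, 1 batch norm, 2 leaky ReLU, 3 spatial dropout,
// 4 max pool, 5 fully connected.

#include <RcppArmadillo.h>
#include <chrono>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// lightweight profiling accumulators (seconds per op kind, fwd/bwd)
static double prof_fwd[8] = {0}, prof_bwd[8] = {0}, prof_misc[4] = {0};
static inline double now_s() {
  return std::chrono::duration<double>(
    std::chrono::steady_clock::now().time_since_epoch()).count();
}

// [[Rcpp::export]]
NumericVector cpp_net_prof(bool reset) {
  NumericVector out(20);
  for (int i = 0; i < 8; ++i) { out[i] = prof_fwd[i]; out[8 + i] = prof_bwd[i]; }
  for (int i = 0; i < 4; ++i) out[16 + i] = prof_misc[i];
  if (reset) {
    std::fill(prof_fwd, prof_fwd + 8, 0.0);
    std::fill(prof_bwd, prof_bwd + 8, 0.0);
    std::fill(prof_misc, prof_misc + 4, 0.0);
  }
  out;
  return out;
}

typedef arma::fmat FM;

static FM as_fmat(NumericMatrix m) {
  FM out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

static NumericMatrix as_rmat(const FM& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

static NumericVector as_rvec(const arma::fvec& v) {
  NumericVector out(v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

static void gather_f(const FM& X, const int* gi, int K, int P, FM& out) {
  const int n = X.n_rows;
  for (int k = 0; k < K; ++k) {
    float* oc = out.colptr(k);
    for (int p = 0; p < P; ++p) {
      std::memcpy(oc + (size_t)n * p, X.colptr(gi[(size_t)k + (size_t)K * p]),
                  n * sizeof(float));
    }
  }
}

static void scatter_f(const FM& dXc2, const int* gi, int K, int P, FM& dX) {
  const int n = dX.n_rows;
  for (int k = 0; k < K; ++k) {
    const float* oc = dXc2.colptr(k);
    for (int p = 0; p < P; ++p) {
      float* xc = dX.colptr(gi[(size_t)k + (size_t)K * p]);
      const float* src = oc + (size_t)n * p;
      for (int i = 0; i < n; ++i) xc[i] += src[i];
    }
  }
}

// [[Rcpp::export]]
List cpp_net_run(List prog, List params, NumericMatrix Xr, IntegerVector y,
                 List masks, bool training, bool want_grads,
                 double leaky_slope, double bn_eps) {
  const int n_ops = prog.size();
  const float slope = (float)leaky_slope;
  const int n = Xr.nrow();

  std::vector<FM> acts(n_ops + 1);       // acts[i+1] = output of op i
  std::vector<FM> cache_xc(n_ops);       // conv patch matrices
  std::vector<FM> cache_xhat(n_ops);     // BN standardized inputs
  std::vector<arma::fvec> cache_istd(n_ops);
  std::vector<arma::imat> cache_amax(n_ops);
  List bn_stats(n_ops);                  // batch moments per BN op

  acts[0] = as_fmat(Xr);

  // ---------------- forward ----------------
  for (int i = 0; i < n_ops; ++i) {
    List op = prog[i];
    const int kind = op["kind"];
    const double t_op = now_s();
    FM& X = acts[i];
    if (kind == 0) {                     // conv
      IntegerVector gi = op["gi"]; const int K = op["K"], P = op["P"];
      List pr = params[(int)op["pidx"]];
      FM W = as_fmat(pr["W"]);
      arma::fvec b(W.n_cols);
      { NumericVector br = pr["b"];
        std::copy(br.begin(), br.end(), b.begin()); }
      FM Xc((size_t)n * P, K);
      gather_f(X, gi.begin(), K, P, Xc);
      FM Y2 = Xc * W;                    // (n*P) x cout
      Y2.each_row() += b.t();
      Y2.reshape(n, (size_t)P * W.n_cols);
      acts[i + 1] = std::move(Y2);
      if (want_grads) cache_xc[i] = std::move(Xc);
    } else if (kind == 1) {              // batch norm
      const int TS = op["TS"], C = op["C"];
      const size_t N = (size_t)n * TS;
      List pr = params[(int)op["pidx"]];
      NumericVector gamma = pr["gamma"], beta = pr["beta"];
      NumericVector rmean = pr["run_mean"], rvar = pr["run_var"];
      arma::fvec mu(C), istd(C);
      NumericVector mu_out(C), va_out(C);
      for (int c = 0; c < C; ++c) {
        double m, v;
        if (training) {
          const float* x = X.colptr(0) + (size_t)c * N;
          double s = 0, s2 = 0;
          for (size_t t = 0; t < N; ++t) { s += x[t]; s2 += (double)x[t] * x[t]; }
          m = s / N;
          v = std::max(s2 / N - m * m, 0.0);
        } else {
          m = rmean[c]; v = rvar[c];
        }
        mu_out[c] = m; va_out[c] = v;
        mu[c] = (float)m;
        istd[c] = (float)(1.0 / std::sqrt(v + bn_eps));
      }
      FM Y = std::move(X);               // transform in place; the
      FM Xh;                             // standardized copy is the cache
      if (want_grads) Xh.set_size(n, (size_t)TS * C);
      for (int c = 0; c < C; ++c) {
        float* yp = Y.colptr(0) + (size_t)c * N;
        float* xh = want_grads ? Xh.colptr(0) + (size_t)c * N : nullptr;
        const float m = mu[c], is = istd[c];
        const float g = (float)(double)gamma[c], bb = (float)(double)beta[c];
        for (size_t t = 0; t < N; ++t) {
          const float z = (yp[t] - m) * is;
          if (xh) xh[t] = z;
          yp[t] = g * z + bb;
        }
      }
      acts[i + 1] = std::move(Y);
      if (want_grads) { cache_xhat[i] = std::move(Xh); cache_istd[i] = istd; }
      if (training) bn_stats[i] = List::create(_["mean"] = mu_out,
                                               _["var"] = va_out);
    } else if (kind == 2) {              // leaky ReLU
      // In place: nothing re-reads the pre-activation.  The backward pass
      // needs the output's sign, which any following in-place spatial
      // dropout preserves; only an (unconventional) act -> batch-norm
      // ordering would destroy it, so copy in that one case.
      bool next_bn = false;
      if (i + 1 < n_ops) {
        List nx = prog[i + 1];
        next_bn = (int)nx["kind"] == 1;
      }
      FM Y = next_bn ? X : std::move(X);
      float* yp = Y.begin();
      const size_t len = Y.n_elem;
      // branchless via min/max: ~50% of activations are negative, so a
      // conditional here would mispredict constantly
      for (size_t t = 0; t < len; ++t) {
        yp[t] = std::max(yp[t], 0.0f) + slope * std::min(yp[t], 0.0f);
      }
      acts[i + 1] = std::move(Y);
    } else if (kind == 3) {              // spatial dropout (mask prescaled)
      const int midx = op["midx"];
      if (midx < 0 || !training) { acts[i + 1] = std::move(X); continue; }
      const int TS = op["TS"], C = op["C"];
      NumericMatrix mk = masks[midx];
      FM Y = std::move(X);               // in place, mask cached separately
      for (int c = 0; c < C; ++c) {
        const double* sc = &mk(0, c);
        for (int t = 0; t < TS; ++t) {
          float* yp = Y.colptr((size_t)c * TS + t);
          for (int r = 0; r < n; ++r) yp[r] *= (float)sc[r];
        }
      }
      acts[i + 1] = std::move(Y);
    } else if (kind == 4) {              // max pool
      IntegerVector gi = op["gi"]; const int K = op["K"], P = op["P"];
      FM Y(n, P);
      arma::imat amax;
      if (want_grads) amax.set_size(n, P);
      for (int p = 0; p < P; ++p) {
        float* yc = Y.colptr(p);
        std::memcpy(yc, X.colptr(gi[(size_t)K * p]), n * sizeof(float));
        if (want_grads) {
          arma::sword* ac = amax.colptr(p);
          std::fill(ac, ac + n, 0);
        }
        for (int k = 1; k < K; ++k) {
          const float* xc = X.colptr(gi[(size_t)k + (size_t)K * p]);
          arma::sword* ac = want_grads ? amax.colptr(p) : nullptr;
          if (ac) {
            for (int r = 0; r < n; ++r) {   // branchless select (cmov)
              const bool gt = xc[r] > yc[r];
              yc[r] = gt ? xc[r] : yc[r];
              ac[r] = gt ? k : ac[r];
            }
          } else {
            for (int r = 0; r < n; ++r) yc[r] = std::max(yc[r], xc[r]);
          }
        }
      }
      acts[i + 1] = std::move(Y);
      if (want_grads) cache_amax[i] = std::move(amax);
    } else if (kind == 5) {              // fully connected
      List pr = params[(int)op["pidx"]];
      FM W = as_fmat(pr["W"]);
      arma::fvec b(W.n_cols);
      { NumericVector br = pr["b"];
        std::copy(br.begin(), br.end(), b.begin()); }
      FM Y = X * W;
      Y.each_row() += b.t();
      acts[i + 1] = std::move(Y);
    } else stop("unknown op kind");
    prof_fwd[kind] += now_s() - t_op;
  }

  // softmax probabilities
  FM& logits = acts[n_ops];
  const int nc = logits.n_cols;
  FM probs = logits;
  for (int r = 0; r < n; ++r) {
    float mx = probs(r, 0);
    for (int c = 1; c < nc; ++c) mx = std::max(mx, probs(r, c));
    double s = 0;
    for (int c = 0; c < nc; ++c) { probs(r, c) = std::exp(probs(r, c) - mx); s += probs(r, c); }
    for (int c = 0; c < nc; ++c) probs(r, c) = (float)(probs(r, c) / s);
  }

  double loss = NA_REAL;
  if (y.size() > 0) {
    double s = 0;
    for (int r = 0; r < n; ++r) {
      s -= std::log(std::max((double)probs(r, y[r] - 1), 1e-12));
    }
    loss = s / n;
  }

  if (!want_grads) {
    return List::create(_["probs"] = as_rmat(probs), _["loss"] = loss,
                        _["bn_stats"] = bn_stats);
  }
  if (y.size() == 0) stop("gradients require labels");

  // ---------------- backward ----------------
  List grads(params.size());
  FM dZ = probs;
  for (int r = 0; r < n; ++r) dZ(r, y[r] - 1) -= 1.0f;
  dZ /= (float)n;

  for (int i = n_ops - 1; i >= 0; --i) {
    List op = prog[i];
    const int kind = op["kind"];
    const double t_op = now_s();
    if (kind == 5) {                     // fc
      List pr = params[(int)op["pidx"]];
      FM W = as_fmat(pr["W"]);
      FM dW = acts[i].t() * dZ;
      arma::fvec db = arma::sum(dZ, 0).t();
      grads[(int)op["pidx"]] = List::create(_["W"] = as_rmat(dW),
                                            _["b"] = as_rvec(db));
      dZ = dZ * W.t();
    } else if (kind == 4) {              // pool
      IntegerVector gi = op["gi"]; const int K = op["K"], P = op["P"];
      const int D = op["D"];
      FM dX(n, D, arma::fill::zeros);
      const arma::imat& amax = cache_amax[i];
      for (int p = 0; p < P; ++p) {
        const float* dc = dZ.colptr(p);
        const arma::sword* ac = amax.colptr(p);
        for (int r = 0; r < n; ++r) {
          dX(r, gi[(size_t)ac[r] + (size_t)K * p]) += dc[r];
        }
      }
      dZ = std::move(dX);
    } else if (kind == 3) {              // dropout
      const int midx = op["midx"];
      if (midx < 0 || !training) continue;
      const int TS = op["TS"], C = op["C"];
      NumericMatrix mk = masks[midx];
      for (int c = 0; c < C; ++c) {
        const double* sc = &mk(0, c);
        for (int t = 0; t < TS; ++t) {
          float* dp = dZ.colptr((size_t)c * TS + t);
          for (int r = 0; r < n; ++r) dp[r] *= (float)sc[r];
        }
      }
    } else if (kind == 2) {              // leaky ReLU (branch from output sign)
      // the output buffer may have been moved down an in-place chain;
      // sign-preserving ops (dropout) make the next surviving buffer valid
      int j = i + 1;
      while (j < n_ops && acts[j].n_elem == 0) ++j;
      const FM& out = acts[j];
      float* dp = dZ.begin();
      const float* op_ = out.begin();
      const size_t len = dZ.n_elem;
      for (size_t t = 0; t < len; ++t) {
        dp[t] = op_[t] > 0 ? dp[t] : dp[t] * slope;   // compiles to a select
      }
    } else if (kind == 1) {              // batch norm
      const int TS = op["TS"], C = op["C"];
      const size_t N = (size_t)n * TS;
      List pr = params[(int)op["pidx"]];
      NumericVector gamma = pr["gamma"];
      const FM& Xh = cache_xhat[i];
      const arma::fvec& istd = cache_istd[i];
      NumericVector dgamma(C), dbeta(C);
      FM dX(n, (size_t)TS * C);
      for (int c = 0; c < C; ++c) {
        const float* dy = dZ.colptr(0) + (size_t)c * N;
        const float* xh = Xh.colptr(0) + (size_t)c * N;
        double s_dy = 0, s_dyxh = 0;
        for (size_t t = 0; t < N; ++t) {
          s_dy += dy[t]; s_dyxh += (double)dy[t] * xh[t];
        }
        dgamma[c] = s_dyxh; dbeta[c] = s_dy;
        const float g = (float)(double)gamma[c], is = istd[c];
        const float m1 = (float)(s_dy / N), m2 = (float)(s_dyxh / N);
        float* dx = dX.colptr(0) + (size_t)c * N;
        for (size_t t = 0; t < N; ++t) {
          dx[t] = g * is * (dy[t] - m1 - xh[t] * m2);
        }
      }
      grads[(int)op["pidx"]] = List::create(_["gamma"] = dgamma,
                                            _["beta"] = dbeta);
      dZ = std::move(dX);
    } else if (kind == 0) {              // conv
      IntegerVector gi = op["gi"]; const int K = op["K"], P = op["P"];
      const int D = op["D"];
      List pr = params[(int)op["pidx"]];
      FM W = as_fmat(pr["W"]);
      const int cout = W.n_cols;
      // (n, P*cout) and (n*P, cout) share one column-major layout: alias
      FM dY2(dZ.memptr(), (size_t)n * P, cout, false, true);
      FM dW = cache_xc[i].t() * dY2;
      arma::fvec db = arma::sum(dY2, 0).t();
      grads[(int)op["pidx"]] = List::create(_["W"] = as_rmat(dW),
                                            _["b"] = as_rvec(db));
      if (i > 0) {                       // input layer needs no data gradient
        FM dXc2 = dY2 * W.t();
        FM dX(n, D, arma::fill::zeros);
        scatter_f(dXc2, gi.begin(), K, P, dX);
        dZ = std::move(dX);
      }
    }
    prof_bwd[kind] += now_s() - t_op;
  }

  return List::create(_["probs"] = as_rmat(probs), _["loss"] = loss,
                      _["grads"] = grads, _["bn_stats"] = bn_stats);
}
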