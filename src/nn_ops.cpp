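// Hot numerical kernels for the segment encoder. The matrix products
// themselves go through R's BLAS; these helpers do the single-pass
// layout work (im2col / col2im / axis reordering) that dominates when
// done with R-level array copies.
//
// Layouts follow R's column-major arrays: X is N x C x T (sample
// fastest), W is O x C x k, activations are N x O x T.

#include <Rcpp.h>
using namespace Rcpp;

// im2col with 'same' zero padding, stride 1:
// out is (N*T) x (C*k); row (n,t), column (c,j) holds X[n, c, t+j-pad]
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector X, IntegerVector dims, int k) {
  const int N = dims[0], C = dims[1], T = dims[2];
  const int pad = (k - 1) / 2;
  NumericMatrix out(N * T, C * k);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      double* col = &out(0, c * k + j);
      for (int t = 0; t < T; ++t) {
        const int ts = t + j - pad;
        double* op = col + static_cast<R_xlen_t>(N) * t;
        if (ts < 0 || ts >= T) {
          for (int n = 0; n < N; ++n) op[n] = 0.0;
        } else {
          const double* xp = &X[static_cast<R_xlen_t>(N) * (c + C * ts)];
          for (int n = 0; n < N; ++n) op[n] = xp[n];
        }
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col: dXc is (N*T) x (C*k) -> dX (N x C x T)
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dXc, IntegerVector dims, int k) {
  const int N = dims[0], C = dims[1], T = dims[2];
  const int pad = (k - 1) / 2;
  NumericVector dX(static_cast<R_xlen_t>(N) * C * T);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      const double* col = &dXc(0, c * k + j);
      for (int t = 0; t < T; ++t) {
        const int ts = t + j - pad;
        if (ts < 0 || ts >= T) continue;
        const double* ip = col + static_cast<R_xlen_t>(N) * t;
        double* op = &dX[static_cast<R_xlen_t>(N) * (c + C * ts)];
        for (int n = 0; n < N; ++n) op[n] += ip[n];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(N, C, T);
  return dX;
}

// (N*T) x O matrix (n fastest, then t) -> N x O x T array, adding bias
// [[Rcpp::export]]
NumericVector nt_o_to_not_cpp(NumericMatrix M, int N, int T, int O,
                              NumericVector b) {
  NumericVector out(static_cast<R_xlen_t>(N) * O * T);
  for (int o = 0; o < O; ++o) {
    const double* col = &M(0, o);
    for (int t = 0; t < T; ++t) {
      const double* ip = col + static_cast<R_xlen_t>(N) * t;
      double* op = &out[static_cast<R_xlen_t>(N) * (o + O * t)];
      const double bo = b[o];
      for (int n = 0; n < N; ++n) op[n] = ip[n] + bo;
    }
  }
  out.attr("dim") = IntegerVector::create(N, O, T);
  return out;
}

// N x O x T array -> (N*T) x O matrix (inverse of the above, no bias)
// [[Rcpp::export]]
NumericMatrix not_to_nt_o_cpp(NumericVector X, IntegerVector dims) {
  const int N = dims[0], O = dims[1], T = dims[2];
  NumericMatrix out(N * T, O);
  for (int o = 0; o < O; ++o) {
    double* col = &out(0, o);
    for (int t = 0; t < T; ++t) {
      const double* ip = &X[static_cast<R_xlen_t>(N) * (o + O * t)];
      double* op = col + static_cast<R_xlen_t>(N) * t;
      for (int n = 0; n < N; ++n) op[n] = ip[n];
    }
  }
  return out;
}

// width-2 stride-2 max pooling along T; winner mask kept for backward
// [[Rcpp::export]]
List pool2_fwd_cpp(NumericVector X, IntegerVector dims) {
  const int N = dims[0], C = dims[1], T = dims[2];
  const int To = T / 2;
  NumericVector out(static_cast<R_xlen_t>(N) * C * To);
  LogicalVector take_a(static_cast<R_xlen_t>(N) * C * To);
  for (int t = 0; t < To; ++t) {
    for (int c = 0; c < C; ++c) {
      const double* a = &X[static_cast<R_xlen_t>(N) * (c + C * (2 * t))];
      const double* b = &X[static_cast<R_xlen_t>(N) * (c + C * (2 * t + 1))];
      double* op = &out[static_cast<R_xlen_t>(N) * (c + C * t)];
      int* tp = &(LOGICAL(take_a)[static_cast<R_xlen_t>(N) * (c + C * t)]);
      for (int n = 0; n < N; ++n) {
        if (a[n] >= b[n]) { op[n] = a[n]; tp[n] = 1; }
        else { op[n] = b[n]; tp[n] = 0; }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, C, To);
  take_a.attr("dim") = IntegerVector::create(N, C, To);
  return List::create(_["out"] = out, _["take_a"] = take_a);
}

// scatter pooled gradients back to the unpooled time axis
// [[Rcpp::export]]
NumericVector pool2_bwd_cpp(NumericVector dout, LogicalVector take_a,
                            IntegerVector dims_out, int T_in) {
  const int N = dims_out[0], C = dims_out[1], To = dims_out[2];
  NumericVector dX(static_cast<R_xlen_t>(N) * C * T_in);
  for (int t = 0; t < To; ++t) {
    for (int c = 0; c < C; ++c) {
      const double* dp = &dout[static_cast<R_xlen_t>(N) * (c + C * t)];
      const int* tp = &(LOGICAL(take_a)[static_cast<R_xlen_t>(N) * (c + C * t)]);
      double* a = &dX[static_cast<R_xlen_t>(N) * (c + C * (2 * t))];
      double* b = &dX[static_cast<R_xlen_t>(N) * (c + C * (2 * t + 1))];
      for (int n = 0; n < N; ++n) {
        if (tp[n]) a[n] = dp[n]; else b[n] = dp[n];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(N, C, T_in);
  return dX;
}

// per-channel batch-norm statistics in one pass: mean and biased var
// over the N and T axes of an N x C x T array
// [[Rcpp::export]]
NumericMatrix bn_stats_cpp(NumericVector X, IntegerVector dims) {
  const int N = dims[0], C = dims[1], T = dims[2];
  NumericMatrix out(C, 2);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int t = 0; t < T; ++t) {
      const double* xp = &X[static_cast<R_xlen_t>(N) * (c + C * t)];
      for (int n = 0; n < N; ++n) { s += xp[n]; s2 += xp[n] * xp[n]; }
    }
    const double m = s / (static_cast<double>(N) * T);
    out(c, 0) = m;
    out(c, 1) = s2 / (static_cast<double>(N) * T) - m * m;
  }
  return out;
}

// batch-norm normalize + scale/shift in one pass; also emits Xhat
// [[Rcpp::export]]
List bn_apply_cpp(NumericVector X, IntegerVector dims, NumericVector mu,
                  NumericVector inv_sd, NumericVector gamma,
                  NumericVector beta) {
  const int N = dims[0], C = dims[1], T = dims[2];
  NumericVector out(static_cast<R_xlen_t>(N) * C * T);
  NumericVector xhat(static_cast<R_xlen_t>(N) * C * T);
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const double m = mu[c], is = inv_sd[c], g = gamma[c], bt = beta[c];
      const double* xp = &X[static_cast<R_xlen_t>(N) * (c + C * t)];
      double* hp = &xhat[static_cast<R_xlen_t>(N) * (c + C * t)];
      double* op = &out[static_cast<R_xlen_t>(N) * (c + C * t)];
      for (int n = 0; n < N; ++n) {
        const double h = (xp[n] - m) * is;
        hp[n] = h;
        op[n] = g * h + bt;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, C, T);
  xhat.attr("dim") = IntegerVector::create(N, C, T);
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// batch-norm backward (train mode uses batch-statistic coupling)
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dout, NumericVector xhat, IntegerVector dims,
                NumericVector inv_sd, NumericVector gamma, bool train) {
  const int N = dims[0], C = dims[1], T = dims[2];
  const double nt = static_cast<double>(N) * T;
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const double* dp = &dout[static_cast<R_xlen_t>(N) * (c + C * t)];
      const double* hp = &xhat[static_cast<R_xlen_t>(N) * (c + C * t)];
      double a = 0.0, b = 0.0;
      for (int n = 0; n < N; ++n) { a += dp[n]; b += dp[n] * hp[n]; }
      dbeta[c] += a;
      dgamma[c] += b;
    }
  }
  for (int c = 0; c < C; ++c) { s1[c] = dbeta[c] / nt; s2[c] = dgamma[c] / nt; }
  NumericVector dX(static_cast<R_xlen_t>(N) * C * T);
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const double g = gamma[c], is = inv_sd[c];
      const double m1 = s1[c] * g, m2 = s2[c] * g;
      const double* dp = &dout[static_cast<R_xlen_t>(N) * (c + C * t)];
      const double* hp = &xhat[static_cast<R_xlen_t>(N) * (c + C * t)];
      double* op = &dX[static_cast<R_xlen_t>(N) * (c + C * t)];
      if (train) {
        for (int n = 0; n < N; ++n)
          op[n] = is * (g * dp[n] - m1 - hp[n] * m2);
      } else {
        for (int n = 0; n < N; ++n) op[n] = is * g * dp[n];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(N, C, T);
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ReLU with retained mask
// [[Rcpp::export]]
List relu_fwd_cpp(NumericVector X) {
  const R_xlen_t n = X.size();
  NumericVector out(n);
  LogicalVector mask(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (X[i] > 0) { out[i] = X[i]; mask[i] = 1; }
  }
  out.attr("dim") = X.attr("dim");
  mask.attr("dim") = X.attr("dim");
  return List::create(_["out"] = out, _["mask"] = mask);
}

// broadcast the pooled gradient back across the time axis
// [[Rcpp::export]]
NumericVector gap_bwd_cpp(NumericMatrix dout, int T) {
  const int N = dout.nrow(), C = dout.ncol();
  NumericVector dX(static_cast<R_xlen_t>(N) * C * T);
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const double* dp = &dout(0, c);
      double* op = &dX[static_cast<R_xlen_t>(N) * (c + C * t)];
      for (int n = 0; n < N; ++n) op[n] = dp[n] / T;
    }
  }
  dX.attr("dim") = IntegerVector::create(N, C, T);
  return dX;
}
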