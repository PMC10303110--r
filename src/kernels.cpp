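// Hot numerical kernels: the three convolution types dominate training time,
// so their forward/backward passes live here. Layout conventions match the R
// side (column-major, feature axis first).

#include <Rcpp.h>
using namespace Rcpp;

// Temporal convolution on raw trials: x [C, T, B] (one input map, F filters
// of length k applied per channel, zero padded) -> y [F, C, T, B].
// [[Rcpp::export]]
NumericVector tconv_fwd_cpp(NumericVector x, int C, int T, int B,
                            NumericMatrix W, int left) {
  const int F = W.nrow(), k = W.ncol();
  NumericVector y(static_cast<R_xlen_t>(F) * C * T * B);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < T; ++t) {
        double *yo = yp + ((static_cast<R_xlen_t>(b) * T + t) * C + c) * F;
        for (int i = 0; i < k; ++i) {
          int ts = t + i - left;
          if (ts < 0 || ts >= T) continue;
          double xv = xp[(static_cast<R_xlen_t>(b) * T + ts) * C + c];
          const double *wc = &W(0, i);
          for (int f = 0; f < F; ++f) yo[f] += wc[f] * xv;
        }
      }
  y.attr("dim") = IntegerVector::create(F, C, T, B);
  return y;
}

// [[Rcpp::export]]
List tconv_bwd_cpp(NumericVector x, NumericVector dy, int C, int T, int B,
                   NumericMatrix W, int left) {
  const int F = W.nrow(), k = W.ncol();
  NumericMatrix dW(F, k);
  NumericVector dx(static_cast<R_xlen_t>(C) * T * B);
  const double *xp = x.begin(), *dyp = dy.begin();
  double *dxp = dx.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < T; ++t) {
        const double *dyo = dyp + ((static_cast<R_xlen_t>(b) * T + t) * C + c) * F;
        for (int i = 0; i < k; ++i) {
          int ts = t + i - left;
          if (ts < 0 || ts >= T) continue;
          R_xlen_t xi = (static_cast<R_xlen_t>(b) * T + ts) * C + c;
          double xv = xp[xi];
          double acc = 0.0;
          double *dwc = &dW(0, i);
          const double *wc = &W(0, i);
          for (int f = 0; f < F; ++f) {
            dwc[f] += dyo[f] * xv;
            acc += wc[f] * dyo[f];
          }
          dxp[xi] += acc;
        }
      }
  dx.attr("dim") = IntegerVector::create(C, T, B);
  return List::create(_["dW"] = dW, _["dx"] = dx);
}

// Depthwise spatial convolution: x [F, C, T, B], W [C, F, D] -> y [F*D, T, B].
// [[Rcpp::export]]
NumericVector depthwise_fwd_cpp(NumericVector x, int F, int C, int T, int B,
                                NumericVector W, int D) {
  NumericVector y(static_cast<R_xlen_t>(F) * D * T * B);
  const double *xp = x.begin(), *wp = W.begin();
  double *yp = y.begin();
  const R_xlen_t FD = static_cast<R_xlen_t>(F) * D;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      const double *xo = xp + (static_cast<R_xlen_t>(b) * T + t) * C * F;
      double *yo = yp + (static_cast<R_xlen_t>(b) * T + t) * FD;
      for (int f = 0; f < F; ++f)
        for (int m = 0; m < D; ++m) {
          double acc = 0.0;
          const double *wc = wp + (static_cast<R_xlen_t>(m) * F + f) * C;
          for (int c = 0; c < C; ++c) acc += wc[c] * xo[c * F + f];
          yo[f * D + m] = acc;
        }
    }
  y.attr("dim") = IntegerVector::create(F * D, T, B);
  return y;
}

// [[Rcpp::export]]
List depthwise_bwd_cpp(NumericVector x, NumericVector dy, int F, int C,
                       int T, int B, NumericVector W, int D) {
  NumericVector dW(static_cast<R_xlen_t>(C) * F * D);
  NumericVector dx(static_cast<R_xlen_t>(F) * C * T * B);
  const double *xp = x.begin(), *wp = W.begin(), *dyp = dy.begin();
  double *dWp = dW.begin(), *dxp = dx.begin();
  const R_xlen_t FD = static_cast<R_xlen_t>(F) * D;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      const double *xo = xp + (static_cast<R_xlen_t>(b) * T + t) * C * F;
      const double *dyo = dyp + (static_cast<R_xlen_t>(b) * T + t) * FD;
      double *dxo = dxp + (static_cast<R_xlen_t>(b) * T + t) * C * F;
      for (int f = 0; f < F; ++f)
        for (int m = 0; m < D; ++m) {
          double g = dyo[f * D + m];
          double *dwc = dWp + (static_cast<R_xlen_t>(m) * F + f) * C;
          const double *wc = wp + (static_cast<R_xlen_t>(m) * F + f) * C;
          for (int c = 0; c < C; ++c) {
            dwc[c] += g * xo[c * F + f];
            dxo[c * F + f] += g * wc[c];
          }
        }
    }
  dW.attr("dim") = IntegerVector::create(C, F, D);
  dx.attr("dim") = IntegerVector::create(F, C, T, B);
  return List::create(_["dW"] = dW, _["dx"] = dx);
}

// General 1-D convolution over sequence features: x [Fin, T, B],
// W [Fout, Fin*k] (column index i*Fin + fin), shift[i] = signed time offset
// of tap i (input index t + shift[i]) -> y [Fout, T, B].
// [[Rcpp::export]]
NumericVector conv1d_fwd_cpp(NumericVector x, int Fin, int T, int B,
                             NumericMatrix W, IntegerVector shift) {
  const int Fout = W.nrow(), k = shift.size();
  NumericVector y(static_cast<R_xlen_t>(Fout) * T * B);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      double *yo = yp + (static_cast<R_xlen_t>(b) * T + t) * Fout;
      for (int i = 0; i < k; ++i) {
        int ts = t + shift[i];
        if (ts < 0 || ts >= T) continue;
        const double *xo = xp + (static_cast<R_xlen_t>(b) * T + ts) * Fin;
        for (int fin = 0; fin < Fin; ++fin) {
          double xv = xo[fin];
          if (xv == 0.0) continue;
          const double *wc = &W(0, i * Fin + fin);
          for (int fo = 0; fo < Fout; ++fo) yo[fo] += wc[fo] * xv;
        }
      }
    }
  y.attr("dim") = IntegerVector::create(Fout, T, B);
  return y;
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(NumericVector x, NumericVector dy, int Fin, int T, int B,
                    NumericMatrix W, IntegerVector shift) {
  const int Fout = W.nrow(), k = shift.size();
  NumericMatrix dW(Fout, Fin * k);
  NumericVector dx(static_cast<R_xlen_t>(Fin) * T * B);
  const double *xp = x.begin(), *dyp = dy.begin();
  double *dxp = dx.begin();
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      const double *dyo = dyp + (static_cast<R_xlen_t>(b) * T + t) * Fout;
      for (int i = 0; i < k; ++i) {
        int ts = t + shift[i];
        if (ts < 0 || ts >= T) continue;
        const double *xo = xp + (static_cast<R_xlen_t>(b) * T + ts) * Fin;
        double *dxo = dxp + (static_cast<R_xlen_t>(b) * T + ts) * Fin;
        for (int fin = 0; fin < Fin; ++fin) {
          double xv = xo[fin];
          double *dwc = &dW(0, i * Fin + fin);
          const double *wc = &W(0, i * Fin + fin);
          double acc = 0.0;
          for (int fo = 0; fo < Fout; ++fo) {
            dwc[fo] += dyo[fo] * xv;
            acc += wc[fo] * dyo[fo];
          }
          dxo[fin] += acc;
        }
      }
    }
  dx.attr("dim") = IntegerVector::create(Fin, T, B);
  return List::create(_["dW"] = dW, _["dx"] = dx);
}

// Batch normalization over the feature axis (dim 1): x viewed as [F, M].
// If use_batch is true the statistics are computed from x, otherwise the
// supplied running statistics are used. Returns y, xhat and the stats.
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, int F, NumericVector gamma,
                NumericVector beta, NumericVector mean_in,
                NumericVector var_in, double eps, bool use_batch) {
  const R_xlen_t M = x.size() / F;
  NumericVector mu(F), var(F);
  const double *xp = x.begin();
  if (use_batch) {
    NumericVector sq(F);
    for (R_xlen_t m = 0; m < M; ++m) {
      const double *xo = xp + m * F;
      for (int f = 0; f < F; ++f) {
        mu[f] += xo[f];
        sq[f] += xo[f] * xo[f];
      }
    }
    for (int f = 0; f < F; ++f) {
      mu[f] /= M;
      var[f] = sq[f] / M - mu[f] * mu[f];
      if (var[f] < 0) var[f] = 0;
    }
  } else {
    mu = clone(mean_in);
    var = clone(var_in);
  }
  NumericVector invstd(F), g(F), b(F);
  for (int f = 0; f < F; ++f) {
    invstd[f] = 1.0 / std::sqrt(var[f] + eps);
    g[f] = gamma[f];
    b[f] = beta[f];
  }
  NumericVector y(x.size()), xhat(x.size());
  double *yp = y.begin(), *hp = xhat.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *xo = xp + m * F;
    double *yo = yp + m * F, *ho = hp + m * F;
    for (int f = 0; f < F; ++f) {
      double h = (xo[f] - mu[f]) * invstd[f];
      ho[f] = h;
      yo[f] = g[f] * h + b[f];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, int F,
                NumericVector gamma, NumericVector invstd, bool batch_stats) {
  const R_xlen_t M = dy.size() / F;
  NumericVector dgamma(F), dbeta(F);
  const double *dp = dy.begin(), *hp = xhat.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double *dyo = dp + m * F, *ho = hp + m * F;
    for (int f = 0; f < F; ++f) {
      dgamma[f] += dyo[f] * ho[f];
      dbeta[f] += dyo[f];
    }
  }
  NumericVector dx(dy.size());
  double *dxp = dx.begin();
  if (batch_stats) {
    NumericVector s1(F), s2(F);  // mean(dxhat), mean(dxhat * xhat)
    for (R_xlen_t m = 0; m < M; ++m) {
      const double *dyo = dp + m * F, *ho = hp + m * F;
      for (int f = 0; f < F; ++f) {
        double dh = dyo[f] * gamma[f];
        s1[f] += dh;
        s2[f] += dh * ho[f];
      }
    }
    for (int f = 0; f < F; ++f) { s1[f] /= M; s2[f] /= M; }
    for (R_xlen_t m = 0; m < M; ++m) {
      const double *dyo = dp + m * F, *ho = hp + m * F;
      double *dxo = dxp + m * F;
      for (int f = 0; f < F; ++f) {
        double dh = dyo[f] * gamma[f];
        dxo[f] = invstd[f] * (dh - s1[f] - ho[f] * s2[f]);
      }
    }
  } else {
    for (R_xlen_t m = 0; m < M; ++m) {
      const double *dyo = dp + m * F;
      double *dxo = dxp + m * F;
      for (int f = 0; f < F; ++f)
        dxo[f] = dyo[f] * gamma[f] * invstd[f];
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ELU and its input-side backward (derivative recovered from the output:
// elu'(x) = y + 1 where y < 0, else 1).
// [[Rcpp::export]]
NumericVector elu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double *xp = x.begin();
  double *yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    yp[i] = xp[i] < 0 ? std::expm1(xp[i]) : xp[i];
  return y;
}

// [[Rcpp::export]]
NumericVector elu_bwd_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double *dp = dy.begin(), *yp = y.begin();
  double *xp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    xp[i] = yp[i] < 0 ? dp[i] * (yp[i] + 1.0) : dp[i];
  return dx;
}
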