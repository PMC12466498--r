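#include <Rcpp.h>
using namespace Rcpp;

// Tensor memory layout throughout the package: dim = (C, H, W, B), column-major,
// i.e. channel index varies fastest. im2col emits a (C*Kh*Kw, Ho*Wo*B) matrix whose
// row index is i + Kh*(j + Kw*c)  (kernel row fastest, then kernel col, then channel)
// and whose column index is ho + Ho*(wo + Wo*b). Convolution weights are stored as a
// (Cout, Cin/g*Kh*Kw) matrix with matching column semantics, so a forward pass is a
// single matrix product per group.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int B,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int dh, int dw) {
  int Ho = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  int Wo = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  int ncol = Ho * Wo * B;
  int nrow = C * kh * kw;
  NumericMatrix out(nrow, ncol);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * b);
        double* oc = op + col * nrow;
        for (int c = 0; c < C; ++c) {
          for (int j = 0; j < kw; ++j) {
            int w_in = wo * sw - pw + j * dw;
            for (int i = 0; i < kh; ++i) {
              int h_in = ho * sh - ph + i * dh;
              int row = i + kh * (j + kw * c);
              if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W) {
                oc[row] = xp[c + (R_xlen_t)C * (h_in + (R_xlen_t)H * (w_in + (R_xlen_t)W * b))];
              } else {
                oc[row] = 0.0;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Batch-norm forward (training): per-channel stats over all other dims for a
// (C, n) view. Returns y and caches xhat and 1/sd for the backward pass.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, int C, NumericVector gamma, NumericVector beta,
                double eps) {
  R_xlen_t total = x.size();
  R_xlen_t n = total / C;
  std::vector<double> mu(C, 0.0), var(C, 0.0);
  const double* xp = x.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* col = xp + j * C;
    for (int c = 0; c < C; ++c) mu[c] += col[c];
  }
  for (int c = 0; c < C; ++c) mu[c] /= n;
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* col = xp + j * C;
    for (int c = 0; c < C; ++c) { double d = col[c] - mu[c]; var[c] += d * d; }
  }
  NumericVector y(total), xhat(total), invsd(C), muv(C), varv(C);
  for (int c = 0; c < C; ++c) {
    var[c] /= n;
    invsd[c] = 1.0 / std::sqrt(var[c] + eps);
    muv[c] = mu[c]; varv[c] = var[c];
  }
  double* yp = y.begin(); double* hp = xhat.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* col = xp + j * C;
    double* yc = yp + j * C; double* hc = hp + j * C;
    for (int c = 0; c < C; ++c) {
      double h = (col[c] - mu[c]) * invsd[c];
      hc[c] = h;
      yc[c] = gamma[c] * h + beta[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invsd"] = invsd,
                      _["mu"] = muv, _["var"] = varv);
}

// Batch-norm backward: returns dx and accumulates dgamma/dbeta.
// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector gy, NumericVector xhat, NumericVector invsd,
                NumericVector gamma, int C) {
  R_xlen_t total = gy.size();
  R_xlen_t n = total / C;
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  const double* gp = gy.begin();
  const double* hp = xhat.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* gc = gp + j * C;
    const double* hc = hp + j * C;
    for (int c = 0; c < C; ++c) { s1[c] += gc[c]; s2[c] += gc[c] * hc[c]; }
  }
  NumericVector dx(total), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) { dgamma[c] = s2[c]; dbeta[c] = s1[c]; }
  double* dp = dx.begin();
  for (R_xlen_t j = 0; j < n; ++j) {
    const double* gc = gp + j * C;
    const double* hc = hp + j * C;
    double* dc = dp + j * C;
    for (int c = 0; c < C; ++c) {
      dc[c] = gamma[c] * invsd[c] * (gc[c] - s1[c] / n - hc[c] * s2[c] / n);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// SiLU forward/backward
// [[Rcpp::export]]
List cpp_silu_fwd(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n), s(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double sv = 1.0 / (1.0 + std::exp(-x[i]));
    s[i] = sv;
    y[i] = x[i] * sv;
  }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector cpp_silu_bwd(NumericVector gy, NumericVector x, NumericVector s) {
  R_xlen_t n = gy.size();
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    dx[i] = gy[i] * s[i] * (1.0 + x[i] * (1.0 - s[i]));
  }
  return dx;
}

// Adjoint of im2col: scatter-adds columns back into an input-shaped gradient.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int H, int W, int B,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int dh, int dw) {
  int Ho = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  int Wo = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  int nrow = C * kh * kw;
  NumericVector out((R_xlen_t)C * H * W * B);
  double* op = out.begin();
  const double* cp = cols.begin();
  for (int b = 0; b < B; ++b) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * b);
        const double* cc = cp + col * nrow;
        for (int c = 0; c < C; ++c) {
          for (int j = 0; j < kw; ++j) {
            int w_in = wo * sw - pw + j * dw;
            for (int i = 0; i < kh; ++i) {
              int h_in = ho * sh - ph + i * dh;
              if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W) {
                int row = i + kh * (j + kw * c);
                op[c + (R_xlen_t)C * (h_in + (R_xlen_t)H * (w_in + (R_xlen_t)W * b))] += cc[row];
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W, B);
  return out;
}
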