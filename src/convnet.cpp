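// Minimal conv-net kernels: 3x3 same-padding convolution (forward/backward),
// 2x2 max pooling, and adaptive average pooling. Batches are R arrays in
// H x W x C x N layout (column-major). Weights are Cout x (Cin*9) matrices
// whose column order is (channel, dw, dh), matching the im2col below.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col3x3(const double* xn, int H, int W, int C, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)c * H * W;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        int r = c * 9 + (dw + 1) * 3 + (dh + 1);
        int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        for (int w = 0; w < W; ++w) {
          int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          double* dst = col.colptr(0) + r; // col is (C*9) x (H*W)
          const double* src = xc + (size_t)H * ws;
          for (int h = h0; h < h1; ++h) {
            dst[(size_t)(h + (size_t)H * w) * col.n_rows] = src[h + dh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3x3_forward(NumericVector x, NumericMatrix Wm,
                                  NumericVector b, bool relu) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wm.nrow();
  if (Wm.ncol() != C * 9) stop("conv weight shape mismatch");
  arma::mat Wmat(Wm.begin(), Cout, C * 9, false);
  arma::vec bv(b.begin(), Cout);
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col(C * 9, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col3x3(x.begin() + (size_t)n * H * W * C, H, W, C, col);
    arma::mat y = Wmat * col;
    y.each_col() += bv;
    if (relu) y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    double* on = out.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      for (size_t j = 0; j < (size_t)H * W; ++j) on[j + (size_t)H * W * co] = y(co, j);
    }
  }
  return out;
}

// y is the forward output (post-relu if relu=true); dy the upstream gradient.
// Returns dx, dW, db. Set need_dx = false at the lowest layer to skip input
// gradients.
// [[Rcpp::export]]
List cpp_conv3x3_backward(NumericVector x, NumericVector y, NumericMatrix Wm,
                          NumericVector dy, bool relu, bool need_dx) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wm.nrow();
  arma::mat Wmat(Wm.begin(), Cout, C * 9, false);
  arma::mat dW(Cout, C * 9, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat col(C * 9, (size_t)H * W);
  arma::mat dyn(Cout, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    const double* yn = y.begin() + (size_t)n * H * W * Cout;
    const double* gn = dy.begin() + (size_t)n * H * W * Cout;
    for (int co = 0; co < Cout; ++co) {
      for (size_t j = 0; j < (size_t)H * W; ++j) {
        double g = gn[j + (size_t)H * W * co];
        if (relu && yn[j + (size_t)H * W * co] <= 0.0) g = 0.0;
        dyn(co, j) = g;
      }
    }
    im2col3x3(x.begin() + (size_t)n * H * W * C, H, W, C, col);
    dW += dyn * col.t();
    db += arma::sum(dyn, 1);
    if (need_dx) {
      arma::mat dcol = Wmat.t() * dyn; // (C*9) x (H*W)
      double* dxn = dx.begin() + (size_t)n * H * W * C;
      for (int c = 0; c < C; ++c) {
        double* dxc = dxn + (size_t)c * H * W;
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            int r = c * 9 + (dw + 1) * 3 + (dh + 1);
            int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            for (int w = 0; w < W; ++w) {
              int ws = w + dw;
              if (ws < 0 || ws >= W) continue;
              for (int h = h0; h < h1; ++h) {
                dxc[(h + dh) + (size_t)H * ws] += dcol(r, h + (size_t)H * w);
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = NumericMatrix(Cout, C * 9, dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("input too small for 2x2 max pooling");
  NumericVector out((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // linear index into x (0-based)
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t k = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)n * H * W * C + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = base + (size_t)2 * ho + (size_t)H * 2 * wo;
          double bv = x[best];
          const int hh[4] = {0, 1, 0, 1}, ww[4] = {0, 0, 1, 1};
          for (int t = 1; t < 4; ++t) {
            size_t cand = base + (size_t)(2 * ho + hh[t]) + (size_t)H * (2 * wo + ww[t]);
            if (x[cand] > bv) { bv = x[cand]; best = cand; }
          }
          // column-major output order is (ho, wo, c, n) which matches k order
          size_t o = (size_t)ho + (size_t)Ho * wo + (size_t)Ho * Wo * c +
                     (size_t)Ho * Wo * C * n;
          out[o] = bv;
          idx[o] = (int)best;
          ++k;
        }
      }
    }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    IntegerVector in_dim) {
  NumericVector dx((size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// adaptive average pooling to side_out x side_out (bin edges as in the
// standard floor/ceil convention, so any input side >= side_out works)
// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool(NumericVector x, int S) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out((size_t)S * S * C * N);
  out.attr("dim") = IntegerVector::create(S, S, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)n * H * W * C + (size_t)c * H * W;
      double* oc = out.begin() + (size_t)n * S * S * C + (size_t)c * S * S;
      for (int j = 0; j < S; ++j) {
        int w0 = (int)std::floor((double)j * W / S);
        int w1 = (int)std::ceil((double)(j + 1) * W / S);
        for (int i = 0; i < S; ++i) {
          int h0 = (int)std::floor((double)i * H / S);
          int h1 = (int)std::ceil((double)(i + 1) * H / S);
          double s = 0.0;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) s += xc[h + (size_t)H * w];
          oc[i + (size_t)S * j] = s / ((h1 - h0) * (w1 - w0));
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool_backward(NumericVector dy, IntegerVector in_dim,
                                            int S) {
  int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = in_dim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)n * H * W * C + (size_t)c * H * W;
      const double* oc = dy.begin() + (size_t)n * S * S * C + (size_t)c * S * S;
      for (int j = 0; j < S; ++j) {
        int w0 = (int)std::floor((double)j * W / S);
        int w1 = (int)std::ceil((double)(j + 1) * W / S);
        for (int i = 0; i < S; ++i) {
          int h0 = (int)std::floor((double)i * H / S);
          int h1 = (int)std::ceil((double)(i + 1) * H / S);
          double g = oc[i + (size_t)S * j] / ((h1 - h0) * (w1 - w0));
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) xc[h + (size_t)H * w] += g;
        }
      }
    }
  }
  return dx;
}
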