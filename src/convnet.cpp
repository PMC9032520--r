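// Minimal im2col + GEMM convolution kernels for the two-branch embedding
// network. Layout conventions (column-major, matching R arrays):
//   1-D activations: cube (channels, length, batch)
//   2-D activations: cube (channels, height*width, batch), height fastest
// Weights: matrix (filters, channels*kernel). "Same" zero padding throughout;
// pooling uses ceiling mode (a partial final window is kept) so any input
// length survives four stride-4 stages.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col1d(const cube& X, int K, int dil) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int half = K / 2;
  mat out(C * K, (size_t)L * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& Xs = X.slice(b);
    for (int l = 0; l < L; ++l) {
      double* col = out.colptr((size_t)b * L + l);
      for (int k = 0; k < K; ++k) {
        int src = l + (k - half) * dil;
        if (src >= 0 && src < L)
          std::memcpy(col + (size_t)k * C, Xs.colptr(src), C * sizeof(double));
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv1d_fw")]]
arma::cube conv1d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& bias, int K, int dil) {
  const int L = X.n_cols, B = X.n_slices, F = W.n_rows;
  mat Xcol = im2col1d(X, K, dil);
  mat Y = W * Xcol;
  Y.each_col() += bias;
  cube out(F, L, B);
  std::memcpy(out.memptr(), Y.memptr(), Y.n_elem * sizeof(double));
  return out;
}

// [[Rcpp::export(name = ".conv1d_bw")]]
Rcpp::List conv1d_bw(const arma::cube& X, const arma::mat& W,
                     const arma::cube& dY, int K, int dil) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int F = W.n_rows, half = K / 2;
  mat Xcol = im2col1d(X, K, dil);
  mat dYm((double*)dY.memptr(), F, (size_t)L * B, false, true);
  mat dW = dYm * Xcol.t();
  vec db = sum(dYm, 1);
  mat dXcol = W.t() * dYm;            // (C*K, L*B)
  cube dX(C, L, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat& dXs = dX.slice(b);
    for (int l = 0; l < L; ++l) {
      const double* col = dXcol.colptr((size_t)b * L + l);
      for (int k = 0; k < K; ++k) {
        int src = l + (k - half) * dil;
        if (src >= 0 && src < L) {
          double* dst = dXs.colptr(src);
          const double* s = col + (size_t)k * C;
          for (int c = 0; c < C; ++c) dst[c] += s[c];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

static mat im2col2d(const cube& X, int H, int Wd, int KH, int KW, int dil) {
  const int C = X.n_rows, B = X.n_slices;
  const int hh = KH / 2, hw = KW / 2;
  mat out((size_t)C * KH * KW, (size_t)H * Wd * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& Xs = X.slice(b);
    for (int w = 0; w < Wd; ++w) {
      for (int h = 0; h < H; ++h) {
        double* col = out.colptr(((size_t)b * Wd + w) * H + h);
        for (int kw = 0; kw < KW; ++kw) {
          int sw = w + (kw - hw) * dil;
          if (sw < 0 || sw >= Wd) continue;
          for (int kh = 0; kh < KH; ++kh) {
            int sh = h + (kh - hh) * dil;
            if (sh < 0 || sh >= H) continue;
            std::memcpy(col + ((size_t)kw * KH + kh) * C,
                        Xs.colptr((size_t)sw * H + sh), C * sizeof(double));
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& bias, int H, int Wd,
                     int KH, int KW, int dil) {
  const int B = X.n_slices, F = W.n_rows;
  mat Xcol = im2col2d(X, H, Wd, KH, KW, dil);
  mat Y = W * Xcol;
  Y.each_col() += bias;
  cube out(F, (size_t)H * Wd, B);
  std::memcpy(out.memptr(), Y.memptr(), Y.n_elem * sizeof(double));
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::cube& X, const arma::mat& W,
                     const arma::cube& dY, int H, int Wd,
                     int KH, int KW, int dil) {
  const int C = X.n_rows, B = X.n_slices, F = W.n_rows;
  const int hh = KH / 2, hw = KW / 2;
  mat Xcol = im2col2d(X, H, Wd, KH, KW, dil);
  mat dYm((double*)dY.memptr(), F, (size_t)H * Wd * B, false, true);
  mat dW = dYm * Xcol.t();
  vec db = sum(dYm, 1);
  mat dXcol = W.t() * dYm;
  cube dX(C, (size_t)H * Wd, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat& dXs = dX.slice(b);
    for (int w = 0; w < Wd; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* col = dXcol.colptr(((size_t)b * Wd + w) * H + h);
        for (int kw = 0; kw < KW; ++kw) {
          int sw = w + (kw - hw) * dil;
          if (sw < 0 || sw >= Wd) continue;
          for (int kh = 0; kh < KH; ++kh) {
            int sh = h + (kh - hh) * dil;
            if (sh < 0 || sh >= H) continue;
            double* dst = dXs.colptr((size_t)sw * H + sh);
            const double* s = col + ((size_t)kw * KH + kh) * C;
            for (int c = 0; c < C; ++c) dst[c] += s[c];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool1d_fw")]]
Rcpp::List maxpool1d_fw(const arma::cube& X, int width, int stride) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lo = (L + stride - 1) / stride;  // ceiling mode
  cube Y(C, Lo, B);
  ucube idx(C, Lo, B);  // flat index into the input slice
  for (int b = 0; b < B; ++b) {
    const mat& Xs = X.slice(b);
    for (int lo = 0; lo < Lo; ++lo) {
      int from = lo * stride, to = std::min(from + width, L);
      for (int c = 0; c < C; ++c) {
        double best = Xs(c, from);
        int besti = from;
        for (int l = from + 1; l < to; ++l)
          if (Xs(c, l) > best) { best = Xs(c, l); besti = l; }
        Y(c, lo, b) = best;
        idx(c, lo, b) = (size_t)besti * C + c;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool1d_bw")]]
arma::cube maxpool1d_bw(const arma::cube& dY, const arma::ucube& idx,
                        int C, int L) {
  const int B = dY.n_slices, Lo = dY.n_cols;
  cube dX(C, L, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* dst = dX.slice(b).memptr();
    for (int lo = 0; lo < Lo; ++lo)
      for (int c = 0; c < C; ++c)
        dst[idx(c, lo, b)] += dY(c, lo, b);
  }
  return dX;
}

// [[Rcpp::export(name = ".maxpool2d_fw")]]
Rcpp::List maxpool2d_fw(const arma::cube& X, int H, int Wd,
                        int width, int stride) {
  const int C = X.n_rows, B = X.n_slices;
  const int Ho = (H + stride - 1) / stride, Wo = (Wd + stride - 1) / stride;
  cube Y(C, (size_t)Ho * Wo, B);
  ucube idx(C, (size_t)Ho * Wo, B);
  for (int b = 0; b < B; ++b) {
    const mat& Xs = X.slice(b);
    for (int wo = 0; wo < Wo; ++wo) {
      int wfrom = wo * stride, wto = std::min(wfrom + width, Wd);
      for (int ho = 0; ho < Ho; ++ho) {
        int hfrom = ho * stride, hto = std::min(hfrom + width, H);
        size_t ocol = (size_t)wo * Ho + ho;
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int w = wfrom; w < wto; ++w)
            for (int h = hfrom; h < hto; ++h) {
              double v = Xs(c, (size_t)w * H + h);
              if (v > best) { best = v; besti = ((size_t)w * H + h) * C + c; }
            }
          Y(c, ocol, b) = best;
          idx(c, ocol, b) = besti;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2d_bw")]]
arma::cube maxpool2d_bw(const arma::cube& dY, const arma::ucube& idx,
                        int C, int HW) {
  const int B = dY.n_slices;
  const size_t n = dY.n_cols;
  cube dX(C, HW, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* dst = dX.slice(b).memptr();
    for (size_t o = 0; o < n; ++o)
      for (int c = 0; c < C; ++c)
        dst[idx(c, o, b)] += dY(c, o, b);
  }
  return dX;
}
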