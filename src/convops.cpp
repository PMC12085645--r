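#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Activations are stored as C x (H*W*N) matrices, pixels column-major per
// sample (row index fastest), samples consecutive. im2col unrolls k x k
// receptive fields (stride s, zero padding p) into a (C*k*k) x (Ho*Wo*N)
// matrix so convolution becomes one BLAS matmul; col2im is its adjoint.

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(const NumericMatrix& A, int H, int W, int N,
                         int k, int stride, int pad) {
  const int C = A.nrow();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, Ho * Wo * N);
  const double* a = A.begin();
  double* o = out.begin();
  const int nrow_out = C * k * k;
  for (int n = 0; n < N; ++n) {
    const int in_off = n * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int col = n * Ho * Wo + wo * Ho + ho;
        double* ocol = o + (size_t)col * nrow_out;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            const bool win = (w >= 0 && w < W);
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              double v = 0.0;
              if (win && h >= 0 && h < H)
                v = a[(size_t)(in_off + w * H + h) * C + c];
              ocol[c * k * k + kw * k + kh] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im_cpp")]]
NumericMatrix col2im_cpp(const NumericMatrix& cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C, H * W * N);
  const double* cl = cols.begin();
  double* o = out.begin();
  const int nrow_cols = C * k * k;
  for (int n = 0; n < N; ++n) {
    const int in_off = n * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int col = n * Ho * Wo + wo * Ho + ho;
        const double* ccol = cl + (size_t)col * nrow_cols;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              o[(size_t)(in_off + w * H + h) * C + c] += ccol[c * k * k + kw * k + kh];
            }
          }
        }
      }
    }
  }
  return out;
}

// Sliding-window median with replicate border padding. Window may be even
// (offsets split floor/ceil around the centre pixel), matching the 40 px
// kernel convention used for label-free background estimation.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(const NumericMatrix& x, int kh, int kw) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  const int up = (kh - 1) / 2, down = kh - 1 - up;
  const int left = (kw - 1) / 2, right = kw - 1 - left;
  std::vector<double> buf;
  buf.reserve((size_t)kh * kw);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      buf.clear();
      for (int dj = -left; dj <= right; ++dj) {
        int jj = std::min(std::max(j + dj, 0), W - 1);
        for (int di = -up; di <= down; ++di) {
          int ii = std::min(std::max(i + di, 0), H - 1);
          buf.push_back(x(ii, jj));
        }
      }
      const size_t m = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      double med = buf[m];
      if (buf.size() % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
        med = 0.5 * (med + buf[m - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Grey-level co-occurrence counts for one direction over a labelled region.
// vals: quantised levels 1..nlev (0 = outside region), row-major H x W matrix;
// (di, dj) the pixel offset. Symmetric accumulation (both orderings).
// [[Rcpp::export(name = ".glcm_cpp")]]
NumericMatrix glcm_cpp(const IntegerMatrix& vals, int nlev, int di, int dj) {
  const int H = vals.nrow(), W = vals.ncol();
  NumericMatrix P(nlev, nlev);
  for (int j = 0; j < W; ++j) {
    const int jj = j + dj;
    if (jj < 0 || jj >= W) continue;
    for (int i = 0; i < H; ++i) {
      const int ii = i + di;
      if (ii < 0 || ii >= H) continue;
      const int a = vals(i, j), b = vals(ii, jj);
      if (a > 0 && b > 0) {
        P(a - 1, b - 1) += 1.0;
        P(b - 1, a - 1) += 1.0;
      }
    }
  }
  return P;
}
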