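// Convolution / pooling kernels for the network engine.
//
// Tensor layout follows R column-major arrays: activations are [H, W, C, N],
// conv weights are [k, k, Cin, Cout] (so a flattened input-channel patch has
// the same linear order as one output-filter slice of the weight array, and
// the im2col product is a single dgemm).  Stride is always 1 with "same"
// zero padding; pooling is 2x2/stride 2 with floor semantics.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}


// Fill the im2col patch matrix for output columns [j0, j1).
// M is (k*k*C) x (H * (j1-j0)); zero padding outside the image.
void fill_cols(const double* x, int H, int W, int C, int k, int pad,
               int j0, int j1, arma::mat& M) {
  M.zeros();
  const int k2 = k * k;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k2 * c;
        for (int j = j0; j < j1; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          const double* col = xc + (size_t)jj * H;
          double* mrow = M.memptr() + r + (size_t)(j - j0) * H * M.n_rows;
          const int ilo = std::max(0, pad - di);
          const int ihi = std::min(H, H + pad - di);
          for (int i = ilo; i < ihi; ++i)
            mrow[(size_t)i * M.n_rows] = col[i + di - pad];
        }
      }
    }
  }
}

int chunk_width(int H, int W, int C, int k) {
  // cap the im2col buffer near 4e6 doubles (~32 MB)
  double per_col = (double)k * k * C * H;
  int wc = (int)std::max(1.0, std::floor(4e6 / per_col));
  return std::min(wc, W);
}

} // namespace

// x: [H,W,C,N], w: [k,k,C,F], b: length F (may be NULL) -> y: [H,W,F,N]
// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  if (wd[1] != k || wd[2] != C) stop("weight dims do not match input");
  const int pad = (k - 1) / 2, k2C = k * k * C;
  NumericVector y = alloc4(H, W, F, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k2C, F, false, true);
  arma::vec bv(F, arma::fill::zeros);
  if (b.isNotNull()) bv = Rcpp::as<arma::vec>(b.get());
  const int wc = chunk_width(H, W, C, k);
  arma::mat M(k2C, (size_t)H * wc);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * H * W * F;
    for (int j0 = 0; j0 < W; j0 += wc) {
      const int j1 = std::min(W, j0 + wc);
      arma::mat Mv(M.memptr(), k2C, (size_t)H * (j1 - j0), false, true);
      fill_cols(xn, H, W, C, k, pad, j0, j1, Mv);
      arma::mat Y = Mv.t() * Wm;                       // (H*wc) x F
      Y.each_row() += bv.t();
      for (int f = 0; f < F; ++f)
        std::copy(Y.colptr(f), Y.colptr(f) + Y.n_rows,
                  yn + (size_t)f * H * W + (size_t)j0 * H);
    }
  }
  return y;
}

// Backward pass. Returns dx always; dw/db only when need_dw.
// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool need_dw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const int pad = (k - 1) / 2, k2C = k * k * C;
  NumericVector dx = alloc4(H, W, C, N);
  arma::mat dWm(k2C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  const arma::mat Wm(const_cast<double*>(w.begin()), k2C, F, false, true);
  const int wc = chunk_width(H, W, C, k);
  arma::mat M(k2C, (size_t)H * wc);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* dyn = dy.begin() + (size_t)n * H * W * F;
    double* dxn = dx.begin() + (size_t)n * H * W * C;
    for (int j0 = 0; j0 < W; j0 += wc) {
      const int j1 = std::min(W, j0 + wc);
      const size_t ncol = (size_t)H * (j1 - j0);
      arma::mat dY(ncol, F);
      for (int f = 0; f < F; ++f)
        std::copy(dyn + (size_t)f * H * W + (size_t)j0 * H,
                  dyn + (size_t)f * H * W + (size_t)j0 * H + ncol,
                  dY.colptr(f));
      if (need_dw) {
        arma::mat Mv(M.memptr(), k2C, ncol, false, true);
        fill_cols(xn, H, W, C, k, pad, j0, j1, Mv);
        dWm += Mv * dY;
        db += arma::sum(dY, 0).t();
      }
      arma::mat dM = Wm * dY.t();                      // k2C x ncol
      // col2im scatter-add
      const int k2 = k * k;
      for (int c = 0; c < C; ++c) {
        double* dxc = dxn + (size_t)c * H * W;
        for (int dj = 0; dj < k; ++dj) {
          for (int di = 0; di < k; ++di) {
            const int r = di + k * dj + k2 * c;
            for (int j = j0; j < j1; ++j) {
              const int jj = j + dj - pad;
              if (jj < 0 || jj >= W) continue;
              double* col = dxc + (size_t)jj * H;
              const double* mrow = dM.memptr() + r +
                (size_t)(j - j0) * H * dM.n_rows;
              const int ilo = std::max(0, pad - di);
              const int ihi = std::min(H, H + pad - di);
              for (int i = ilo; i < ihi; ++i)
                col[i + di - pad] += mrow[(size_t)i * dM.n_rows];
            }
          }
        }
      }
    }
  }
  NumericVector dwR = alloc4(k, k, C, F);
  std::copy(dWm.begin(), dWm.end(), dwR.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwR,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2 (floor). Returns pooled values and argmax
// linear indices (1-based into the input array) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = H / 2, W2 = W / 2;
  if (H2 < 1 || W2 < 1) stop("input too small to pool");
  NumericVector y = alloc4(H2, W2, C, N);
  IntegerVector idx = alloc4i(H2, W2, C, N);
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < W2; ++j)
        for (int i = 0; i < H2; ++i) {
          size_t best = base + (size_t)(2 * j) * H + 2 * i;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t p = base + (size_t)(2 * j + dj) * H + 2 * i + di;
              if (x[p] > x[best]) best = p;
            }
          y[q] = x[best];
          idx[q] = (int)(best + 1);
          ++q;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector dy,
                           IntegerVector xdim) {
  NumericVector dx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t q = 0; q < dy.size(); ++q)
    dx[idx[q] - 1] += dy[q];
  return dx;
}
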