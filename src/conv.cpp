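// 2-D convolution primitives for the segmentation network.
//
// Layout conventions (match R's column-major 3-D arrays):
//   feature map  : cube (H, W, C)
//   weight matrix: (kh*kw*Cin) x Cout, rows ordered di + kh*(dj + kw*c)
//   padding      : (top, left, bottom, right), zero fill
// Output spatial size: floor((H + pt + pb - kh)/stride) + 1.
//
// Patches are gathered as an (Ho*Wo) x (kh*kw*Cin) matrix with contiguous
// column-strip copies (stride 1) so both the gather and the GEMM are
// cache-friendly; col2im is the exact scatter-add adjoint.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void out_size(int H, int W, int kh, int kw, int stride,
                     int pt, int pl, int pb, int pr, int& Ho, int& Wo) {
  Ho = (H + pt + pb - kh) / stride + 1;
  Wo = (W + pl + pr - kw) / stride + 1;
}

// patches(i + Ho*j, di + kh*(dj + kw*c)) = x(i*s - pt + di, j*s - pl + dj, c)
static mat im2col_t(const cube& x, int kh, int kw, int stride,
                    int pt, int pl, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(Ho * Wo, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        double* ocol = out.colptr(di + kh * (dj + kw * c));
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride - pl + dj;
          if (sj < 0 || sj >= W) continue;
          const double* xcol = xs + (size_t)sj * H;
          double* o = ocol + (size_t)j * Ho;
          if (stride == 1) {
            const int i0 = std::max(0, pt - di);
            const int i1 = std::min(Ho - 1, H - 1 - di + pt);
            if (i1 >= i0)
              std::copy(xcol + (i0 - pt + di), xcol + (i1 - pt + di) + 1,
                        o + i0);
          } else {
            for (int i = 0; i < Ho; ++i) {
              const int si = i * stride - pt + di;
              if (si >= 0 && si < H) o[i] = xcol[si];
            }
          }
        }
      }
  }
  return out;
}

static cube col2im_t(const mat& cols, int H, int W, int C,
                     int kh, int kw, int stride, int pt, int pl,
                     int Ho, int Wo) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xs = x.slice_memptr(c);
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const double* ocol = cols.colptr(di + kh * (dj + kw * c));
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * stride - pl + dj;
          if (sj < 0 || sj >= W) continue;
          double* xcol = xs + (size_t)sj * H;
          const double* o = ocol + (size_t)j * Ho;
          if (stride == 1) {
            const int i0 = std::max(0, pt - di);
            const int i1 = std::min(Ho - 1, H - 1 - di + pt);
            for (int i = i0; i <= i1; ++i) xcol[i - pt + di] += o[i];
          } else {
            for (int i = 0; i < Ho; ++i) {
              const int si = i * stride - pt + di;
              if (si >= 0 && si < H) xcol[si] += o[i];
            }
          }
        }
      }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int kh, int kw, int stride,
                      int pt, int pl, int pb, int pr) {
  int Ho, Wo;
  out_size(x.n_rows, x.n_cols, kh, kw, stride, pt, pl, pb, pr, Ho, Wo);
  const mat patches = im2col_t(x, kh, kw, stride, pt, pl, Ho, Wo);
  mat y = patches * w;               // (Ho*Wo) x Cout
  y.each_row() += b.t();
  const int Cout = w.n_cols;
  cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    std::copy(y.colptr(c), y.colptr(c) + (size_t)Ho * Wo,
              out.slice_memptr(c));
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, int kh, int kw, int stride,
                      int pt, int pl, int pb, int pr) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  const mat patches = im2col_t(x, kh, kw, stride, pt, pl, Ho, Wo);
  mat dy_mat(Ho * Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    std::copy(dy.slice_memptr(c), dy.slice_memptr(c) + (size_t)Ho * Wo,
              dy_mat.colptr(c));
  mat dw = patches.t() * dy_mat;     // K x Cout
  vec db = sum(dy_mat, 0).t();
  const mat dcols = dy_mat * w.t();  // (Ho*Wo) x K
  cube dx = col2im_t(dcols, x.n_rows, x.n_cols, x.n_slices,
                     kh, kw, stride, pt, pl, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// batched variants: xs is a list of cubes; one GEMM pair per sample but a
// single R round-trip per layer.

// [[Rcpp::export]]
Rcpp::List conv2d_fwd_batch(Rcpp::List xs, const arma::mat& w,
                            const arma::vec& b, int kh, int kw, int stride,
                            int pt, int pl, int pb, int pr) {
  const int n = xs.size();
  Rcpp::List out(n);
  for (int s = 0; s < n; ++s) {
    cube x = Rcpp::as<cube>(xs[s]);
    out[s] = conv2d_fwd(x, w, b, kh, kw, stride, pt, pl, pb, pr);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd_batch(Rcpp::List xs, const arma::mat& w, Rcpp::List dys,
                            int kh, int kw, int stride,
                            int pt, int pl, int pb, int pr) {
  const int n = xs.size();
  Rcpp::List dxs(n);
  mat dw_acc(w.n_rows, w.n_cols, fill::zeros);
  vec db_acc(w.n_cols, fill::zeros);
  for (int s = 0; s < n; ++s) {
    cube x = Rcpp::as<cube>(xs[s]);
    cube dy = Rcpp::as<cube>(dys[s]);
    const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
    const mat patches = im2col_t(x, kh, kw, stride, pt, pl, Ho, Wo);
    mat dy_mat(Ho * Wo, Cout);
    for (int c = 0; c < Cout; ++c)
      std::copy(dy.slice_memptr(c), dy.slice_memptr(c) + (size_t)Ho * Wo,
                dy_mat.colptr(c));
    dw_acc += patches.t() * dy_mat;
    db_acc += sum(dy_mat, 0).t();
    const mat dcols = dy_mat * w.t();
    dxs[s] = col2im_t(dcols, x.n_rows, x.n_cols, x.n_slices,
                      kh, kw, stride, pt, pl, Ho, Wo);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dxs,
                            Rcpp::Named("dw") = dw_acc,
                            Rcpp::Named("db") = db_acc);
}
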