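// Low-level array kernels for the segmentation network.
//
// Layout conventions (match R's column-major array semantics):
//   feature map  : arma::cube (H, W, C)  <-> R array dim c(H, W, C)
//   conv weights : arma::mat  (k*k*Cin, Cout) <-> R array dim c(k, k, Cin, Cout)
//                  row index r = ki + kj*k + ci*k*k  (ki = row tap, kj = col tap)
//   convT weights: arma::mat  (4*Cin, Cout) <-> R array dim c(2, 2, Cin, Cout)
// All convolutions are stride 1 with caller-chosen zero padding; the
// transposed convolution is the fixed 2x2 / stride-2 up-convolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Patch matrix layout: (H*W, k*k*Cin), so each (tap, channel) pair is one
// contiguous column and the convolution is a single col * W gemm.
static mat im2col(const cube& x, const int k, const int pad, const int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(H * W, k * k * C, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const double* xs = x.slice_memptr(ci);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + kj * k + ci * k * k;
        const int di = dil * ki - pad, dj = dil * kj - pad;
        double* cp = col.colptr(r);
        const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        if (i1 < i0) continue;
        for (int j = j0; j <= j1; ++j)
          std::memcpy(cp + i0 + j * H, xs + (i0 + di) + (j + dj) * H,
                      (i1 - i0 + 1) * sizeof(double));
      }
    }
  }
  return col;
}

static void col2im_acc(cube& dx, const mat& dcol, const int k, const int pad,
                       const int dil) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int ci = 0; ci < C; ++ci) {
    double* xs = dx.slice_memptr(ci);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + kj * k + ci * k * k;
        const int di = dil * ki - pad, dj = dil * kj - pad;
        const double* cp = dcol.colptr(r);
        const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        if (i1 < i0) continue;
        for (int j = j0; j <= j1; ++j) {
          double* dst = xs + (i0 + di) + (j + dj) * H;
          const double* src = cp + i0 + j * H;
          for (int i = 0; i <= i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, const int k, const int pad,
                          const int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_cols;
  mat col = im2col(x, k, pad, dil);
  mat y = col * w;                // (H*W, Cout)
  y.each_row() += b.t();
  cube out(H, W, cout);
  for (int co = 0; co < cout; ++co)
    out.slice(co) = reshape(y.col(co), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, const int k, const int pad,
                          const int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w.n_cols;
  mat col = im2col(x, k, pad, dil);
  mat dym(H * W, cout);
  for (int co = 0; co < cout; ++co)
    dym.col(co) = vectorise(dy.slice(co));
  mat dw = col.t() * dym;                   // (k*k*Cin, Cout)
  vec db = sum(dym, 0).t();
  mat dcol = dym * w.t();                   // (H*W, k*k*Cin)
  cube dx(H, W, x.n_slices, fill::zeros);
  col2im_acc(dx, dcol, k, pad, dil);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube cpp_convt2_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  const int cout = w.n_cols;
  cube y(2 * H, 2 * W, cout);
  for (int co = 0; co < cout; ++co) y.slice(co).fill(b(co));
  for (int ci = 0; ci < cin; ++ci) {
    const mat& xs = x.slice(ci);
    for (int co = 0; co < cout; ++co) {
      mat& ys = y.slice(co);
      for (int bb = 0; bb < 2; ++bb) {
        for (int aa = 0; aa < 2; ++aa) {
          const double wv = w(aa + 2 * bb + 4 * ci, co);
          if (wv == 0.0) continue;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              ys(2 * i + aa, 2 * j + bb) += wv * xs(i, j);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_convt2_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy) {
  const int H = x.n_rows, W = x.n_cols, cin = x.n_slices;
  const int cout = w.n_cols;
  cube dx(H, W, cin, fill::zeros);
  mat dw(4 * cin, cout, fill::zeros);
  vec db(cout, fill::zeros);
  for (int co = 0; co < cout; ++co) db(co) = accu(dy.slice(co));
  for (int ci = 0; ci < cin; ++ci) {
    const mat& xs = x.slice(ci);
    mat& dxs = dx.slice(ci);
    for (int co = 0; co < cout; ++co) {
      const mat& dys = dy.slice(co);
      for (int bb = 0; bb < 2; ++bb) {
        for (int aa = 0; aa < 2; ++aa) {
          const double wv = w(aa + 2 * bb + 4 * ci, co);
          double acc = 0.0;
          for (int j = 0; j < W; ++j) {
            for (int i = 0; i < H; ++i) {
              const double g = dys(2 * i + aa, 2 * j + bb);
              dxs(i, j) += wv * g;
              acc += g * xs(i, j);
            }
          }
          dw(aa + 2 * bb + 4 * ci, co) += acc;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int oh = H / 2, ow = W / 2;
  cube y(oh, ow, C);
  Rcpp::IntegerVector idx(oh * ow * C);  // offset a + 2*b of the argmax
  int p = 0;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    mat& ys = y.slice(c);
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        double best = xs(2 * i, 2 * j);
        int bo = 0;
        for (int bb = 0; bb < 2; ++bb)
          for (int aa = 0; aa < 2; ++aa) {
            const double v = xs(2 * i + aa, 2 * j + bb);
            if (v > best) { best = v; bo = aa + 2 * bb; }
          }
        ys(i, j) = best;
        idx[c * oh * ow + j * oh + i] = bo;
        ++p;
      }
    }
  }
  (void)p;
  idx.attr("dim") = Rcpp::IntegerVector::create(oh, ow, C);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy,
                            const Rcpp::IntegerVector& idx) {
  const int oh = dy.n_rows, ow = dy.n_cols, C = dy.n_slices;
  cube dx(2 * oh, 2 * ow, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& dys = dy.slice(c);
    mat& dxs = dx.slice(c);
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const int bo = idx[c * oh * ow + j * oh + i];
        dxs(2 * i + bo % 2, 2 * j + bo / 2) += dys(i, j);
      }
  }
  return dx;
}

// Bilinear resize with the half-pixel-center convention; backward pass is the
// exact transpose of the forward interpolation weights.
// [[Rcpp::export]]
arma::cube cpp_bilinear_fwd(const arma::cube& x, const int oh, const int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(oh, ow, C);
  const double si = double(H) / oh, sj = double(W) / ow;
  for (int j = 0; j < ow; ++j) {
    double fj = (j + 0.5) * sj - 0.5;
    if (fj < 0) fj = 0;
    if (fj > W - 1) fj = W - 1;
    const int j0 = int(fj), j1 = std::min(j0 + 1, W - 1);
    const double wj = fj - j0;
    for (int i = 0; i < oh; ++i) {
      double fi = (i + 0.5) * si - 0.5;
      if (fi < 0) fi = 0;
      if (fi > H - 1) fi = H - 1;
      const int i0 = int(fi), i1 = std::min(i0 + 1, H - 1);
      const double wi = fi - i0;
      for (int c = 0; c < C; ++c) {
        const mat& xs = x.slice(c);
        y(i, j, c) = (1 - wi) * (1 - wj) * xs(i0, j0) +
                     wi * (1 - wj) * xs(i1, j0) +
                     (1 - wi) * wj * xs(i0, j1) + wi * wj * xs(i1, j1);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear_bwd(const arma::cube& dy, const int H, const int W) {
  const int oh = dy.n_rows, ow = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const double si = double(H) / oh, sj = double(W) / ow;
  for (int j = 0; j < ow; ++j) {
    double fj = (j + 0.5) * sj - 0.5;
    if (fj < 0) fj = 0;
    if (fj > W - 1) fj = W - 1;
    const int j0 = int(fj), j1 = std::min(j0 + 1, W - 1);
    const double wj = fj - j0;
    for (int i = 0; i < oh; ++i) {
      double fi = (i + 0.5) * si - 0.5;
      if (fi < 0) fi = 0;
      if (fi > H - 1) fi = H - 1;
      const int i0 = int(fi), i1 = std::min(i0 + 1, H - 1);
      const double wi = fi - i0;
      for (int c = 0; c < C; ++c) {
        const double g = dy(i, j, c);
        mat& dxs = dx.slice(c);
        dxs(i0, j0) += (1 - wi) * (1 - wj) * g;
        dxs(i1, j0) += wi * (1 - wj) * g;
        dxs(i0, j1) += (1 - wi) * wj * g;
        dxs(i1, j1) += wi * wj * g;
      }
    }
  }
  return dx;
}
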