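// Low-level primitives for the U-shaped segmentation networks.
// Feature maps are arma::cube (rows = H, cols = W, slices = channels),
// matching R's column-major array(dim = c(H, W, C)).
// Conv weights are matrices of shape (kh*kw*cin) x cout, rows ordered as
// (dh, dw, cin) column-major, i.e. index = dh + kh*(dw + kw*c).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col with "same" zero padding for odd kernels (pad = k/2), stride 1.
static arma::mat im2col_same(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  arma::mat out(H * W, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int col = dh + kh * (dw + kw * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dw - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dh - ph;
            if (si < 0 || si >= H) continue;
            out(i + H * j, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col_same
static arma::cube col2im_same(const arma::mat& cols, int H, int W, int C,
                              int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int col = dh + kh * (dw + kw * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dw - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + dh - ph;
            if (si < 0 || si >= H) continue;
            out(si, sj, c) += cols(i + H * j, col);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int kh, int kw) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int cout = W.n_cols;
  arma::mat cols = im2col_same(x, kh, kw);
  arma::mat y = cols * W;            // (H*W) x cout
  y.each_row() += b.t();
  arma::cube out(y.memptr(), H, Wd, cout);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& W,
                const arma::cube& gout, int kh, int kw) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int cout = W.n_cols;
  arma::mat g(const_cast<double*>(gout.memptr()), H * Wd, cout, false, true);
  arma::mat cols = im2col_same(x, kh, kw);
  arma::mat gW = cols.t() * g;                    // (kh*kw*C) x cout
  arma::vec gb = arma::sum(g, 0).t();
  arma::mat gcols = g * W.t();                    // (H*W) x (kh*kw*C)
  arma::cube gx = col2im_same(gcols, H, Wd, C, kh, kw);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled map and linear argmax indices
// (1-based into the H*W plane of each channel) for SegNet-style unpooling.
// [[Rcpp::export]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  arma::cube out(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -arma::datum::inf;
        int besti = 0, bestj = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; besti = 2 * i + di; bestj = 2 * j + dj; }
          }
        out(i, j, c) = best;
        idx(i, j, c) = besti + H * bestj + 1;     // 1-based plane index
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& gout, const arma::ucube& idx,
                        int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* plane = gx.slice_memptr(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        plane[idx(i, j, c) - 1] += gout(i, j, c);
  }
  return gx;
}

// SegNet unpooling: place values at recorded argmax positions, zero elsewhere.
// [[Rcpp::export]]
arma::cube maxunpool2_fwd(const arma::cube& x, const arma::ucube& idx,
                          int H, int W) {
  return maxpool2_bwd(x, idx, H, W);   // same scatter
}

// [[Rcpp::export]]
arma::cube maxunpool2_bwd(const arma::cube& gout, const arma::ucube& idx) {
  const int Ho = idx.n_rows, Wo = idx.n_cols, C = idx.n_slices;
  arma::cube gx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* plane = gout.slice_memptr(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        gx(i, j, c) = plane[idx(i, j, c) - 1];
  }
  return gx;
}

// 2x2 up-convolution (transposed conv, stride 2: blocks do not overlap).
// Weight shape: (4*cin) x cout, rows ordered (dh, dw, cin) as above (kh=kw=2).
// [[Rcpp::export]]
arma::cube upconv2_fwd(const arma::cube& x, const arma::mat& W,
                       const arma::vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int cout = W.n_cols;
  arma::mat xm(const_cast<double*>(x.memptr()), H * Wd, C, false, true);
  arma::cube out(2 * H, 2 * Wd, cout);
  for (int dw = 0; dw < 2; ++dw) {
    for (int dh = 0; dh < 2; ++dh) {
      arma::mat Wsub(C, cout);                   // rows for this (dh, dw)
      for (int c = 0; c < C; ++c) Wsub.row(c) = W.row(dh + 2 * (dw + 2 * c));
      arma::mat y = xm * Wsub;                   // (H*W) x cout
      for (int co = 0; co < cout; ++co)
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            out(2 * i + dh, 2 * j + dw, co) = y(i + H * j, co) + b(co);
    }
  }
  return out;
}

// [[Rcpp::export]]
List upconv2_bwd(const arma::cube& x, const arma::mat& W,
                 const arma::cube& gout) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int cout = W.n_cols;
  arma::mat xm(const_cast<double*>(x.memptr()), H * Wd, C, false, true);
  arma::mat gW(4 * C, cout, arma::fill::zeros);
  arma::vec gb(cout, arma::fill::zeros);
  arma::mat gxm(H * Wd, C, arma::fill::zeros);
  for (int dw = 0; dw < 2; ++dw) {
    for (int dh = 0; dh < 2; ++dh) {
      arma::mat g(H * Wd, cout);
      for (int co = 0; co < cout; ++co)
        for (int j = 0; j < Wd; ++j)
          for (int i = 0; i < H; ++i)
            g(i + H * j, co) = gout(2 * i + dh, 2 * j + dw, co);
      arma::mat gWsub = xm.t() * g;              // C x cout
      for (int c = 0; c < C; ++c) gW.row(dh + 2 * (dw + 2 * c)) = gWsub.row(c);
      arma::mat Wsub(C, cout);
      for (int c = 0; c < C; ++c) Wsub.row(c) = W.row(dh + 2 * (dw + 2 * c));
      gxm += g * Wsub.t();
      gb += arma::sum(g, 0).t();
    }
  }
  arma::cube gx(gxm.memptr(), H, Wd, C);
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
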