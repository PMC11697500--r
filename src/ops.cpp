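// Low-level numeric kernels: small-kernel 2D convolution (im2col + GEMM),
// nearest-neighbour 2x upsampling, and bilinear affine warping.
// Tensors cross the R boundary as numeric arrays dim = c(H, W, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static cube as_cube(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-d array (H, W, C)");
  return cube(const_cast<double*>(x.begin()), d[0], d[1], d[2], false, true);
}

static Rcpp::NumericVector wrap_cube(const cube& x) {
  Rcpp::NumericVector out(x.begin(), x.end());
  out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// im2col for k x k kernels with pad = k/2. Column j (column-major over the
// Ho x Wo output grid) holds the receptive field, rows ordered (ky, kx, c).
static mat im2col(const cube& X, int k, int stride) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, p = k / 2;
  const int Ho = (H + 2 * p - k) / stride + 1;
  const int Wo = (W + 2 * p - k) / stride + 1;
  mat K(k * k * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& Xc = X.slice(c);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int row = c * k * k + kx * k + ky;
        for (int wo = 0; wo < Wo; ++wo) {
          const int x = wo * stride + kx - p;
          if (x < 0 || x >= W) continue;
          double* col = K.colptr(wo * Ho);
          for (int ho = 0; ho < Ho; ++ho) {
            const int y = ho * stride + ky - p;
            if (y < 0 || y >= H) continue;
            col[(size_t)ho * K.n_rows + row] = Xc(y, x);
          }
        }
      }
    }
  }
  return K;
}

// [[Rcpp::export(name = ".conv_fw")]]
Rcpp::NumericVector conv_fw(Rcpp::NumericVector x, const arma::mat& W,
                            const arma::vec& b, int k, int stride) {
  cube X = as_cube(x);
  const int p = k / 2;
  const int Ho = ((int)X.n_rows + 2 * p - k) / stride + 1;
  const int Wo = ((int)X.n_cols + 2 * p - k) / stride + 1;
  if ((int)W.n_cols != k * k * (int)X.n_slices)
    Rcpp::stop("weight shape does not match input channels/kernel");
  mat K = im2col(X, k, stride);
  mat Y = W * K;
  Y.each_col() += b;
  cube out(Ho, Wo, W.n_rows);
  for (uword o = 0; o < W.n_rows; ++o)
    out.slice(o) = reshape(Y.row(o), Ho, Wo);
  return wrap_cube(out);
}

// [[Rcpp::export(name = ".conv_bw")]]
Rcpp::List conv_bw(Rcpp::NumericVector x, const arma::mat& W,
                   Rcpp::NumericVector dy, int k, int stride) {
  cube X = as_cube(x);
  cube dY = as_cube(dy);
  const int H = X.n_rows, Wd = X.n_cols, C = X.n_slices, p = k / 2;
  const int Ho = dY.n_rows, Wo = dY.n_cols, OC = dY.n_slices;
  mat dY_mat(OC, Ho * Wo);
  for (int o = 0; o < OC; ++o)
    dY_mat.row(o) = vectorise(dY.slice(o)).t();
  mat K = im2col(X, k, stride);
  mat dW = dY_mat * K.t();
  vec db = sum(dY_mat, 1);
  mat dK = W.t() * dY_mat;            // (k*k*C) x (Ho*Wo)
  cube dX(H, Wd, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& dXc = dX.slice(c);
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int row = c * k * k + kx * k + ky;
        for (int wo = 0; wo < Wo; ++wo) {
          const int xx = wo * stride + kx - p;
          if (xx < 0 || xx >= Wd) continue;
          const double* col = dK.colptr(wo * Ho);
          for (int ho = 0; ho < Ho; ++ho) {
            const int yy = ho * stride + ky - p;
            if (yy < 0 || yy >= H) continue;
            dXc(yy, xx) += col[(size_t)ho * dK.n_rows + row];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = wrap_cube(dX),
                            Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".upsample2_fw")]]
Rcpp::NumericVector upsample2_fw(Rcpp::NumericVector x) {
  cube X = as_cube(x);
  cube out(2 * X.n_rows, 2 * X.n_cols, X.n_slices);
  for (uword c = 0; c < X.n_slices; ++c)
    for (uword j = 0; j < X.n_cols; ++j)
      for (uword i = 0; i < X.n_rows; ++i) {
        const double v = X(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return wrap_cube(out);
}

// [[Rcpp::export(name = ".upsample2_bw")]]
Rcpp::NumericVector upsample2_bw(Rcpp::NumericVector dy) {
  cube dY = as_cube(dy);
  cube out(dY.n_rows / 2, dY.n_cols / 2, dY.n_slices);
  for (uword c = 0; c < out.n_slices; ++c)
    for (uword j = 0; j < out.n_cols; ++j)
      for (uword i = 0; i < out.n_rows; ++i)
        out(i, j, c) = dY(2 * i, 2 * j, c) + dY(2 * i + 1, 2 * j, c) +
                       dY(2 * i, 2 * j + 1, c) + dY(2 * i + 1, 2 * j + 1, c);
  return wrap_cube(out);
}

// Bilinear warp. `minv` is the 2x3 affine mapping OUTPUT pixel-centre
// coordinates (0-based x, y) to INPUT coordinates. Outside the input the
// sample is either clamped to the border or filled with `fill` (length C).
// [[Rcpp::export(name = ".affine_warp")]]
Rcpp::NumericVector affine_warp(Rcpp::NumericVector img, const arma::mat& minv,
                                int out_h, int out_w, const arma::vec& fill,
                                bool clamp_border) {
  cube X = as_cube(img);
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube out(out_h, out_w, C);
  for (int xo = 0; xo < out_w; ++xo) {
    for (int yo = 0; yo < out_h; ++yo) {
      double xi = minv(0, 0) * xo + minv(0, 1) * yo + minv(0, 2);
      double yi = minv(1, 0) * xo + minv(1, 1) * yo + minv(1, 2);
      bool inside = xi >= 0.0 && xi <= W - 1.0 && yi >= 0.0 && yi <= H - 1.0;
      if (!inside && !clamp_border) {
        for (int c = 0; c < C; ++c) out(yo, xo, c) = fill(c);
        continue;
      }
      if (xi < 0) xi = 0; if (xi > W - 1.0) xi = W - 1.0;
      if (yi < 0) yi = 0; if (yi > H - 1.0) yi = H - 1.0;
      const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double fx = xi - x0, fy = yi - y0;
      for (int c = 0; c < C; ++c) {
        const double v =
            (1 - fx) * ((1 - fy) * X(y0, x0, c) + fy * X(y1, x0, c)) +
            fx * ((1 - fy) * X(y0, x1, c) + fy * X(y1, x1, c));
        out(yo, xo, c) = v;
      }
    }
  }
  return wrap_cube(out);
}
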