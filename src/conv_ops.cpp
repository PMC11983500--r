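#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction and accumulation for the convolution layers.
// Arrays are in [H x W x C x N] column-major layout (R convention);
// patch-matrix rows are ordered (h_out, w_out, n), columns (i, j, c).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& xp, int Hp, int Wp, int C,
                         int N, int k, int stride, int oh, int ow) {
  NumericMatrix cols(oh * ow * N, k * k * C);
  const double* x = xp.begin();
  int m = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i, ++m) {
        double* col = &cols(0, m);
        R_xlen_t r = 0;
        for (int n = 0; n < N; ++n) {
          const double* base =
              x + (R_xlen_t)Hp * Wp * (c + (R_xlen_t)C * n);
          for (int w = 0; w < ow; ++w) {
            const double* p = base + (R_xlen_t)(j + w * stride) * Hp + i;
            for (int h = 0; h < oh; ++h) col[r++] = p[(R_xlen_t)h * stride];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& dcols, int Hp, int Wp, int C,
                         int N, int k, int stride, int oh, int ow) {
  NumericVector dxp((R_xlen_t)Hp * Wp * C * N);
  double* x = dxp.begin();
  int m = 0;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i, ++m) {
        const double* col = &dcols(0, m);
        R_xlen_t r = 0;
        for (int n = 0; n < N; ++n) {
          double* base = x + (R_xlen_t)Hp * Wp * (c + (R_xlen_t)C * n);
          for (int w = 0; w < ow; ++w) {
            double* p = base + (R_xlen_t)(j + w * stride) * Hp + i;
            for (int h = 0; h < oh; ++h) p[(R_xlen_t)h * stride] += col[r++];
          }
        }
      }
    }
  }
  dxp.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  return dxp;
}

// reshape conv output [(oh*ow*N) x Cout] (rows ordered h,w,n) to an
// [oh x ow x Cout x N] array
// [[Rcpp::export]]
NumericVector cpp_mat2feat(const NumericMatrix& m, int oh, int ow, int Cout,
                           int N) {
  NumericVector out((R_xlen_t)oh * ow * Cout * N);
  double* o = out.begin();
  const R_xlen_t hw = (R_xlen_t)oh * ow;
  for (int c = 0; c < Cout; ++c) {
    const double* col = &m(0, c);
    for (int n = 0; n < N; ++n) {
      double* dst = o + hw * (c + (R_xlen_t)Cout * n);
      const double* src = col + hw * n;
      std::copy(src, src + hw, dst);
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, Cout, N);
  return out;
}

// inverse of cpp_mat2feat: [oh x ow x Cout x N] -> [(oh*ow*N) x Cout]
// [[Rcpp::export]]
NumericMatrix cpp_feat2mat(const NumericVector& a, int oh, int ow, int Cout,
                           int N) {
  NumericMatrix m((R_xlen_t)oh * ow * N, Cout);
  const double* x = a.begin();
  const R_xlen_t hw = (R_xlen_t)oh * ow;
  for (int c = 0; c < Cout; ++c) {
    double* col = &m(0, c);
    for (int n = 0; n < N; ++n) {
      const double* src = x + hw * (c + (R_xlen_t)Cout * n);
      std::copy(src, src + hw, col + hw * n);
    }
  }
  return m;
}

// zero-pad spatial dims of [H x W x C x N]
// [[Rcpp::export]]
NumericVector cpp_pad_hw(const NumericVector& a, int H, int W, int C, int N,
                         int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  NumericVector out((R_xlen_t)Hp * Wp * C * N);
  const double* x = a.begin();
  double* o = out.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* src = x + (R_xlen_t)H * W * cn;
    double* dst = o + (R_xlen_t)Hp * Wp * cn;
    for (int w = 0; w < W; ++w)
      std::copy(src + (R_xlen_t)w * H, src + (R_xlen_t)(w + 1) * H,
                dst + (R_xlen_t)(w + p) * Hp + p);
  }
  out.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  return out;
}

// crop spatial padding: inverse of cpp_pad_hw (no accumulation)
// [[Rcpp::export]]
NumericVector cpp_crop_hw(const NumericVector& a, int Hp, int Wp, int C,
                          int N, int p) {
  const int H = Hp - 2 * p, W = Wp - 2 * p;
  NumericVector out((R_xlen_t)H * W * C * N);
  const double* x = a.begin();
  double* o = out.begin();
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* src = x + (R_xlen_t)Hp * Wp * cn;
    double* dst = o + (R_xlen_t)H * W * cn;
    for (int w = 0; w < W; ++w)
      std::copy(src + (R_xlen_t)(w + p) * Hp + p,
                src + (R_xlen_t)(w + p) * Hp + p + H,
                dst + (R_xlen_t)w * H);
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// cyclic coordinate descent for 1/2||H b - y||^2 + lambda ||b||_1 given the
// Gram matrix G = H'H and correlation c0 = H'y (covariance updates)
// [[Rcpp::export]]
NumericVector cpp_lasso_cd(const NumericMatrix& G, const NumericVector& c0,
                           double lambda, NumericVector beta0, double tol,
                           int max_iter) {
  const int L = G.ncol();
  NumericVector beta = clone(beta0);
  std::vector<double> gb(L, 0.0);  // (G beta)_j
  for (int j = 0; j < L; ++j) {
    if (beta[j] != 0.0) {
      const double* gcol = &G(0, j);
      for (int i = 0; i < L; ++i) gb[i] += gcol[i] * beta[j];
    }
  }
  for (int it = 0; it < max_iter; ++it) {
    double delta_max = 0.0;
    for (int j = 0; j < L; ++j) {
      const double hh = G(j, j);
      if (hh <= 0.0) continue;
      const double rho = c0[j] - gb[j] + hh * beta[j];
      double bnew = 0.0;
      if (rho > lambda) bnew = (rho - lambda) / hh;
      else if (rho < -lambda) bnew = (rho + lambda) / hh;
      const double d = bnew - beta[j];
      if (d != 0.0) {
        beta[j] = bnew;
        const double* gcol = &G(0, j);
        for (int i = 0; i < L; ++i) gb[i] += gcol[i] * d;
        const double ad = d < 0 ? -d : d;
        if (ad > delta_max) delta_max = ad;
      }
    }
    if (delta_max < tol) break;
  }
  return beta;
}
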