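// Dense numeric kernels backing the network and image modules.
//
// Tensor convention: feature maps are R arrays [h, w, c, n] (column-major,
// h fastest).  Convolution weights arrive flattened as a
// (kh*kw*c_in) x c_out matrix whose row index is ki + kh*(kj + kw*ci),
// i.e. the column-major flattening of an R array [kh, kw, c_in, c_out].
// All convolutions use im2col + GEMM; the backward pass rebuilds the
// column matrix instead of caching it, trading ~30% recompute for memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static int out_dim(int d, int k, int s, int pad, bool ceil_mode) {
  double num = double(d + 2 * pad - k);
  int o = ceil_mode ? (int)std::ceil(num / s) + 1 : (int)std::floor(num / s) + 1;
  if (ceil_mode && (o - 1) * s >= d + pad) o -= 1;  // last window must start inside
  return o;
}

// [[Rcpp::export]]
IntegerVector conv_out_shape(IntegerVector in_hw, int kh, int kw, int stride,
                             int ph, int pw, bool ceil_mode) {
  return IntegerVector::create(out_dim(in_hw[0], kh, stride, ph, ceil_mode),
                               out_dim(in_hw[1], kw, stride, pw, ceil_mode));
}

static arma::mat im2col(const double* x, int h, int w, int c, int n,
                        int kh, int kw, int stride, int ph, int pw,
                        int oh, int ow) {
  arma::mat cols((size_t)oh * ow * n, (size_t)kh * kw * c);
  for (int ci = 0; ci < c; ++ci)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        size_t q = ki + (size_t)kh * (kj + (size_t)kw * ci);
        double* col = cols.colptr(q);
        for (int l = 0; l < n; ++l) {
          const double* xs = x + (size_t)h * w * c * l + (size_t)h * w * ci;
          double* dst = col + (size_t)oh * ow * l;
          for (int j = 0; j < ow; ++j) {
            int sj = j * stride - pw + kj;
            bool jin = (sj >= 0 && sj < w);
            const double* xcol = xs + (size_t)h * sj;
            for (int i = 0; i < oh; ++i) {
              int si = i * stride - ph + ki;
              dst[i + (size_t)oh * j] =
                  (jin && si >= 0 && si < h) ? xcol[si] : 0.0;
            }
          }
        }
      }
  return cols;
}

static void col2im(arma::mat& dcols, double* dx, int h, int w, int c, int n,
                   int kh, int kw, int stride, int ph, int pw, int oh, int ow) {
  for (int ci = 0; ci < c; ++ci)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        size_t q = ki + (size_t)kh * (kj + (size_t)kw * ci);
        double* col = dcols.colptr(q);
        for (int l = 0; l < n; ++l) {
          double* xs = dx + (size_t)h * w * c * l + (size_t)h * w * ci;
          double* src = col + (size_t)oh * ow * l;
          for (int j = 0; j < ow; ++j) {
            int sj = j * stride - pw + kj;
            if (sj < 0 || sj >= w) continue;
            double* xcol = xs + (size_t)h * sj;
            for (int i = 0; i < oh; ++i) {
              int si = i * stride - ph + ki;
              if (si >= 0 && si < h) xcol[si] += src[i + (size_t)oh * j];
            }
          }
        }
      }
}

// y (r x cout, rows r = i + oh*j + oh*ow*l) -> array [oh, ow, cout, n]
static NumericVector mat_to_array(const arma::mat& y, int oh, int ow, int cout,
                                  int n) {
  NumericVector out((size_t)oh * ow * cout * n);
  double* op = REAL(out);
  size_t plane = (size_t)oh * ow;
  for (int k = 0; k < cout; ++k) {
    const double* col = y.colptr(k);
    for (int l = 0; l < n; ++l)
      std::memcpy(op + plane * (k + (size_t)cout * l), col + plane * l,
                  plane * sizeof(double));
  }
  out.attr("dim") = IntegerVector::create(oh, ow, cout, n);
  return out;
}

static arma::mat array_to_mat(const double* a, int oh, int ow, int cout, int n) {
  arma::mat y((size_t)oh * ow * n, cout);
  size_t plane = (size_t)oh * ow;
  for (int k = 0; k < cout; ++k) {
    double* col = y.colptr(k);
    for (int l = 0; l < n; ++l)
      std::memcpy(col + plane * l, a + plane * (k + (size_t)cout * l),
                  plane * sizeof(double));
  }
  return y;
}

// [[Rcpp::export]]
List conv_forward_cpp(NumericVector x, NumericMatrix w,
                      NumericVector b, int kh, int kw, int stride,
                      int ph, int pw, bool relu, bool return_cols) {
  IntegerVector d = x.attr("dim");
  int h = d[0], wd = d[1], c = d[2], n = d[3];
  int oh = out_dim(h, kh, stride, ph, false);
  int ow = out_dim(wd, kw, stride, pw, false);
  int cout = w.ncol();
  arma::mat W(w.begin(), w.nrow(), cout, false);
  arma::rowvec bb(b.begin(), cout, false);
  if (kh == 1 && kw == 1 && stride == 1 && ph == 0 && pw == 0) {
    // pointwise convolution: per-image plane is already the im2col matrix
    NumericVector ya((size_t)h * wd * cout * n);
    size_t plane = (size_t)h * wd;
    for (int l = 0; l < n; ++l) {
      arma::mat Xl(const_cast<double*>(REAL(x)) + plane * c * l, plane, c,
                   false, true);
      arma::mat Yl(REAL(ya) + plane * cout * l, plane, cout, false, true);
      Yl = Xl * W;
      Yl.each_row() += bb;
      if (relu) Yl.for_each([](double& v) { if (v < 0) v = 0; });
    }
    ya.attr("dim") = IntegerVector::create(h, wd, cout, n);
    return List::create(_["y"] = ya);
  }
  arma::mat cols = im2col(REAL(x), h, wd, c, n, kh, kw, stride, ph, pw, oh, ow);
  arma::mat y = cols * W;
  y.each_row() += bb;
  if (relu) y.for_each([](double& v) { if (v < 0) v = 0; });
  NumericVector ya = mat_to_array(y, oh, ow, cout, n);
  if (return_cols) {
    // hand the column matrix to R as an external pointer (no copy); the
    // backward pass reuses it instead of rebuilding
    XPtr<arma::mat> p(new arma::mat(std::move(cols)), true);
    return List::create(_["y"] = ya, _["cols"] = p);
  }
  return List::create(_["y"] = ya);
}

// [[Rcpp::export]]
List conv_backward_cpp(NumericVector x, NumericMatrix w, NumericVector dy,
                       NumericVector y, int kh, int kw, int stride, int ph,
                       int pw, bool relu, bool need_dx, SEXP cached_cols) {
  IntegerVector d = x.attr("dim");
  int h = d[0], wd = d[1], c = d[2], n = d[3];
  IntegerVector dd = dy.attr("dim");
  int oh = dd[0], ow = dd[1], cout = dd[2];
  arma::mat W(w.begin(), w.nrow(), cout, false);
  if (kh == 1 && kw == 1 && stride == 1 && ph == 0 && pw == 0) {
    size_t plane = (size_t)h * wd;
    arma::mat dW(c, cout, arma::fill::zeros);
    arma::vec db(cout, arma::fill::zeros);
    NumericVector dx;
    if (need_dx) {
      dx = NumericVector((size_t)h * wd * c * n);
      dx.attr("dim") = d;
    }
    for (int l = 0; l < n; ++l) {
      arma::mat Xl(const_cast<double*>(REAL(x)) + plane * c * l, plane, c,
                   false, true);
      arma::mat Gl(const_cast<double*>(REAL(dy)) + plane * cout * l, plane,
                   cout, false, true);
      arma::mat G = Gl;  // copy: the relu mask must not alter the caller's dy
      if (relu) {
        arma::mat Yl(const_cast<double*>(REAL(y)) + plane * cout * l, plane,
                     cout, false, true);
        G.elem(arma::find(Yl <= 0)).zeros();
      }
      dW += Xl.t() * G;
      db += arma::sum(G, 0).t();
      if (need_dx) {
        arma::mat DXl(REAL(dx) + plane * c * l, plane, c, false, true);
        DXl = G * W.t();
      }
    }
    return List::create(_["dw"] = wrap(dW), _["db"] = wrap(db),
                        _["dx"] = need_dx ? (SEXP)dx : R_NilValue);
  }
  arma::mat dy_mat = array_to_mat(REAL(dy), oh, ow, cout, n);
  if (relu) {
    arma::mat y_mat = array_to_mat(REAL(y), oh, ow, cout, n);
    dy_mat.elem(arma::find(y_mat <= 0)).zeros();
  }
  arma::mat dW;
  if (cached_cols != R_NilValue) {
    XPtr<arma::mat> cols(cached_cols);
    dW = cols->t() * dy_mat;
  } else {
    arma::mat cols = im2col(REAL(x), h, wd, c, n, kh, kw, stride, ph, pw,
                            oh, ow);
    dW = cols.t() * dy_mat;
  }
  arma::rowvec db = arma::sum(dy_mat, 0);
  List out = List::create(_["dw"] = wrap(dW),
                          _["db"] = wrap(arma::vec(db.t())),
                          _["dx"] = R_NilValue);
  if (need_dx) {
    arma::mat dcols = dy_mat * W.t();
    NumericVector dx((size_t)h * wd * c * n);
    col2im(dcols, REAL(dx), h, wd, c, n, kh, kw, stride, ph, pw, oh, ow);
    dx.attr("dim") = d;
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int kh, int kw, int stride, int ph,
                         int pw, bool ceil_mode) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  int oh = out_dim(h, kh, stride, ph, ceil_mode);
  int ow = out_dim(w, kw, stride, pw, ceil_mode);
  NumericVector y((size_t)oh * ow * c * n);
  IntegerVector idx(y.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  size_t t = 0;
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < c; ++k) {
      const double* xs = xp + (size_t)h * w * (k + (size_t)c * l);
      size_t base = (size_t)h * w * (k + (size_t)c * l);
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int kj = 0; kj < kw; ++kj) {
            int sj = j * stride - pw + kj;
            if (sj < 0 || sj >= w) continue;
            for (int ki = 0; ki < kh; ++ki) {
              int si = i * stride - ph + ki;
              if (si < 0 || si >= h) continue;
              double v = xs[si + (size_t)h * sj];
              if (v > best) { best = v; bidx = si + (size_t)h * sj; }
            }
          }
          size_t out_pos = (size_t)i + (size_t)oh * j +
                           (size_t)oh * ow * (k + (size_t)c * l);
          yp[out_pos] = best;
          ip[out_pos] = (int)(base + bidx);
          ++t;
        }
    }
  (void)t;
  y.attr("dim") = IntegerVector::create(oh, ow, c, n);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  size_t sz = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(sz);
  double* dp = REAL(dx);
  const double* gp = REAL(dy);
  const int* ip = INTEGER(idx);
  for (R_xlen_t t = 0; t < dy.size(); ++t) dp[ip[t]] += gp[t];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export]]
NumericVector avgpool_forward_cpp(NumericVector x, int kh, int kw, int stride) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  int oh = out_dim(h, kh, stride, 0, false);
  int ow = out_dim(w, kw, stride, 0, false);
  NumericVector y((size_t)oh * ow * c * n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double inv = 1.0 / (kh * kw);
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < c; ++k) {
      const double* xs = xp + (size_t)h * w * (k + (size_t)c * l);
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double s = 0;
          for (int kj = 0; kj < kw; ++kj)
            for (int ki = 0; ki < kh; ++ki)
              s += xs[(i * stride + ki) + (size_t)h * (j * stride + kj)];
          yp[(size_t)i + (size_t)oh * j + (size_t)oh * ow * (k + (size_t)c * l)] =
              s * inv;
        }
    }
  y.attr("dim") = IntegerVector::create(oh, ow, c, n);
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_backward_cpp(NumericVector dy, IntegerVector xdim, int kh,
                                   int kw, int stride) {
  int h = xdim[0], w = xdim[1], c = xdim[2], n = xdim[3];
  IntegerVector dd = dy.attr("dim");
  int oh = dd[0], ow = dd[1];
  NumericVector dx((size_t)h * w * c * n);
  double* dp = REAL(dx);
  const double* gp = REAL(dy);
  double inv = 1.0 / (kh * kw);
  for (int l = 0; l < n; ++l)
    for (int k = 0; k < c; ++k) {
      double* xs = dp + (size_t)h * w * (k + (size_t)c * l);
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double g = gp[(size_t)i + (size_t)oh * j +
                        (size_t)oh * ow * (k + (size_t)c * l)] * inv;
          for (int kj = 0; kj < kw; ++kj)
            for (int ki = 0; ki < kh; ++ki)
              xs[(i * stride + ki) + (size_t)h * (j * stride + kj)] += g;
        }
    }
  dx.attr("dim") = xdim;
  return dx;
}

// pow(d, -beta) with a fast closed form for the conventional beta = 0.75
static inline double inv_pow_beta(double d, double beta) {
  if (beta == 0.75) return 1.0 / std::sqrt(d * std::sqrt(d));
  return std::pow(d, -beta);
}

// Cross-channel (local response) normalization:
//   y_c = x_c / (k + alpha * sum_{c' in window(c)} x_{c'}^2)^beta
// [[Rcpp::export]]
List lrn_forward_cpp(NumericVector x, int window, double k, double alpha,
                     double beta) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  int half = window / 2;
  NumericVector y(x.size()), S(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* sp = REAL(S);
  size_t plane = (size_t)h * w;
  for (int l = 0; l < n; ++l) {
    const double* xb = xp + plane * c * l;
    double* yb = yp + plane * c * l;
    double* sb = sp + plane * c * l;
    for (size_t p = 0; p < plane; ++p)
      for (int ci = 0; ci < c; ++ci) {
        double s = 0;
        int lo = std::max(0, ci - half), hi = std::min(c - 1, ci + half);
        for (int cj = lo; cj <= hi; ++cj) {
          double v = xb[p + plane * cj];
          s += v * v;
        }
        double denom = k + alpha * s;
        sb[p + plane * ci] = denom;
        yb[p + plane * ci] = xb[p + plane * ci] * inv_pow_beta(denom, beta);
      }
  }
  y.attr("dim") = d;
  S.attr("dim") = d;
  return List::create(_["y"] = y, _["scale"] = S);
}

// [[Rcpp::export]]
NumericVector lrn_backward_cpp(NumericVector x, NumericVector S,
                               NumericVector dy, int window, double alpha,
                               double beta) {
  IntegerVector d = x.attr("dim");
  int h = d[0], w = d[1], c = d[2], n = d[3];
  int half = window / 2;
  NumericVector dx(x.size());
  const double* xp = REAL(x);
  const double* sp = REAL(S);
  const double* gp = REAL(dy);
  double* dp = REAL(dx);
  size_t plane = (size_t)h * w;
  for (int l = 0; l < n; ++l) {
    size_t off = plane * c * l;
    for (size_t p = 0; p < plane; ++p)
      for (int ci = 0; ci < c; ++ci) {
        size_t ii = off + p + plane * ci;
        double acc = gp[ii] * inv_pow_beta(sp[ii], beta);
        // window symmetry: ci appears in window(cj) iff cj in window(ci)
        int lo = std::max(0, ci - half), hi = std::min(c - 1, ci + half);
        double cross = 0;
        for (int cj = lo; cj <= hi; ++cj) {
          size_t jj = off + p + plane * cj;
          cross += gp[jj] * xp[jj] * inv_pow_beta(sp[jj], beta) / sp[jj];
        }
        dp[ii] = acc - 2.0 * alpha * beta * xp[ii] * cross;
      }
  }
  dx.attr("dim") = d;
  return dx;
}

static double reflect_coord(double t, int d) {
  if (d == 1) return 0.0;
  double period = 2.0 * (d - 1);
  t -= period * std::floor(t / period);  // fold into [0, period)
  return (t > d - 1) ? period - t : t;
}

// Bilinear warp of src [h, w, c]: output pixel (row r, col q), 0-based centers,
// samples source at (sx, sy) = M %*% (q, r, 1); sx = source col, sy = source row.
// boundary: 0 -> constant `fill`, 1 -> reflect at the border.
// [[Rcpp::export]]
NumericVector warp_affine_cpp(NumericVector src, int out_h, int out_w,
                              NumericVector m, int boundary, double fill) {
  IntegerVector d = src.attr("dim");
  int h = d[0], w = d[1], c = d.size() > 2 ? d[2] : 1;
  NumericVector out((size_t)out_h * out_w * c);
  const double* sp = REAL(src);
  double* op = REAL(out);
  for (int r = 0; r < out_h; ++r)
    for (int q = 0; q < out_w; ++q) {
      double sx = m[0] * q + m[1] * r + m[2];
      double sy = m[3] * q + m[4] * r + m[5];
      bool outside = (sx < -0.5 || sx > w - 0.5 || sy < -0.5 || sy > h - 0.5);
      if (boundary == 0 && outside) {
        for (int k = 0; k < c; ++k)
          op[(size_t)r + (size_t)out_h * q + (size_t)out_h * out_w * k] = fill;
        continue;
      }
      double x0f = std::floor(sx), y0f = std::floor(sy);
      double fx = sx - x0f, fy = sy - y0f;
      int xs[2], ys[2];
      for (int t = 0; t < 2; ++t) {
        double xc = x0f + t, yc = y0f + t;
        if (boundary == 1) {
          xc = reflect_coord(xc, w);
          yc = reflect_coord(yc, h);
        } else {
          xc = std::min(std::max(xc, 0.0), (double)(w - 1));
          yc = std::min(std::max(yc, 0.0), (double)(h - 1));
        }
        xs[t] = (int)xc;
        ys[t] = (int)yc;
      }
      for (int k = 0; k < c; ++k) {
        const double* pl = sp + (size_t)h * w * k;
        double v00 = pl[ys[0] + (size_t)h * xs[0]];
        double v01 = pl[ys[0] + (size_t)h * xs[1]];
        double v10 = pl[ys[1] + (size_t)h * xs[0]];
        double v11 = pl[ys[1] + (size_t)h * xs[1]];
        double v = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                   fy * ((1 - fx) * v10 + fx * v11);
        op[(size_t)r + (size_t)out_h * q + (size_t)out_h * out_w * k] = v;
      }
    }
  if (d.size() > 2)
    out.attr("dim") = IntegerVector::create(out_h, out_w, c);
  else
    out.attr("dim") = IntegerVector::create(out_h, out_w);
  return out;
}

// Even-odd scanline rasterization of a polygon given as an N x 2 matrix of
// (x, y) 0-based pixel coordinates.  A pixel is inside when its center is.
// [[Rcpp::export]]
LogicalMatrix polygon_mask_cpp(int h, int w, NumericMatrix poly) {
  LogicalMatrix mask(h, w);
  int nv = poly.nrow();
  std::vector<double> xs;
  for (int r = 0; r < h; ++r) {
    double yr = r;
    xs.clear();
    for (int e = 0; e < nv; ++e) {
      double x1 = poly(e, 0), y1 = poly(e, 1);
      double x2 = poly((e + 1) % nv, 0), y2 = poly((e + 1) % nv, 1);
      if ((y1 > yr) != (y2 > yr))
        xs.push_back(x1 + (yr - y1) * (x2 - x1) / (y2 - y1));
    }
    std::sort(xs.begin(), xs.end());
    for (size_t m = 0; m + 1 < xs.size(); m += 2) {
      int c0 = std::max(0, (int)std::ceil(xs[m] - 1e-9));
      int c1 = std::min(w - 1, (int)std::floor(xs[m + 1] - 1e-9));
      for (int cc = c0; cc <= c1; ++cc) mask(r, cc) = true;
    }
  }
  return mask;
}
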