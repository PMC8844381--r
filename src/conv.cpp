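// Convolution and pooling kernels for the small CNN trainer.
//
// The 3x3 same-padding convolution is evaluated as im2col followed by a
// single BLAS dgemm per layer (and the transposed pair of dgemms for the
// gradients), which is the standard fast path for small CNNs on CPU.
// Arrays are column-major [h, w, c, n] as R lays them out.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// cols: (h*w*n) x (9*c); column r = (di + 3*dj + 9*ch) holds x shifted by
// (di-1, dj-1), zero outside the image.
static void im2col3(const double *x, int h, int w, int c, int n,
                    double *cols) {
  const R_xlen_t hw = (R_xlen_t)h * w, rows = hw * n;
  for (int ch = 0; ch < c; ++ch) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        double *dst0 = cols + ((R_xlen_t)(di + 3 * dj + 9 * ch)) * rows;
        const int oi = di - 1, oj = dj - 1;
        for (int m = 0; m < n; ++m) {
          const double *xs = x + ((R_xlen_t)m * c + ch) * hw;
          double *dst = dst0 + (R_xlen_t)m * hw;
          for (int j = 0; j < w; ++j) {
            const int sj = j + oj;
            double *d = dst + (R_xlen_t)j * h;
            if (sj < 0 || sj >= w) {
              std::fill(d, d + h, 0.0);
              continue;
            }
            const double *s = xs + (R_xlen_t)sj * h + oi;
            const int i0 = std::max(0, -oi), i1 = std::min(h, h - oi);
            if (i0 > 0) d[0] = 0.0;
            std::copy(s + i0, s + i1, d + i0);
            if (i1 < h) d[h - 1] = 0.0;
          }
        }
      }
    }
  }
}

// scatter-add of cols back into x-shaped gradient (transpose of im2col3)
static void col2im3(const double *cols, int h, int w, int c, int n,
                    double *dx) {
  const R_xlen_t hw = (R_xlen_t)h * w, rows = hw * n;
  for (int ch = 0; ch < c; ++ch) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const double *src0 = cols + ((R_xlen_t)(di + 3 * dj + 9 * ch)) * rows;
        const int oi = di - 1, oj = dj - 1;
        for (int m = 0; m < n; ++m) {
          double *xs = dx + ((R_xlen_t)m * c + ch) * hw;
          const double *src = src0 + (R_xlen_t)m * hw;
          for (int j = 0; j < w; ++j) {
            const int sj = j + oj;
            if (sj < 0 || sj >= w) continue;
            const double *s = src + (R_xlen_t)j * h;
            double *d = xs + (R_xlen_t)sj * h + oi;
            const int i0 = std::max(0, -oi), i1 = std::min(h, h - oi);
            for (int i = i0; i < i1; ++i) d[i] += s[i];
          }
        }
      }
    }
  }
}

// (h*w*n, f) column-major -> [h, w, f, n]
static void to_hwfn(const double *src, int h, int w, int f, int n,
                    double *dst) {
  const R_xlen_t hw = (R_xlen_t)h * w;
  for (int ff = 0; ff < f; ++ff) {
    for (int m = 0; m < n; ++m) {
      const double *s = src + ((R_xlen_t)ff * n + m) * hw;
      double *d = dst + ((R_xlen_t)m * f + ff) * hw;
      std::copy(s, s + hw, d);
    }
  }
}

// [h, w, f, n] -> (h*w*n, f) column-major
static void from_hwfn(const double *src, int h, int w, int f, int n,
                      double *dst) {
  const R_xlen_t hw = (R_xlen_t)h * w;
  for (int ff = 0; ff < f; ++ff) {
    for (int m = 0; m < n; ++m) {
      const double *s = src + ((R_xlen_t)m * f + ff) * hw;
      double *d = dst + ((R_xlen_t)ff * n + m) * hw;
      std::copy(s, s + hw, d);
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3_fwd_cpp(NumericVector x, NumericVector kern,
                            NumericVector bias) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = kern.attr("dim");
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3], f = kd[3];
  const R_xlen_t rows = (R_xlen_t)h * w * n;
  std::vector<double> cols(rows * 9 * c);
  im2col3(x.begin(), h, w, c, n, cols.data());
  std::vector<double> outmat(rows * f);
  const int m_ = (int)rows, n_ = f, k_ = 9 * c;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m_, &n_, &k_, &one, cols.data(), &m_,
                  kern.begin(), &k_, &zero, outmat.data(), &m_ FCONE FCONE);
  // add bias per filter, then lay out as [h, w, f, n]
  for (int ff = 0; ff < f; ++ff) {
    double *o = outmat.data() + (R_xlen_t)ff * rows;
    const double b = bias[ff];
    for (R_xlen_t t = 0; t < rows; ++t) o[t] += b;
  }
  NumericVector out((R_xlen_t)h * w * f * n);
  out.attr("dim") = IntegerVector::create(h, w, f, n);
  // outmat columns are (frame-major rows, filter) = (h*w x n) stacked per f
  to_hwfn(outmat.data(), h, w, f, n, out.begin());
  return out;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(NumericVector dout, NumericVector x, NumericVector kern) {
  IntegerVector xd = x.attr("dim");
  IntegerVector kd = kern.attr("dim");
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3], f = kd[3];
  const R_xlen_t rows = (R_xlen_t)h * w * n;
  const int m_ = (int)rows, k9c = 9 * c;
  const double one = 1.0, zero = 0.0;

  std::vector<double> dmat(rows * f);
  from_hwfn(dout.begin(), h, w, f, n, dmat.data());

  NumericVector db(f);
  for (int ff = 0; ff < f; ++ff) {
    const double *d = dmat.data() + (R_xlen_t)ff * rows;
    double acc = 0.0;
    for (R_xlen_t t = 0; t < rows; ++t) acc += d[t];
    db[ff] = acc;
  }

  std::vector<double> cols(rows * k9c);
  im2col3(x.begin(), h, w, c, n, cols.data());

  NumericVector dk((R_xlen_t)9 * c * f);
  dk.attr("dim") = kd;
  F77_CALL(dgemm)("T", "N", &k9c, &f, &m_, &one, cols.data(), &m_,
                  dmat.data(), &m_, &zero, dk.begin(), &k9c FCONE FCONE);

  std::vector<double> dcols(rows * k9c);
  F77_CALL(dgemm)("N", "T", &m_, &k9c, &f, &one, dmat.data(), &m_,
                  kern.begin(), &k9c, &zero, dcols.data(), &m_ FCONE FCONE);

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  col2im3(dcols.data(), h, w, c, n, dx.begin());
  return List::create(_["dx"] = dx, _["dk"] = dk, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int h = xd[0], w = xd[1], c = xd[2], n = xd[3];
  const int h2 = h / 2, w2 = w / 2;
  NumericVector out((R_xlen_t)h2 * w2 * c * n);
  IntegerVector arg((R_xlen_t)h2 * w2 * c * n);
  out.attr("dim") = IntegerVector::create(h2, w2, c, n);
  arg.attr("dim") = IntegerVector::create(h2, w2, c, n);
  const double *px = x.begin();
  double *po = out.begin();
  int *pa = arg.begin();
  for (R_xlen_t s = 0; s < (R_xlen_t)c * n; ++s) {
    const double *xs = px + s * h * w;
    double *os = po + s * h2 * w2;
    int *as = pa + s * h2 * w2;
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i) {
        // corner order: (odd,odd), (even,odd), (odd,even), (even,even);
        // strict > keeps the earliest corner on ties
        const double v1 = xs[2 * i + (R_xlen_t)(2 * j) * h];
        const double v2 = xs[2 * i + 1 + (R_xlen_t)(2 * j) * h];
        const double v3 = xs[2 * i + (R_xlen_t)(2 * j + 1) * h];
        const double v4 = xs[2 * i + 1 + (R_xlen_t)(2 * j + 1) * h];
        double best = v1; int k = 1;
        if (v2 > best) { best = v2; k = 2; }
        if (v3 > best) { best = v3; k = 3; }
        if (v4 > best) { best = v4; k = 4; }
        os[i + (R_xlen_t)j * h2] = best;
        as[i + (R_xlen_t)j * h2] = k;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dout, IntegerVector argmax,
                               IntegerVector xdim) {
  const int h = xdim[0], w = xdim[1], c = xdim[2], n = xdim[3];
  const int h2 = h / 2, w2 = w / 2;
  NumericVector dx((R_xlen_t)h * w * c * n);
  dx.attr("dim") = xdim;
  const double *pd = dout.begin();
  const int *pa = argmax.begin();
  double *px = dx.begin();
  for (R_xlen_t s = 0; s < (R_xlen_t)c * n; ++s) {
    const double *ds = pd + s * h2 * w2;
    const int *as = pa + s * h2 * w2;
    double *xs = px + s * h * w;
    for (int j = 0; j < w2; ++j) {
      for (int i = 0; i < h2; ++i) {
        const int k = as[i + (R_xlen_t)j * h2];
        const int ii = 2 * i + ((k == 2 || k == 4) ? 1 : 0);
        const int jj = 2 * j + ((k >= 3) ? 1 : 0);
        xs[ii + (R_xlen_t)jj * h] = ds[i + (R_xlen_t)j * h2];
      }
    }
  }
  return dx;
}

// Circular column filtering for the wavelet transform:
// corr: y[i,j] = sum_k h[k] x[(i + k - center) mod n, j]
// conv: y[i,j] = sum_k h[k] x[(i - k + center) mod n, j]
// [[Rcpp::export]]
NumericMatrix filt_cols_cpp(NumericMatrix x, NumericVector taps,
                            int center, bool conv) {
  const int n = x.nrow(), p = x.ncol(), L = taps.size();
  NumericMatrix y(n, p);
  const double *px = x.begin();
  double *py = y.begin();
  for (int k = 0; k < L; ++k) {
    const double hv = taps[k];
    if (hv == 0.0) continue;
    int off = conv ? (-(k)+center) : (k - center);
    off = ((off % n) + n) % n;      // y[i] += hv * x[(i + off) mod n]
    for (int j = 0; j < p; ++j) {
      const double *xc = px + (R_xlen_t)j * n;
      double *yc = py + (R_xlen_t)j * n;
      const int first = n - off;    // i in [0, first) reads xc[i + off]
      for (int i = 0; i < first; ++i) yc[i] += hv * xc[i + off];
      for (int i = first; i < n; ++i) yc[i] += hv * xc[i + off - n];
    }
  }
  return y;
}
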