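#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Separable 1D correlation along one axis of a 3D array stored in R's
// column-major order, with replicate (nearest) boundary padding.  The kernel
// is assumed symmetric (a discrete Gaussian), so correlation == convolution.
// Inner loops run over the contiguous x index wherever possible so the
// compiler can vectorize them; boundary clamping happens per tap, outside
// the hot loop.
static inline int clampi(int i, int L) {
  return i < 0 ? 0 : (i >= L ? L - 1 : i);
}

// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector x, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != x.size())
    stop("dims inconsistent with data length");
  if (kernel.size() % 2 == 0) stop("kernel length must be odd");
  const int r = (kernel.size() - 1) / 2;
  NumericVector out(x.size());
  const double *in = x.begin();
  const double *k = kernel.begin();
  double *o = out.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  if (axis == 0) {
    // per contiguous line: split interior (no clamping) from edges
    for (int kk = 0; kk < nz; ++kk)
      for (int jj = 0; jj < ny; ++jj) {
        const double *line = in + jj * sy + kk * sz;
        double *ol = o + jj * sy + kk * sz;
        const int lo = r < nx ? r : nx;
        const int hi = nx - r > lo ? nx - r : lo;
        for (int i = 0; i < lo; ++i) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t) s += k[t + r] * line[clampi(i + t, nx)];
          ol[i] = s;
        }
        for (int i = lo; i < hi; ++i) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t) s += k[t + r] * line[i + t];
          ol[i] = s;
        }
        for (int i = hi; i < nx; ++i) {
          double s = 0.0;
          for (int t = -r; t <= r; ++t) s += k[t + r] * line[clampi(i + t, nx)];
          ol[i] = s;
        }
      }
  } else if (axis == 1) {
    for (int kk = 0; kk < nz; ++kk)
      for (int jj = 0; jj < ny; ++jj) {
        double *ol = o + jj * sy + kk * sz;
        for (int t = -r; t <= r; ++t) {
          const double kt = k[t + r];
          const double *il = in + (R_xlen_t)clampi(jj + t, ny) * sy + kk * sz;
          for (int ii = 0; ii < nx; ++ii) ol[ii] += kt * il[ii];
        }
      }
  } else if (axis == 2) {
    for (int kk = 0; kk < nz; ++kk)
      for (int jj = 0; jj < ny; ++jj) {
        double *ol = o + jj * sy + kk * sz;
        for (int t = -r; t <= r; ++t) {
          const double kt = k[t + r];
          const double *il = in + jj * sy + (R_xlen_t)clampi(kk + t, nz) * sz;
          for (int ii = 0; ii < nx; ++ii) ol[ii] += kt * il[ii];
        }
      }
  } else {
    stop("axis must be 0, 1 or 2");
  }
  return out;
}

// Catmull-Rom cubic interpolation of a line sampled at integer positions,
// evaluated at i - shift for every output index i; replicate boundary.
static void shift_line(const double *in, double *out, R_xlen_t base,
                       R_xlen_t stride, int L, double shift) {
  for (int i = 0; i < L; ++i) {
    double s = i - shift;
    int i1 = (int)std::floor(s);
    double t = s - i1;
    int i0 = i1 - 1, i2 = i1 + 1, i3 = i1 + 2;
    int c0 = i0 < 0 ? 0 : (i0 >= L ? L - 1 : i0);
    int c1 = i1 < 0 ? 0 : (i1 >= L ? L - 1 : i1);
    int c2 = i2 < 0 ? 0 : (i2 >= L ? L - 1 : i2);
    int c3 = i3 < 0 ? 0 : (i3 >= L ? L - 1 : i3);
    double p0 = in[base + (R_xlen_t)c0 * stride];
    double p1 = in[base + (R_xlen_t)c1 * stride];
    double p2 = in[base + (R_xlen_t)c2 * stride];
    double p3 = in[base + (R_xlen_t)c3 * stride];
    out[base + (R_xlen_t)i * stride] =
        0.5 * (2.0 * p1 + t * (-p0 + p2) +
               t * t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3) +
               t * t * t * (-p0 + 3.0 * p1 - 3.0 * p2 + p3));
  }
}

// [[Rcpp::export]]
NumericVector shift_axis_cpp(NumericVector x, IntegerVector dims,
                             double shift, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != x.size())
    stop("dims inconsistent with data length");
  NumericVector out(x.size());
  const double *in = x.begin();
  double *o = out.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  if (axis == 0) {
    for (int kk = 0; kk < nz; ++kk)
      for (int jj = 0; jj < ny; ++jj)
        shift_line(in, o, jj * sy + kk * sz, sx, nx, shift);
  } else if (axis == 1) {
    for (int kk = 0; kk < nz; ++kk)
      for (int ii = 0; ii < nx; ++ii)
        shift_line(in, o, ii * sx + kk * sz, sy, ny, shift);
  } else if (axis == 2) {
    for (int jj = 0; jj < ny; ++jj)
      for (int ii = 0; ii < nx; ++ii)
        shift_line(in, o, ii * sx + jj * sy, sz, nz, shift);
  } else {
    stop("axis must be 0, 1 or 2");
  }
  return out;
}
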