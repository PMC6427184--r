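#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pixel convention used throughout the package: an image is an M x N matrix
// (M rows = height, N cols = width); a point (v, w) has v = 0-based column
// index and w = 0-based row index, with pixel centers on the integer lattice.

static inline int reflect(int i, int n) {
  // reflect-101 boundary (no repeated edge sample)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

static NumericMatrix blur_sep(const NumericMatrix& img, double sigma) {
  const int M = img.nrow(), N = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(M, N), out(M, N);
  // along rows (vertical direction)
  for (int c = 0; c < N; ++c)
    for (int rw = 0; rw < M; ++rw) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * img(reflect(rw + i, M), c);
      tmp(rw, c) = acc;
    }
  // along columns (horizontal direction)
  for (int rw = 0; rw < M; ++rw)
    for (int c = 0; c < N; ++c) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) acc += k[i + r] * tmp(rw, reflect(c + i, N));
      out(rw, c) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  return blur_sep(img, sigma);
}

// Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
// suppression along the quantized gradient direction, double-threshold
// hysteresis with thresholds given as fractions of the maximum gradient
// magnitude.  Returns a binary (0/1) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_canny(NumericMatrix img, double sigma, double low_frac,
                        double high_frac) {
  const int M = img.nrow(), N = img.ncol();
  NumericMatrix out(M, N);
  NumericMatrix sm = blur_sep(img, sigma);

  NumericMatrix gx(M, N), gy(M, N), mag(M, N);
  double max_mag = 0.0;
  for (int r = 0; r < M; ++r)
    for (int c = 0; c < N; ++c) {
      int rm = reflect(r - 1, M), rp = reflect(r + 1, M);
      int cm = reflect(c - 1, N), cp = reflect(c + 1, N);
      // Sobel, x = column direction, y = row direction
      double sx = (sm(rm, cp) + 2.0 * sm(r, cp) + sm(rp, cp)) -
                  (sm(rm, cm) + 2.0 * sm(r, cm) + sm(rp, cm));
      double sy = (sm(rp, cm) + 2.0 * sm(rp, c) + sm(rp, cp)) -
                  (sm(rm, cm) + 2.0 * sm(rm, c) + sm(rm, cp));
      gx(r, c) = sx;
      gy(r, c) = sy;
      double m = std::sqrt(sx * sx + sy * sy);
      mag(r, c) = m;
      if (m > max_mag) max_mag = m;
    }
  if (max_mag <= 0.0) return out;  // constant image: no edges

  const double hi = high_frac * max_mag, lo = low_frac * max_mag;
  // non-maximum suppression
  NumericMatrix nms(M, N);
  for (int r = 1; r < M - 1; ++r)
    for (int c = 1; c < N - 1; ++c) {
      double m = mag(r, c);
      if (m <= 0.0) continue;
      double ang = std::atan2(gy(r, c), gx(r, c));  // in [-pi, pi]
      double a = ang + M_PI;                        // fold to [0, pi)
      if (a >= M_PI) a -= M_PI;
      double m1, m2;
      if (a < M_PI / 8 || a >= 7 * M_PI / 8) {        // horizontal gradient
        m1 = mag(r, c - 1); m2 = mag(r, c + 1);
      } else if (a < 3 * M_PI / 8) {                  // diagonal /
        m1 = mag(r - 1, c - 1); m2 = mag(r + 1, c + 1);
      } else if (a < 5 * M_PI / 8) {                  // vertical gradient
        m1 = mag(r - 1, c); m2 = mag(r + 1, c);
      } else {                                        // diagonal backslash
        m1 = mag(r - 1, c + 1); m2 = mag(r + 1, c - 1);
      }
      // strict (with a tie tolerance) on one side so constant-gradient
      // plateaus are suppressed, including float-ripple plateaus
      const double tie = 1e-9 * max_mag;
      if (m > m1 + tie && m >= m2 - tie) nms(r, c) = m;
    }
  // exclude a border margin: gradients there reflect the boundary
  // padding, not image structure (a pure ramp must yield no edges)
  const int margin = std::max(2, (int)std::ceil(3.0 * sigma) + 2);
  for (int r = 0; r < M; ++r)
    for (int c = 0; c < N; ++c)
      if (r < margin || r >= M - margin || c < margin || c >= N - margin)
        nms(r, c) = 0.0;
  // hysteresis: seed from strong pixels, grow through weak ones
  std::vector<int> stack;
  IntegerMatrix state(M, N);  // 0 unvisited, 1 on edge
  for (int r = 0; r < M; ++r)
    for (int c = 0; c < N; ++c)
      if (nms(r, c) >= hi && state(r, c) == 0) {
        state(r, c) = 1;
        stack.push_back(r + c * M);
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int rr = idx % M, cc = idx / M;
          for (int dr = -1; dr <= 1; ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
              int r2 = rr + dr, c2 = cc + dc;
              if (r2 < 0 || r2 >= M || c2 < 0 || c2 >= N) continue;
              if (state(r2, c2) == 0 && nms(r2, c2) >= lo) {
                state(r2, c2) = 1;
                stack.push_back(r2 + c2 * M);
              }
            }
        }
      }
  for (int r = 0; r < M; ++r)
    for (int c = 0; c < N; ++c) out(r, c) = state(r, c) ? 1.0 : 0.0;
  return out;
}

// Inverse-mapping warp.  T is a 3x3 matrix acting on row homogeneous vectors
// [v w 1]; for each output pixel (v, w) the source position (g, h) is
// [v w 1] %*% T followed by division by the homogeneous coordinate, and the
// intensity is resampled from src there.  Out-of-frame sources fill with 0
// and get mask 0.
// [[Rcpp::export]]
List cpp_warp(NumericMatrix src, NumericMatrix T, int outM, int outN,
              bool bilinear) {
  const int M = src.nrow(), N = src.ncol();
  NumericMatrix out(outM, outN), mask(outM, outN);
  const double t11 = T(0, 0), t12 = T(0, 1), t13 = T(0, 2);
  const double t21 = T(1, 0), t22 = T(1, 1), t23 = T(1, 2);
  const double t31 = T(2, 0), t32 = T(2, 1), t33 = T(2, 2);
  for (int r = 0; r < outM; ++r) {
    const double w = (double)r;
    for (int c = 0; c < outN; ++c) {
      const double v = (double)c;
      const double g = v * t11 + w * t21 + t31;
      const double h = v * t12 + w * t22 + t32;
      const double s = v * t13 + w * t23 + t33;
      if (std::fabs(s) < 1e-12) continue;
      double x = g / s;  // source column
      double y = h / s;  // source row
      // tolerance so an identity-composite round trip cannot shed border
      // pixels to floating-point error
      const double eps = 1e-9;
      if (x < -eps || x > (double)(N - 1) + eps ||
          y < -eps || y > (double)(M - 1) + eps)
        continue;
      if (x < 0.0) x = 0.0;
      if (x > (double)(N - 1)) x = (double)(N - 1);
      if (y < 0.0) y = 0.0;
      if (y > (double)(M - 1)) y = (double)(M - 1);
      double val;
      if (bilinear) {
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        if (x0 > N - 2) x0 = N - 2;
        if (y0 > M - 2) y0 = M - 2;
        if (x0 < 0) x0 = 0;
        if (y0 < 0) y0 = 0;
        const double fx = x - x0, fy = y - y0;
        val = (1 - fy) * ((1 - fx) * src(y0, x0) + fx * src(y0, x0 + 1)) +
              fy * ((1 - fx) * src(y0 + 1, x0) + fx * src(y0 + 1, x0 + 1));
      } else {
        int xn = (int)std::lround(x), yn = (int)std::lround(y);
        if (xn < 0) xn = 0;
        if (xn > N - 1) xn = N - 1;
        if (yn < 0) yn = 0;
        if (yn > M - 1) yn = M - 1;
        val = src(yn, xn);
      }
      out(r, c) = val;
      mask(r, c) = 1.0;
    }
  }
  return List::create(_["image"] = out, _["mask"] = mask);
}

// Pearson correlation of pixel intensities (population moments).  Returns 0
// when either image is constant (similarity undefined by convention).
// [[Rcpp::export]]
double cpp_ncc(NumericMatrix A, NumericMatrix B) {
  const R_xlen_t n = A.size();
  double sa = 0, sb = 0;
  for (R_xlen_t i = 0; i < n; ++i) { sa += A[i]; sb += B[i]; }
  const double ma = sa / n, mb = sb / n;
  double saa = 0, sbb = 0, sab = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double da = A[i] - ma, db = B[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

// [[Rcpp::export]]
double cpp_mse(NumericMatrix A, NumericMatrix B) {
  const R_xlen_t n = A.size();
  double s = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double d = A[i] - B[i];
    s += d * d;
  }
  return s / n;
}

// Mutual information (bits) from a joint histogram over equal-width bins on
// [0, 1]; values outside [0, 1] are clamped into the end bins.
// [[Rcpp::export]]
double cpp_mi(NumericMatrix A, NumericMatrix B, int bins) {
  const R_xlen_t n = A.size();
  std::vector<double> joint((size_t)bins * bins, 0.0);
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    int ia = (int)std::floor(A[i] * bins);
    int ib = (int)std::floor(B[i] * bins);
    if (ia < 0) ia = 0;
    if (ia >= bins) ia = bins - 1;
    if (ib < 0) ib = 0;
    if (ib >= bins) ib = bins - 1;
    joint[(size_t)ia * bins + ib] += 1.0;
  }
  const double inv = 1.0 / (double)n;
  for (int ia = 0; ia < bins; ++ia)
    for (int ib = 0; ib < bins; ++ib) {
      const double p = joint[(size_t)ia * bins + ib] * inv;
      joint[(size_t)ia * bins + ib] = p;
      pa[ia] += p;
      pb[ib] += p;
    }
  double mi = 0.0;
  for (int ia = 0; ia < bins; ++ia) {
    if (pa[ia] <= 0) continue;
    for (int ib = 0; ib < bins; ++ib) {
      const double p = joint[(size_t)ia * bins + ib];
      if (p > 0 && pb[ib] > 0) mi += p * std::log2(p / (pa[ia] * pb[ib]));
    }
  }
  return mi < 0 ? 0.0 : mi;
}

// Masked variants: statistics restricted to pixels with mask != 0 (the
// valid warp overlap).  Used by the dense objective so that out-of-frame
// fill pixels cannot create spurious optima.

// [[Rcpp::export]]
double cpp_ncc_masked(NumericMatrix A, NumericMatrix B, NumericMatrix mask) {
  const R_xlen_t n = A.size();
  double sa = 0, sb = 0;
  R_xlen_t m = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i] != 0) { sa += A[i]; sb += B[i]; ++m; }
  if (m < 2) return 0.0;
  const double ma = sa / m, mb = sb / m;
  double saa = 0, sbb = 0, sab = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0) continue;
    const double da = A[i] - ma, db = B[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

// [[Rcpp::export]]
double cpp_mse_masked(NumericMatrix A, NumericMatrix B, NumericMatrix mask) {
  const R_xlen_t n = A.size();
  double s = 0;
  R_xlen_t m = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0) continue;
    const double d = A[i] - B[i];
    s += d * d;
    ++m;
  }
  return m > 0 ? s / m : 0.0;
}

// [[Rcpp::export]]
double cpp_mi_masked(NumericMatrix A, NumericMatrix B, NumericMatrix mask,
                     int bins) {
  const R_xlen_t n = A.size();
  std::vector<double> joint((size_t)bins * bins, 0.0);
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  R_xlen_t m = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0) continue;
    int ia = (int)std::floor(A[i] * bins);
    int ib = (int)std::floor(B[i] * bins);
    if (ia < 0) ia = 0;
    if (ia >= bins) ia = bins - 1;
    if (ib < 0) ib = 0;
    if (ib >= bins) ib = bins - 1;
    joint[(size_t)ia * bins + ib] += 1.0;
    ++m;
  }
  if (m == 0) return 0.0;
  const double inv = 1.0 / (double)m;
  for (int ia = 0; ia < bins; ++ia)
    for (int ib = 0; ib < bins; ++ib) {
      const double p = joint[(size_t)ia * bins + ib] * inv;
      joint[(size_t)ia * bins + ib] = p;
      pa[ia] += p;
      pb[ib] += p;
    }
  double mi = 0.0;
  for (int ia = 0; ia < bins; ++ia) {
    if (pa[ia] <= 0) continue;
    for (int ib = 0; ib < bins; ++ib) {
      const double p = joint[(size_t)ia * bins + ib];
      if (p > 0 && pb[ib] > 0) mi += p * std::log2(p / (pa[ia] * pb[ib]));
    }
  }
  return mi < 0 ? 0.0 : mi;
}
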