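#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Volumes are R arrays with dim = c(nz, ny, nx), column-major, so the Z index
// varies fastest. All filters treat sigma in pixel (index) units.

static inline int reflect_index(int i, int n) {
  // scipy-style "reflect": (d c b a | a b c d | d c b a)
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Correlate a volume with a centred 1-D kernel along one axis (0 = Z, 1 = Y,
// 2 = X), reflecting at the boundaries: out[i] = sum_o k[o + r] * in[i + o].
// [[Rcpp::export(name = ".conv3_axis")]]
NumericVector conv3_axis(NumericVector x, IntegerVector dim,
                         NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  if (x.size() != total) stop("volume length does not match dim");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int r = klen / 2;

  int n;            // extent along the filtered axis
  R_xlen_t stride;  // linear-index stride along the filtered axis
  if (axis == 0)      { n = nz; stride = 1; }
  else if (axis == 1) { n = ny; stride = nz; }
  else                { n = nx; stride = (R_xlen_t)nz * ny; }

  NumericVector out(total);
  out.attr("dim") = dim;
  const R_xlen_t n_lines = total / n;
  const R_xlen_t block = stride * n;
  std::vector<double> line(n);

  for (R_xlen_t l = 0; l < n_lines; ++l) {
    const R_xlen_t base = (l / stride) * block + (l % stride);
    for (int i = 0; i < n; ++i) line[i] = x[base + (R_xlen_t)i * stride];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int m = 0; m < klen; ++m)
        acc += kernel[m] * line[reflect_index(i + m - r, n)];
      out[base + (R_xlen_t)i * stride] = acc;
    }
  }
  return out;
}

// Eigenvalues (sorted descending) of per-voxel symmetric 3x3 matrices given as
// six volumes (a11, a22, a33, a12, a13, a23). Analytic trigonometric method.
// [[Rcpp::export(name = ".sym3_eigenvalues")]]
List sym3_eigenvalues(NumericVector a11, NumericVector a22, NumericVector a33,
                      NumericVector a12, NumericVector a13, NumericVector a23) {
  const R_xlen_t n = a11.size();
  NumericVector e1(n), e2(n), e3(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double m11 = a11[i], m22 = a22[i], m33 = a33[i];
    const double m12 = a12[i], m13 = a13[i], m23 = a23[i];
    const double p1 = m12 * m12 + m13 * m13 + m23 * m23;
    double l1, l2, l3;
    if (p1 == 0.0) {
      l1 = m11; l2 = m22; l3 = m33;
      if (l1 < l2) std::swap(l1, l2);
      if (l2 < l3) std::swap(l2, l3);
      if (l1 < l2) std::swap(l1, l2);
    } else {
      const double q = (m11 + m22 + m33) / 3.0;
      const double p2 = (m11 - q) * (m11 - q) + (m22 - q) * (m22 - q) +
                        (m33 - q) * (m33 - q) + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      const double b11 = (m11 - q) / p, b22 = (m22 - q) / p, b33 = (m33 - q) / p;
      const double b12 = m12 / p, b13 = m13 / p, b23 = m23 / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double rr = detB / 2.0;
      if (rr < -1.0) rr = -1.0;
      if (rr > 1.0) rr = 1.0;
      const double phi = std::acos(rr) / 3.0;
      l1 = q + 2.0 * p * std::cos(phi);
      l3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      l2 = 3.0 * q - l1 - l3;
    }
    e1[i] = l1; e2[i] = l2; e3[i] = l3;
  }
  return List::create(e1, e2, e3);
}

// 3-D connected-component labelling. Labels are assigned in raster-scan order
// of each component's first (lowest linear index) voxel, so the labelling is
// canonical. connectivity is 6, 18 or 26.
// [[Rcpp::export(name = ".label_cc3")]]
IntegerVector label_cc3(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  if (mask.size() != total) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> dz, dy, dx;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        const int s = std::abs(cz) + std::abs(cy) + std::abs(cx);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dz.push_back(cz); dy.push_back(cy); dx.push_back(cx);
      }
  const int n_nb = (int)dz.size();

  IntegerVector labels(total, 0);
  labels.attr("dim") = dim;
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t s = 0; s < total; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = (int)(cur % nz);
      const int y = (int)((cur / nz) % ny);
      const int xx = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < n_nb; ++k) {
        const int z2 = z + dz[k], y2 = y + dy[k], x2 = xx + dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        const R_xlen_t idx = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next_label;
          stack.push_back(idx);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
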