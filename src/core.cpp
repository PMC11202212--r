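#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// All arrays are R-order 3D: dim = (n1, n2, n3) with n1 fastest,
// linear index = i1 + n1*(i2 + n2*i3). The package stores stacks as
// [z, y, x], so i1 = z, i2 = y, i3 = x.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on a
// sampled function f at positions x_i = i * step. Exact for arbitrary
// positive step, which is what anisotropic voxel spacing requires.
// Callers guarantee at least one finite entry; infinite entries (no
// source anywhere on the orthogonal slab yet) simply never enter the
// lower envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q0 = 0;
  while (f[q0] == INF) ++q0;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * step;
    while (true) {
      double xv = v[k] * step;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; }      // k >= 1 here because z[0] = -inf
      else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; break; }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance (um) from every voxel to the
// nearest mask voxel centre; 0 on the mask itself.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // axis 1 (stride 1)
  f.resize(n1); d.resize(n1);
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      bool any = false;
      for (int i1 = 0; i1 < n1; ++i1) { f[i1] = g[base + i1]; if (f[i1] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, n1, spacing[0]);
      for (int i1 = 0; i1 < n1; ++i1) g[base + i1] = d[i1];
    }
  // axis 2 (stride n1)
  f.resize(n2); d.resize(n2);
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * n2 * i3;
      bool any = false;
      for (int i2 = 0; i2 < n2; ++i2) { f[i2] = g[base + (R_xlen_t)n1 * i2]; if (f[i2] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, n2, spacing[1]);
      for (int i2 = 0; i2 < n2; ++i2) g[base + (R_xlen_t)n1 * i2] = d[i2];
    }
  // axis 3 (stride n1*n2)
  f.resize(n3); d.resize(n3);
  R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * i2;
      bool any = false;
      for (int i3 = 0; i3 < n3; ++i3) { f[i3] = g[base + s3 * i3]; if (f[i3] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, n3, spacing[2]);
      for (int i3 = 0; i3 < n3; ++i3) g[base + s3 * i3] = d[i3];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

static void blur_axis(std::vector<double>& src, std::vector<double>& dst,
                      int n1, int n2, int n3, int axis, double sigma) {
  int len = (axis == 0) ? n1 : (axis == 1) ? n2 : n3;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2;
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) { dst = src; return; }
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += ker[i + r]; }
  for (size_t i = 0; i < ker.size(); ++i) ker[i] /= s;

  // iterate over all lines along `axis`
  R_xlen_t total = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> line(len), res(len);
  // enumerate starting offsets of lines
  int a1 = (axis == 0) ? n2 : n1;
  int a2 = (axis == 2) ? n2 : n3;
  for (int u = 0; u < a1; ++u)
    for (int v = 0; v < a2; ++v) {
      R_xlen_t base;
      if (axis == 0)      base = (R_xlen_t)n1 * (u + (R_xlen_t)n2 * v);
      else if (axis == 1) base = u + (R_xlen_t)n1 * n2 * v;
      else                base = u + (R_xlen_t)n1 * v;
      for (int i = 0; i < len; ++i) line[i] = src[base + stride * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int idx = i + j;
          if (idx < 0) idx = -idx - 1;            // reflect
          if (idx >= len) idx = 2 * len - idx - 1;
          if (idx < 0) idx = 0;                   // very short lines
          if (idx >= len) idx = len - 1;
          acc += ker[j + r] * line[idx];
        }
        res[i] = acc;
      }
      for (int i = 0; i < len; ++i) dst[base + stride * i] = res[i];
    }
  (void)total;
}

// Separable Gaussian blur with reflective boundaries; sigma per axis in
// voxels (0 skips the axis).
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector img, IntegerVector dim,
                               NumericVector sigma_vox) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> a(img.begin(), img.end()), b(n);
  std::vector<double>* cur = &a;
  std::vector<double>* nxt = &b;
  for (int axis = 0; axis < 3; ++axis) {
    if (sigma_vox[axis] <= 0) continue;
    blur_axis(*cur, *nxt, n1, n2, n3, axis, sigma_vox[axis]);
    std::swap(cur, nxt);
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (*cur)[i];
  out.attr("dim") = dim;
  return out;
}

// Connected-component labels (1..k, 0 = background) under 6- or
// 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i1 = cur % n1;
      int i2 = (cur / n1) % n2;
      int i3 = cur / ((R_xlen_t)n1 * n2);
      for (int d3 = -1; d3 <= 1; ++d3)
        for (int d2 = -1; d2 <= 1; ++d2)
          for (int d1 = -1; d1 <= 1; ++d1) {
            if (d1 == 0 && d2 == 0 && d3 == 0) continue;
            if (connectivity == 6 && std::abs(d1) + std::abs(d2) + std::abs(d3) != 1) continue;
            int j1 = i1 + d1, j2 = i2 + d2, j3 = i3 + d3;
            if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
            R_xlen_t j = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
            if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Strict 26-neighbourhood local maxima at or above `threshold`.
// Plateau ties are broken towards the lowest (i1, i2, i3) index, i.e.
// lowest (z, y, x) for the package's [z, y, x] layout. Returns 1-based
// linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector img, IntegerVector dim,
                               double threshold) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<int> keep;
  for (R_xlen_t cur = 0; cur < n; ++cur) {
    double v = img[cur];
    if (!(v >= threshold)) continue;
    int i1 = cur % n1;
    int i2 = (cur / n1) % n2;
    int i3 = cur / ((R_xlen_t)n1 * n2);
    bool is_max = true;
    for (int d3 = -1; d3 <= 1 && is_max; ++d3)
      for (int d2 = -1; d2 <= 1 && is_max; ++d2)
        for (int d1 = -1; d1 <= 1 && is_max; ++d1) {
          if (d1 == 0 && d2 == 0 && d3 == 0) continue;
          int j1 = i1 + d1, j2 = i2 + d2, j3 = i3 + d3;
          if (j1 < 0 || j1 >= n1 || j2 < 0 || j2 >= n2 || j3 < 0 || j3 >= n3) continue;
          R_xlen_t j = j1 + (R_xlen_t)n1 * (j2 + (R_xlen_t)n2 * j3);
          double w = img[j];
          if (w > v) { is_max = false; break; }
          if (w == v) {
            // lexicographic (i1, i2, i3): earlier index wins the plateau
            bool j_earlier = (j1 < i1) || (j1 == i1 && (j2 < i2 || (j2 == i2 && j3 < i3)));
            if (j_earlier) { is_max = false; break; }
          }
        }
    if (is_max) keep.push_back((int)cur + 1);
  }
  return wrap(keep);
}

// Trilinear interpolation of a 3D array at physical (z,y,x) coordinates
// (um). Fractional voxel index u = coord/spacing + 0.5, clamped to the
// grid; matches the R voxel-centre convention.
// [[Rcpp::export]]
NumericVector cpp_interp3d(NumericVector arr, IntegerVector dim,
                           NumericVector spacing, NumericMatrix coords) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int n = coords.nrow();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double u1 = coords(k, 0) / spacing[0] + 0.5;
    double u2 = coords(k, 1) / spacing[1] + 0.5;
    double u3 = coords(k, 2) / spacing[2] + 0.5;
    if (u1 < 1) u1 = 1; if (u1 > n1) u1 = n1;
    if (u2 < 1) u2 = 1; if (u2 > n2) u2 = n2;
    if (u3 < 1) u3 = 1; if (u3 > n3) u3 = n3;
    int i1 = (int)u1; if (i1 > n1 - 1) i1 = n1 - 1; 
    int i2 = (int)u2; if (i2 > n2 - 1) i2 = n2 - 1;
    int i3 = (int)u3; if (i3 > n3 - 1) i3 = n3 - 1;
    double f1 = u1 - i1, f2 = u2 - i2, f3 = u3 - i3;
    // convert to 0-based corner
    int a1 = i1 - 1, a2 = i2 - 1, a3 = i3 - 1;
    int b1 = (a1 + 1 < n1) ? a1 + 1 : a1;
    int b2 = (a2 + 1 < n2) ? a2 + 1 : a2;
    int b3 = (a3 + 1 < n3) ? a3 + 1 : a3;
    R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
    const double* p = arr.begin();
    double v000 = p[a1 + s2 * a2 + s3 * a3], v100 = p[b1 + s2 * a2 + s3 * a3];
    double v010 = p[a1 + s2 * b2 + s3 * a3], v110 = p[b1 + s2 * b2 + s3 * a3];
    double v001 = p[a1 + s2 * a2 + s3 * b3], v101 = p[b1 + s2 * a2 + s3 * b3];
    double v011 = p[a1 + s2 * b2 + s3 * b3], v111 = p[b1 + s2 * b2 + s3 * b3];
    double c00 = v000 * (1 - f1) + v100 * f1;
    double c10 = v010 * (1 - f1) + v110 * f1;
    double c01 = v001 * (1 - f1) + v101 * f1;
    double c11 = v011 * (1 - f1) + v111 * f1;
    double c0 = c00 * (1 - f2) + c10 * f2;
    double c1 = c01 * (1 - f2) + c11 * f2;
    out[k] = c0 * (1 - f3) + c1 * f3;
  }
  return out;
}
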