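// Voxel-level primitives for 3D morphometry: exact anisotropic squared
// Euclidean distance transform (separable lower-envelope algorithm),
// 6/26-connected components, border flood fill, maximal-inscribed-sphere
// local thickness, geometric primitive voxelizers and separable Gaussian
// smoothing. Arrays are passed as flat vectors in R's column-major [x,y,z]
// layout with dim = c(nx, ny, nz); spacings are physical edge lengths.
#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform over samples at positions i*s, i = 0..n-1.
// f holds squared distances on input; d receives the transformed values.
static void dt1d(const double* f, double* d, int n, double s,
                 std::vector<int>& v, std::vector<double>& z) {
  const double s2 = s * s;
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { // empty line: nothing to propagate
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue; // infinite parabolas never form the envelope
    double sep;
    while (true) {
      // intersection of parabola q with parabola v[k]
      sep = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
            (2.0 * s2 * (q - v[k]));
      if (sep <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* row = &out[(R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = row[i]; if (row[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) row[i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      bool any = false;
      for (int j = 0; j < ny; ++j) {
        f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (f[j] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      bool any = false;
      for (int k = 0; k < nz; ++k) {
        f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        if (f[k] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }
  return out;
}

// Flood fill the complement of `mask` from the grid border (6-connected);
// returns mask with all unreached complement voxels (internal cavities)
// set. Faces flagged in `sealed` (x, y, z) do not seed the flood, which
// treats them as closed specimen-cut planes.
// [[Rcpp::export(name = ".cpp_fill_holes")]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim,
                             LogicalVector sealed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> reached(n, 0);
  std::queue<R_xlen_t> q;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  auto push = [&](int i, int j, int k) {
    R_xlen_t id = idx(i, j, k);
    if (!reached[id] && !mask[id]) { reached[id] = 1; q.push(id); }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool seed = (!sealed[0] && (i == 0 || i == nx - 1)) ||
                    (!sealed[1] && (j == 0 || j == ny - 1)) ||
                    (!sealed[2] && (k == 0 || k == nz - 1));
        if (seed) push(i, j, k);
      }
  while (!q.empty()) {
    R_xlen_t id = q.front(); q.pop();
    int i = id % nx, j = (id / nx) % ny, k = id / ((R_xlen_t)nx * ny);
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !reached[i];
  return out;
}

// Connected component labelling; connectivity 6 or 26.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && m > 1) continue;
        nb.push_back({di, dj, dk});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t id = q.front(); q.pop();
      int i = id % nx, j = (id / nx) % ny, k = id / ((R_xlen_t)nx * ny);
      for (auto& d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t id2 = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[id2] && !lab[id2]) { lab[id2] = cur; q.push(id2); }
      }
    }
  }
  return lab;
}

// Local thickness by the maximal-inscribed-sphere definition. The sphere
// centred at a mask voxel extends to the nearest background voxel centre
// (coverage radius r = EDT); its continuous inscribed radius is r minus
// half the smallest voxel edge, since the physical boundary lies halfway
// between the last mask centre and the first background centre. A voxel
// covered (strictly) by a sphere inherits twice the largest covering
// inscribed radius; an isolated voxel gets one voxel diameter. Spheres are
// painted in decreasing radius order.
// [[Rcpp::export(name = ".cpp_local_thickness")]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector bg(n);
  bool anybg = false, anyfg = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    bg[i] = !mask[i];
    if (bg[i]) anybg = true; else anyfg = true;
  }
  NumericVector th(n, 0.0);
  if (!anyfg) return th;
  const double hv = 0.5 * std::min(spacing[0], std::min(spacing[1], spacing[2]));
  std::vector<double> rad(n, 0.0), rad2(n, 0.0); // rad2 kept exact (no sqrt)
  if (!anybg) {
    // mask fills the grid: bounded by the half bounding-box diagonal
    double dx = nx * spacing[0], dy = ny * spacing[1], dz = nz * spacing[2];
    double r2v = 0.25 * (dx * dx + dy * dy + dz * dz);
    for (R_xlen_t i = 0; i < n; ++i) { rad2[i] = r2v; rad[i] = std::sqrt(r2v); }
  } else {
    NumericVector d2 = cpp_edt_sq(bg, dim, spacing);
    for (R_xlen_t i = 0; i < n; ++i)
      if (mask[i]) { rad2[i] = d2[i]; rad[i] = std::sqrt(d2[i]); }
  }
  std::vector<R_xlen_t> order;
  order.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i) if (mask[i]) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](R_xlen_t a, R_xlen_t b) { return rad[a] > rad[b]; });
  for (R_xlen_t c : order) {
    const double r = rad[c];            // coverage radius (to bg centre)
    const double t = 2.0 * (r - hv);    // inscribed diameter
    int i0 = c % nx, j0 = (c / nx) % ny, k0 = c / ((R_xlen_t)nx * ny);
    int ri = (int)std::floor(r / spacing[0]);
    int rj = (int)std::floor(r / spacing[1]);
    int rk = (int)std::floor(r / spacing[2]);
    const double r2 = rad2[c]; // exact squared coverage radius
    for (int dk = -rk; dk <= rk; ++dk) {
      int kk = k0 + dk;
      if (kk < 0 || kk >= nz) continue;
      double z2 = dk * spacing[2] * dk * spacing[2];
      for (int dj = -rj; dj <= rj; ++dj) {
        int jj = j0 + dj;
        if (jj < 0 || jj >= ny) continue;
        double yz2 = z2 + dj * spacing[1] * dj * spacing[1];
        if (yz2 >= r2) continue;
        for (int di = -ri; di <= ri; ++di) {
          int ii = i0 + di;
          if (ii < 0 || ii >= nx) continue;
          double dd = yz2 + di * spacing[0] * di * spacing[0];
          if (dd >= r2) continue;        // strict: sphere stops at bg centre
          R_xlen_t id = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (th[id] < t) th[id] = t;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) if (!mask[i]) th[i] = 0.0;
  return th;
}

// Paint value into vol (and branch id into aux when given) where the voxel
// centre lies within `radius` of the segment [a, b] (physical coordinates).
// Modifies vol/aux in place; callers own freshly allocated vectors.
// [[Rcpp::export(name = ".cpp_paint_capsule")]]
void cpp_paint_capsule(IntegerVector vol, IntegerVector dim,
                       NumericVector spacing, NumericVector a,
                       NumericVector b, double radius, int value,
                       Nullable<IntegerVector> aux = R_NilValue,
                       int aux_value = 0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector auxv;
  bool has_aux = aux.isNotNull();
  if (has_aux) auxv = aux.get();
  double lo[3], hi[3];
  int ilo[3], ihi[3];
  const int nd[3] = {nx, ny, nz};
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::min(a[d], b[d]) - radius;
    hi[d] = std::max(a[d], b[d]) + radius;
    // voxel centre of index i is at (i + 0.5) * spacing
    ilo[d] = std::max(0, (int)std::floor(lo[d] / spacing[d] - 0.5));
    ihi[d] = std::min(nd[d] - 1, (int)std::ceil(hi[d] / spacing[d] - 0.5));
  }
  double ab[3], ab2 = 0.0;
  for (int d = 0; d < 3; ++d) { ab[d] = b[d] - a[d]; ab2 += ab[d] * ab[d]; }
  const double r2 = radius * radius;
  for (int k = ilo[2]; k <= ihi[2]; ++k) {
    double pz = (k + 0.5) * spacing[2];
    for (int j = ilo[1]; j <= ihi[1]; ++j) {
      double py = (j + 0.5) * spacing[1];
      for (int i = ilo[0]; i <= ihi[0]; ++i) {
        double px = (i + 0.5) * spacing[0];
        double ap[3] = {px - a[0], py - a[1], pz - a[2]};
        double t = 0.0;
        if (ab2 > 0.0) {
          t = (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / ab2;
          t = std::max(0.0, std::min(1.0, t));
        }
        double dd = 0.0;
        for (int d = 0; d < 3; ++d) {
          double c = ap[d] - t * ab[d];
          dd += c * c;
        }
        if (dd <= r2) {
          R_xlen_t id = (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          vol[id] = value;
          if (has_aux) auxv[id] = aux_value;
        }
      }
    }
  }
}

// Paint an axis-aligned ellipsoid (centre and semi-axes in physical units).
// [[Rcpp::export(name = ".cpp_paint_ellipsoid")]]
void cpp_paint_ellipsoid(IntegerVector vol, IntegerVector dim,
                         NumericVector spacing, NumericVector centre,
                         NumericVector semi, int value) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd[3] = {nx, ny, nz};
  int ilo[3], ihi[3];
  for (int d = 0; d < 3; ++d) {
    ilo[d] = std::max(0, (int)std::floor((centre[d] - semi[d]) / spacing[d] - 0.5));
    ihi[d] = std::min(nd[d] - 1, (int)std::ceil((centre[d] + semi[d]) / spacing[d] - 0.5));
  }
  for (int k = ilo[2]; k <= ihi[2]; ++k) {
    double fz = ((k + 0.5) * spacing[2] - centre[2]) / semi[2];
    for (int j = ilo[1]; j <= ihi[1]; ++j) {
      double fy = ((j + 0.5) * spacing[1] - centre[1]) / semi[1];
      double fyz = fz * fz + fy * fy;
      if (fyz > 1.0) continue;
      for (int i = ilo[0]; i <= ihi[0]; ++i) {
        double fx = ((i + 0.5) * spacing[0] - centre[0]) / semi[0];
        if (fx * fx + fyz <= 1.0)
          vol[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = value;
      }
    }
  }
}

// Separable Gaussian smoothing with replicate boundary; sigma per axis in
// voxel units, kernel truncated at 3 sigma.
// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericVector cpp_gaussian_blur(NumericVector vol, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(vol);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int hw = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * hw + 1);
    double sum = 0.0;
    for (int t = -hw; t <= hw; ++t) {
      ker[t + hw] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + hw];
    }
    for (auto& v : ker) v /= sum;
    NumericVector nxt(n);
    const int len = nd[axis];
    const R_xlen_t st = stride[axis];
    // iterate over all lines along `axis`
    const int na = nd[(axis + 1) % 3], nb = nd[(axis + 2) % 3];
    const R_xlen_t sa = stride[(axis + 1) % 3], sb = stride[(axis + 2) % 3];
    for (int ib = 0; ib < nb; ++ib)
      for (int ia = 0; ia < na; ++ia) {
        R_xlen_t base = (R_xlen_t)ia * sa + (R_xlen_t)ib * sb;
        for (int p = 0; p < len; ++p) {
          double acc = 0.0;
          for (int t = -hw; t <= hw; ++t) {
            int pp = std::min(len - 1, std::max(0, p + t));
            acc += ker[t + hw] * cur[base + (R_xlen_t)pp * st];
          }
          nxt[base + (R_xlen_t)p * st] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}
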