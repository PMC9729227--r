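// Low-level volumetric kernels: separable Gaussian/box filtering, trilinear
// warping, displacement-field composition, Jacobian determinants, 26-connected
// component labelling, and threshold-free cluster enhancement.
//
// All arrays are R column-major 3D volumes; voxel indices are 0-based and
// displacements are expressed in voxel units of the grid they live on.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline size_t IDX(int x, int y, int z, int nx, int ny) {
  return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * (size_t)z);
}

// Separable Gaussian smoothing with edge renormalisation (truncated at 3 sigma).
// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;
  int h = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> w(2 * h + 1);
  for (int j = -h; j <= h; ++j) w[j + h] = std::exp(-0.5 * j * j / (sigma * sigma));
  std::vector<double> buf(V);
  const int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    std::copy(out.begin(), out.end(), buf.begin());
    size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nx : (size_t)nx * ny;
    int len = n[axis];
    // iterate over all lines along `axis`
    for (int z = 0; z < (axis == 2 ? 1 : nz); ++z) {
      for (int y = 0; y < (axis == 1 ? 1 : ny); ++y) {
        for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
          size_t base = IDX(x, y, z, nx, ny);
          for (int i = 0; i < len; ++i) {
            double s = 0.0, ws = 0.0;
            int j0 = std::max(-h, -i), j1 = std::min(h, len - 1 - i);
            for (int j = j0; j <= j1; ++j) {
              double wj = w[j + h];
              s += wj * buf[base + (size_t)(i + j) * stride];
              ws += wj;
            }
            out[base + (size_t)i * stride] = s / ws;
          }
        }
      }
    }
  }
  return out;
}

// Box-window mean (cube of half-width `radius`), edge-truncated.
// [[Rcpp::export]]
NumericVector cpp_box_mean3(NumericVector vol, IntegerVector dim, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector out = clone(vol);
  std::vector<double> buf(V);
  std::vector<double> cnt(V, 1.0), cbuf(V);
  const int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    std::copy(out.begin(), out.end(), buf.begin());
    std::copy(cnt.begin(), cnt.end(), cbuf.begin());
    size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nx : (size_t)nx * ny;
    int len = n[axis];
    for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
      for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
        for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
          size_t base = IDX(x, y, z, nx, ny);
          for (int i = 0; i < len; ++i) {
            double s = 0.0, c = 0.0;
            int j0 = std::max(-radius, -i), j1 = std::min(radius, len - 1 - i);
            for (int j = j0; j <= j1; ++j) {
              s += buf[base + (size_t)(i + j) * stride];
              c += cbuf[base + (size_t)(i + j) * stride];
            }
            out[base + (size_t)i * stride] = s;
            cnt[base + (size_t)i * stride] = c;
          }
        }
  }
  for (size_t i = 0; i < V; ++i) out[i] /= cnt[i];
  return out;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double trilinear(const double *vol, int nx, int ny, int nz,
                               double px, double py, double pz) {
  px = clampd(px, 0.0, nx - 1.0);
  py = clampd(py, 0.0, ny - 1.0);
  pz = clampd(pz, 0.0, nz - 1.0);
  int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = px - x0, fy = py - y0, fz = pz - z0;
  double c000 = vol[IDX(x0, y0, z0, nx, ny)],     c100 = vol[IDX(x0 + 1, y0, z0, nx, ny)];
  double c010 = vol[IDX(x0, y0 + 1, z0, nx, ny)], c110 = vol[IDX(x0 + 1, y0 + 1, z0, nx, ny)];
  double c001 = vol[IDX(x0, y0, z0 + 1, nx, ny)], c101 = vol[IDX(x0 + 1, y0, z0 + 1, nx, ny)];
  double c011 = vol[IDX(x0, y0 + 1, z0 + 1, nx, ny)], c111 = vol[IDX(x0 + 1, y0 + 1, z0 + 1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Pull-back warp: out(x) = vol(x + d(x)); nearest = 1 for label volumes.
// [[Rcpp::export]]
NumericVector cpp_warp_image(NumericVector vol, IntegerVector dim,
                             NumericVector dx, NumericVector dy, NumericVector dz,
                             int nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector out(V);
  const double *v = REAL(vol);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = IDX(x, y, z, nx, ny);
        double px = x + dx[i], py = y + dy[i], pz = z + dz[i];
        if (nearest) {
          int xi = (int)std::lround(clampd(px, 0.0, nx - 1.0));
          int yi = (int)std::lround(clampd(py, 0.0, ny - 1.0));
          int zi = (int)std::lround(clampd(pz, 0.0, nz - 1.0));
          out[i] = v[IDX(xi, yi, zi, nx, ny)];
        } else {
          out[i] = trilinear(v, nx, ny, nz, px, py, pz);
        }
      }
  out.attr("dim") = dim;
  return out;
}

// Composition c = a o b of displacement fields: c(x) = b(x) + a(x + b(x)).
// [[Rcpp::export]]
List cpp_compose_disp(NumericVector ax, NumericVector ay, NumericVector az,
                      NumericVector bx, NumericVector by, NumericVector bz,
                      IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector cx(V), cy(V), cz(V);
  const double *pax = REAL(ax), *pay = REAL(ay), *paz = REAL(az);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = IDX(x, y, z, nx, ny);
        double px = x + bx[i], py = y + by[i], pz = z + bz[i];
        cx[i] = bx[i] + trilinear(pax, nx, ny, nz, px, py, pz);
        cy[i] = by[i] + trilinear(pay, nx, ny, nz, px, py, pz);
        cz[i] = bz[i] + trilinear(paz, nx, ny, nz, px, py, pz);
      }
  cx.attr("dim") = dim; cy.attr("dim") = dim; cz.attr("dim") = dim;
  return List::create(_["dx"] = cx, _["dy"] = cy, _["dz"] = cz);
}

// Sample a volume at arbitrary voxel-space points (n x 3 matrix, 0-based).
// [[Rcpp::export]]
NumericVector cpp_sample3(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                          int nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (int k = 0; k < n; ++k) {
    double px = pts(k, 0), py = pts(k, 1), pz = pts(k, 2);
    if (nearest) {
      int xi = (int)std::lround(clampd(px, 0.0, nx - 1.0));
      int yi = (int)std::lround(clampd(py, 0.0, ny - 1.0));
      int zi = (int)std::lround(clampd(pz, 0.0, nz - 1.0));
      out[k] = v[IDX(xi, yi, zi, nx, ny)];
    } else {
      out[k] = trilinear(v, nx, ny, nz, px, py, pz);
    }
  }
  return out;
}

// Jacobian determinant of phi(x) = x + d(x), central differences (one-sided at
// the boundary). Returns the full determinant field.
// [[Rcpp::export]]
NumericVector cpp_jacobian_det(NumericVector dx, NumericVector dy, NumericVector dz,
                               IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector out(V);
  const double *d[3] = {REAL(dx), REAL(dy), REAL(dz)};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = IDX(x, y, z, nx, ny);
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          // derivative along x
          int xm = std::max(x - 1, 0), xp = std::min(x + 1, nx - 1);
          J[c][0] = (d[c][IDX(xp, y, z, nx, ny)] - d[c][IDX(xm, y, z, nx, ny)]) / (xp - xm);
          int ym = std::max(y - 1, 0), yp = std::min(y + 1, ny - 1);
          J[c][1] = (d[c][IDX(x, yp, z, nx, ny)] - d[c][IDX(x, ym, z, nx, ny)]) / (yp - ym);
          int zm = std::max(z - 1, 0), zp = std::min(z + 1, nz - 1);
          J[c][2] = (d[c][IDX(x, y, zp, nx, ny)] - d[c][IDX(x, y, zm, nx, ny)]) / (zp - zm);
          J[c][c] += 1.0;
        }
        out[i] = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
               - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
               + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling of {stat >= thresh}; labels assigned in
// scan order (x fastest), background 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(NumericVector stat, IntegerVector dim, double thresh) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  IntegerVector lab(V);
  std::vector<size_t> stack;
  int next = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t i = IDX(x, y, z, nx, ny);
        if (stat[i] < thresh || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          size_t j = stack.back(); stack.pop_back();
          int zx = (int)(j / ((size_t)nx * ny));
          int rem = (int)(j % ((size_t)nx * ny));
          int yx = rem / nx, xx = rem % nx;
          for (int dz2 = -1; dz2 <= 1; ++dz2)
            for (int dy2 = -1; dy2 <= 1; ++dy2)
              for (int dx2 = -1; dx2 <= 1; ++dx2) {
                if (!dx2 && !dy2 && !dz2) continue;
                int ax = xx + dx2, ay2 = yx + dy2, az2 = zx + dz2;
                if (ax < 0 || ax >= nx || ay2 < 0 || ay2 >= ny || az2 < 0 || az2 >= nz) continue;
                size_t k = IDX(ax, ay2, az2, nx, ny);
                if (stat[k] >= thresh && lab[k] == 0) {
                  lab[k] = next;
                  stack.push_back(k);
                }
              }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// Threshold-free cluster enhancement with 26-connectivity. The positive and
// negative sides are enhanced separately (the negative side by enhancing the
// negated map and negating the result).
// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector stat, IntegerVector dim, double H, double E,
                       int nsteps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t V = (size_t)nx * ny * nz;
  NumericVector out(V);
  std::vector<int> lab(V);
  std::vector<size_t> stack;
  for (int sign = 0; sign < 2; ++sign) {
    double sg = sign == 0 ? 1.0 : -1.0;
    double maxv = 0.0;
    for (size_t i = 0; i < V; ++i) maxv = std::max(maxv, sg * stat[i]);
    if (maxv <= 0.0) continue;
    double dh = maxv / nsteps;
    for (int k = 1; k <= nsteps; ++k) {
      double h = k * dh;
      std::fill(lab.begin(), lab.end(), 0);
      int next = 0;
      std::vector<double> csize;
      csize.push_back(0.0);
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t i = IDX(x, y, z, nx, ny);
            if (sg * stat[i] < h || lab[i] != 0) continue;
            ++next;
            lab[i] = next;
            double sz = 1.0;
            stack.clear();
            stack.push_back(i);
            while (!stack.empty()) {
              size_t j = stack.back(); stack.pop_back();
              int zx = (int)(j / ((size_t)nx * ny));
              int rem = (int)(j % ((size_t)nx * ny));
              int yx = rem / nx, xx = rem % nx;
              for (int dz2 = -1; dz2 <= 1; ++dz2)
                for (int dy2 = -1; dy2 <= 1; ++dy2)
                  for (int dx2 = -1; dx2 <= 1; ++dx2) {
                    if (!dx2 && !dy2 && !dz2) continue;
                    int ax = xx + dx2, ay2 = yx + dy2, az2 = zx + dz2;
                    if (ax < 0 || ax >= nx || ay2 < 0 || ay2 >= ny || az2 < 0 || az2 >= nz) continue;
                    size_t kk = IDX(ax, ay2, az2, nx, ny);
                    if (sg * stat[kk] >= h && lab[kk] == 0) {
                      lab[kk] = next;
                      sz += 1.0;
                      stack.push_back(kk);
                    }
                  }
            }
            csize.push_back(sz);
          }
      if (next == 0) break;  // no supra-threshold voxels at higher h either
      double hH = std::pow(h, H) * dh;
      std::vector<double> inc(next + 1, 0.0);
      for (int c = 1; c <= next; ++c) inc[c] = std::pow(csize[c], E) * hH;
      for (size_t i = 0; i < V; ++i)
        if (lab[i] > 0) out[i] += sg * inc[lab[i]];
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Row-wise medians of a numeric matrix (even counts: mean of the two central
// order statistics).
// [[Rcpp::export]]
NumericVector cpp_row_medians(NumericMatrix m) {
  int n = m.nrow(), p = m.ncol();
  NumericVector out(n);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = m(i, j);
    int mid = p / 2;
    std::nth_element(row.begin(), row.begin() + mid, row.end());
    double hi = row[mid];
    if (p % 2 == 1) {
      out[i] = hi;
    } else {
      double lo = *std::max_element(row.begin(), row.begin() + mid);
      out[i] = 0.5 * (lo + hi);
    }
  }
  return out;
}
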