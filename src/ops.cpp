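#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---- connected-component labelling ------------------------------------------------
// Labels the nonzero voxels of a 3D grid with 6/18/26-connectivity (pass nz = 1 for
// per-slice 2D labelling; 26-connectivity then reduces to in-plane 8-connectivity).

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ad == 0) continue;
        if (connectivity == 6 && ad > 1) continue;
        if (connectivity == 18 && ad > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < ox.size(); ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] != 0 && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---- exact Euclidean distance transform -------------------------------------------
// Felzenszwalb & Huttenlocher separable squared-distance transform, with per-axis
// physical spacing, so distances are in mm between voxel centers.

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb,
                 int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(IntegerVector feature, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (feature.size() != n) stop("feature length does not match dim");
  // large finite sentinel: infinities would turn the lower-envelope
  // intersection formula into NaN on feature-free scan lines
  const double BIG = 1e30;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = feature[i] != 0 ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // x-lines
  double w2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, v, zb, nx, w2);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // y-lines
  w2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)nx * ny * (R_xlen_t)z;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)nx * y];
      dt1d(f, d, v, zb, ny, w2);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)nx * y] = d[y];
    }
  // z-lines
  w2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)nx * ny * z];
      dt1d(f, d, v, zb, nz, w2);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)nx * ny * z] = d[z];
    }
  return g;
}

// ---- capsule rasterization --------------------------------------------------------
// Marks voxels whose center lies within `radius` of any segment p0->p1 (capsule =
// cylinder with hemispherical caps). Voxel center of index (i,j,k), 0-based, is at
// origin + (i*dx, j*dy, k*dz) in mm. Segments are an m x 6 matrix (x0,y0,z0,x1,y1,z1).

// [[Rcpp::export(name = ".raster_capsules")]]
IntegerVector raster_capsules(IntegerVector dim, NumericVector spacing,
                              NumericVector origin, NumericMatrix segments,
                              NumericVector radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  for (int s = 0; s < segments.nrow(); ++s) {
    const double r = radius[s % radius.size()];
    if (r < 0) continue;
    double ax = segments(s, 0), ay = segments(s, 1), az = segments(s, 2);
    double bx = segments(s, 3), by = segments(s, 4), bz = segments(s, 5);
    double lox = std::min(ax, bx) - r, hix = std::max(ax, bx) + r;
    double loy = std::min(ay, by) - r, hiy = std::max(ay, by) + r;
    double loz = std::min(az, bz) - r, hiz = std::max(az, bz) + r;
    int i0 = std::max(0, (int)std::floor((lox - origin[0]) / dx));
    int i1 = std::min(nx - 1, (int)std::ceil((hix - origin[0]) / dx));
    int j0 = std::max(0, (int)std::floor((loy - origin[1]) / dy));
    int j1 = std::min(ny - 1, (int)std::ceil((hiy - origin[1]) / dy));
    int k0 = std::max(0, (int)std::floor((loz - origin[2]) / dz));
    int k1 = std::min(nz - 1, (int)std::ceil((hiz - origin[2]) / dz));
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double uu = ux * ux + uy * uy + uz * uz;
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k) {
      double pz = origin[2] + k * dz;
      for (int j = j0; j <= j1; ++j) {
        double py = origin[1] + j * dy;
        for (int i = i0; i <= i1; ++i) {
          double px = origin[0] + i * dx;
          double wx = px - ax, wy = py - ay, wz = pz - az;
          double t = uu > 0 ? (wx * ux + wy * uy + wz * uz) / uu : 0.0;
          t = std::max(0.0, std::min(1.0, t));
          double qx = wx - t * ux, qy = wy - t * uy, qz = wz - t * uz;
          if (qx * qx + qy * qy + qz * qz <= r2)
            out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
        }
      }
    }
  }
  return out;
}

// ---- exact permutation p-value for correlation statistics -------------------------
// For fixed marginals, |r| >= |r_obs| (Pearson on values, Spearman on ranks) is
// equivalent to |sum(x*y_perm) - n*xbar*ybar| >= |observed|. Enumerates all distinct
// permutations of y and returns the two-sided exceedance proportion.

// [[Rcpp::export(name = ".perm_corr_pvalue")]]
double perm_corr_pvalue(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (n > 10) stop("exact permutation limited to n <= 10");
  double xbar = 0, ybar = 0;
  for (int i = 0; i < n; ++i) { xbar += x[i]; ybar += y[i]; }
  xbar /= n; ybar /= n;
  double obs = 0;
  for (int i = 0; i < n; ++i) obs += x[i] * y[i];
  obs = std::fabs(obs - n * xbar * ybar);

  std::vector<double> yp(y.begin(), y.end());
  std::sort(yp.begin(), yp.end());
  double tol = 1e-9 * (1.0 + obs);
  long double hits = 0, total = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += x[i] * yp[i];
    if (std::fabs(s - n * xbar * ybar) >= obs - tol) hits += 1;
    total += 1;
  } while (std::next_permutation(yp.begin(), yp.end()));
  return (double)(hits / total);
}
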