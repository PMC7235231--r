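#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// ---- 3D squared Euclidean distance transform -------------------------------
// Felzenszwalb & Huttenlocher lower-envelope algorithm, applied separably
// along each axis. Input f: +inf inside the foreground, 0 on background.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    if (!std::isfinite(f[q]) &&
        !std::isfinite(f[v[k]])) { // both +inf: parabola never lower
      continue;
    }
    double s;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      if (!std::isfinite(fq)) { s = std::numeric_limits<double>::infinity(); }
      else if (!std::isfinite(fv)) { s = -std::numeric_limits<double>::infinity(); }
      else s = ((fq + q * (double)q) - (fv + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); i++) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // along x
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      size_t off = (size_t)z * nx * ny + (size_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = g[off + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; x++) g[off + x] = d[x];
    }
  // along y
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      size_t off = (size_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = g[off + (size_t)y * nx];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; y++) g[off + (size_t)y * nx] = d[y];
    }
  // along z
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      size_t off = (size_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = g[off + (size_t)z * nx * ny];
      dt1d(f, d, nz);
      for (int z = 0; z < nz; z++) g[off + (size_t)z * nx * ny] = d[z];
    }

  NumericVector out((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); i++) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}

// ---- parallel-beam forward projection --------------------------------------
// Rotation about the z axis; angle 0 projects along +y. Detector coordinate s
// runs along (cos a, sin a); ray direction is (-sin a, cos a). Bilinear
// interpolation in the (x, y) plane, unit step along the ray, voxel units.
// Output: (ns, nz, n_angles) array of line integrals in value*voxel units.

// [[Rcpp::export(name = ".cpp_forward_project")]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector angles_rad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  const int ns = nx;
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cs = (ns - 1) / 2.0;
  const double tmax = std::sqrt((double)nx * nx + (double)ny * ny) / 2.0 + 1.0;

  NumericVector out((size_t)ns * nz * na);
  const double* v = vol.begin();

  for (int ia = 0; ia < na; ia++) {
    const double ca = std::cos(angles_rad[ia]), sa = std::sin(angles_rad[ia]);
    for (int is = 0; is < ns; is++) {
      const double s = is - cs;
      // accumulate per-z sums along the ray
      std::vector<double> acc(nz, 0.0);
      for (double t = -tmax; t <= tmax; t += 1.0) {
        const double x = cx + s * ca - t * sa;
        const double y = cy + s * sa + t * ca;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        if (x0 < -1 || x0 > nx - 1 || y0 < -1 || y0 > ny - 1) continue;
        const double fx = x - x0, fy = y - y0;
        const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
        const double w01 = (1 - fx) * fy, w11 = fx * fy;
        const bool i00 = x0 >= 0 && y0 >= 0;
        const bool i10 = x0 + 1 < nx && y0 >= 0;
        const bool i01 = x0 >= 0 && y0 + 1 < ny;
        const bool i11 = x0 + 1 < nx && y0 + 1 < ny;
        for (int z = 0; z < nz; z++) {
          const size_t base = (size_t)z * nx * ny;
          double val = 0.0;
          if (i00) val += w00 * v[base + (size_t)y0 * nx + x0];
          if (i10) val += w10 * v[base + (size_t)y0 * nx + x0 + 1];
          if (i01) val += w01 * v[base + (size_t)(y0 + 1) * nx + x0];
          if (i11) val += w11 * v[base + (size_t)(y0 + 1) * nx + x0 + 1];
          acc[z] += val;
        }
      }
      for (int z = 0; z < nz; z++)
        out[(size_t)ia * ns * nz + (size_t)z * ns + is] = acc[z];
    }
  }
  out.attr("dim") = IntegerVector::create(ns, nz, na);
  return out;
}

// ---- backprojection ---------------------------------------------------------
// Accumulates filtered projections over angles; caller multiplies by
// pi / n_angles. proj dims: (ns, nz, na). Output (ns, ns, nz).

// [[Rcpp::export(name = ".cpp_backproject")]]
NumericVector cpp_backproject(NumericVector proj, IntegerVector pdims,
                              NumericVector angles_rad) {
  const int ns = pdims[0], nz = pdims[1], na = pdims[2];
  const int nx = ns, ny = ns;
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cs = (ns - 1) / 2.0;

  NumericVector out((size_t)nx * ny * nz);
  const double* p = proj.begin();
  double* o = out.begin();

  for (int ia = 0; ia < na; ia++) {
    const double ca = std::cos(angles_rad[ia]), sa = std::sin(angles_rad[ia]);
    const size_t poff = (size_t)ia * ns * nz;
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) {
        const double s = (x - cx) * ca + (y - cy) * sa + cs;
        const int s0 = (int)std::floor(s);
        if (s0 < -1 || s0 > ns - 1) continue;
        const double fs = s - s0;
        const bool a0 = s0 >= 0, a1 = s0 + 1 < ns;
        for (int z = 0; z < nz; z++) {
          double val = 0.0;
          if (a0) val += (1 - fs) * p[poff + (size_t)z * ns + s0];
          if (a1) val += fs * p[poff + (size_t)z * ns + s0 + 1];
          o[(size_t)z * nx * ny + (size_t)y * nx + x] += val;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
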