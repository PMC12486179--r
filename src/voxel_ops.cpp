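#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3D voxel primitives shared by the detection and morphometry stages.
// All arrays are passed as flat vectors in R's column-major order with
// dim = (nx, ny, nz); spacing is mm per axis.

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Squared-distance 1D transform (Felzenszwalb & Huttenlocher) on a
// regularly sampled line with sample spacing h.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zbuf,
                 int n, double h) {
  const double INF = R_PosInf;
  int k = 0;
  v[0] = 0;
  zbuf[0] = -INF;
  zbuf[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h * h * q * q) - (f[p] + h * h * p * p)) / (2.0 * h * q - 2.0 * h * p);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INF;
  }
  int k2 = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (zbuf[k2 + 1] < h * q) ++k2;
    double dq = h * q - h * v[k2];
    d[q] = dq * dq + f[v[k2]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double INF = R_PosInf;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[vidx(x, y, z, nx, ny)];
      dt1d(f, d, v, zbuf, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[vidx(x, y, z, nx, ny)] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[vidx(x, y, z, nx, ny)];
      dt1d(f, d, v, zbuf, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[vidx(x, y, z, nx, ny)] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[vidx(x, y, z, nx, ny)];
      dt1d(f, d, v, zbuf, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[vidx(x, y, z, nx, ny)] = d[z];
    }
  return out;
}

// [[Rcpp::export(name = ".label_cpp")]]
IntegerVector label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int cur = 0;
  std::queue<std::array<int, 3>> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = vidx(x, y, z, nx, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++cur;
        lab[i] = cur;
        q.push({x, y, z});
        while (!q.empty()) {
          std::array<int, 3> p = q.front(); q.pop();
          for (size_t k = 0; k < offs.size(); ++k) {
            int xx = p[0] + offs[k][0], yy = p[1] + offs[k][1], zz = p[2] + offs[k][2];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            R_xlen_t j = vidx(xx, yy, zz, nx, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = cur; q.push({xx, yy, zz}); }
          }
        }
      }
  return lab;
}

// Local thickness by the distance-ridge / sphere-painting construction:
// every voxel of the structure is assigned the diameter of the largest
// inscribed sphere that contains it. Distances are centre-to-centre; the
// half-voxel surface offset is subtracted at the end so an n-voxel slab
// measures n * h.
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dim,
                                  NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d2 = edt_sq_cpp(mask, dim, spacing);
  NumericVector th(n, 0.0);

  std::vector<R_xlen_t> fg;
  fg.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i] && R_finite(d2[i])) fg.push_back(i);
  std::sort(fg.begin(), fg.end(),
            [&](R_xlen_t a, R_xlen_t b) { return d2[a] > d2[b]; });

  double hmin = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  for (size_t kk = 0; kk < fg.size(); ++kk) {
    R_xlen_t i = fg[kk];
    double R = std::sqrt(d2[i]);
    double diam = 2.0 * R;
    int x = (int)(i % nx);
    int y = (int)((i / nx) % ny);
    int z = (int)(i / ((R_xlen_t)nx * ny));
    int rx = (int)std::floor(R / spacing[0]);
    int ry = (int)std::floor(R / spacing[1]);
    int rz = (int)std::floor(R / spacing[2]);
    double R2 = R * R;
    for (int dz = -rz; dz <= rz; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      double az = dz * spacing[2]; az *= az;
      for (int dy = -ry; dy <= ry; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        double ay = dy * spacing[1]; ay *= ay;
        if (az + ay > R2) continue;
        for (int dx = -rx; dx <= rx; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          double ax = dx * spacing[0]; ax *= ax;
          if (az + ay + ax > R2) continue;
          R_xlen_t j = vidx(xx, yy, zz, nx, ny);
          if (th[j] == 0.0) th[j] = diam;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) {
      if (!R_finite(d2[i])) th[i] = R_PosInf;   // no background anywhere
      else th[i] = th[i] - hmin;
    } else th[i] = 0.0;
  }
  return th;
}

// Separable Gaussian smoothing, sigma per axis in voxel units, reflected
// boundaries, kernel truncated at 3 sigma.
// [[Rcpp::export(name = ".gauss3_cpp")]]
NumericVector gauss3_cpp(NumericVector x, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector a = clone(x), b(n);

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + r];
    }
    for (int i = 0; i <= 2 * r; ++i) k[i] /= ksum;

    int len = (ax == 0) ? nx : (ax == 1) ? ny : nz;
    for (int z = 0; z < (ax == 2 ? 1 : nz); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y)
        for (int xx = 0; xx < (ax == 0 ? 1 : nx); ++xx) {
          // iterate the full line along axis `ax` through (xx, y, z)
          for (int t = 0; t < len; ++t) {
            double acc = 0;
            for (int o = -r; o <= r; ++o) {
              int tt = t + o;
              if (tt < 0) tt = -tt - 1;
              if (tt >= len) tt = 2 * len - tt - 1;
              R_xlen_t j = (ax == 0) ? vidx(tt, y, z, nx, ny)
                         : (ax == 1) ? vidx(xx, tt, z, nx, ny)
                                     : vidx(xx, y, tt, nx, ny);
              acc += k[o + r] * a[j];
            }
            R_xlen_t i = (ax == 0) ? vidx(t, y, z, nx, ny)
                       : (ax == 1) ? vidx(xx, t, z, nx, ny)
                                   : vidx(xx, y, t, nx, ny);
            b[i] = acc;
          }
        }
    // swap: careful loops above only iterate planes orthogonal to ax
    // (handled by the ternary bounds); copy b -> a
    std::copy(b.begin(), b.end(), a.begin());
  }
  return a;
}

// Mean-intercept-length sampling. For each direction a raster of parallel
// test lines (spacing line_spacing mm) is marched through the volume at
// sub-voxel steps; within the ROI the bone path length and the number of
// distinct bone intercepts (entries into bone) are accumulated.
// Returns an n_dir x 2 matrix: (bone length mm, intercept count).
// [[Rcpp::export(name = ".mil_cpp")]]
NumericMatrix mil_cpp(LogicalVector bone, LogicalVector roi, IntegerVector dim,
                      NumericVector spacing, NumericMatrix dirs,
                      double line_spacing, double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nd = dirs.nrow();
  NumericMatrix out(nd, 2);
  double cx = 0.5 * (nx - 1) * spacing[0];
  double cy = 0.5 * (ny - 1) * spacing[1];
  double cz = 0.5 * (nz - 1) * spacing[2];
  double ex = nx * spacing[0], ey = ny * spacing[1], ez = nz * spacing[2];
  double Rd = 0.5 * std::sqrt(ex * ex + ey * ey + ez * ez);

  for (int d = 0; d < nd; ++d) {
    double dxv = dirs(d, 0), dyv = dirs(d, 1), dzv = dirs(d, 2);
    // orthonormal basis (u, v) perpendicular to the direction
    double ux, uy, uz;
    if (std::fabs(dxv) <= std::fabs(dyv) && std::fabs(dxv) <= std::fabs(dzv)) {
      ux = 0; uy = -dzv; uz = dyv;
    } else if (std::fabs(dyv) <= std::fabs(dzv)) {
      ux = -dzv; uy = 0; uz = dxv;
    } else {
      ux = -dyv; uy = dxv; uz = 0;
    }
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    double vx = dyv * uz - dzv * uy;
    double vy = dzv * ux - dxv * uz;
    double vz = dxv * uy - dyv * ux;

    double len = 0;
    double runs = 0;
    int nsteps = (int)std::ceil(2.0 * Rd / step);
    for (double a = -Rd; a <= Rd; a += line_spacing)
      for (double b = -Rd; b <= Rd; b += line_spacing) {
        double ox = cx + a * ux + b * vx - Rd * dxv;
        double oy = cy + a * uy + b * vy - Rd * dyv;
        double oz = cz + a * uz + b * vz - Rd * dzv;
        bool prev = false;
        for (int t = 0; t <= nsteps; ++t) {
          double px = ox + t * step * dxv;
          double py = oy + t * step * dyv;
          double pz = oz + t * step * dzv;
          int ix = (int)std::lround(px / spacing[0]);
          int iy = (int)std::lround(py / spacing[1]);
          int iz = (int)std::lround(pz / spacing[2]);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) {
            prev = false;
            continue;
          }
          R_xlen_t j = vidx(ix, iy, iz, nx, ny);
          if (!roi[j]) { prev = false; continue; }
          bool cur = bone[j];
          if (cur) {
            len += step;
            if (!prev) runs += 1;
          }
          prev = cur;
        }
      }
    out(d, 0) = len;
    out(d, 1) = runs;
  }
  return out;
}
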