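#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Half-sample symmetric (mirror) index reflection; keeps kernel mass inside
// the grid so normalized convolutions conserve total intensity exactly.
static inline int mirror(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1; else i = 2 * n - 1 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma, int radius) {
  std::vector<double> w(2 * radius + 1);
  double s = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    double v = (sigma > 0.0) ? std::exp(-0.5 * t * t / (sigma * sigma)) : (t == 0 ? 1.0 : 0.0);
    w[t + radius] = v;
    s += v;
  }
  for (double& v : w) v /= s;
  return w;
}

// Separable convolution along one axis with mirror boundaries.
static void conv_axis(std::vector<double>& x, int nx, int ny, int nz,
                      int axis, const std::vector<double>& w) {
  int radius = ((int)w.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> line(len);
  // strides for column-major (R) layout
  long str[3] = {1, (long)nx, (long)nx * ny};
  long s = str[axis];
  int na = n[(axis + 1) % 3], nb = n[(axis + 2) % 3];
  long sa = str[(axis + 1) % 3], sb = str[(axis + 2) % 3];
  for (int b = 0; b < nb; ++b) {
    for (int a = 0; a < na; ++a) {
      long base = a * sa + b * sb;
      for (int i = 0; i < len; ++i) line[i] = x[base + i * s];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int t = -radius; t <= radius; ++t)
          acc += w[t + radius] * line[mirror(i + t, len)];
        x[base + i * s] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector img, IntegerVector dim,
                             NumericVector sigma_vox, IntegerVector radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> x(img.begin(), img.end());
  for (int axis = 0; axis < 3; ++axis) {
    if (sigma_vox[axis] <= 0.0) continue;
    conv_axis(x, nx, ny, nz, axis, gauss_kernel(sigma_vox[axis], radius[axis]));
  }
  NumericVector out(x.begin(), x.end());
  out.attr("dim") = dim;
  return out;
}

// 3-D bilateral filter: product of a spatial Gaussian (per-axis sigma in
// voxels) and a radiometric Gaussian on intensity differences, normalized
// per voxel, applied `iterations` times.
// [[Rcpp::export]]
NumericVector cpp_bilateral(NumericVector img, IntegerVector dim,
                            NumericVector sigma_vox, IntegerVector radius,
                            double sigma_r, int iterations) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  int rx = radius[0], ry = radius[1], rz = radius[2];
  std::vector<double> wx = gauss_kernel(sigma_vox[0], rx);
  std::vector<double> wy = gauss_kernel(sigma_vox[1], ry);
  std::vector<double> wz = gauss_kernel(sigma_vox[2], rz);
  std::vector<double> cur(img.begin(), img.end()), nxt(nvox);
  double inv2sr2 = 1.0 / (2.0 * sigma_r * sigma_r);
  for (int it = 0; it < iterations; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long idx = i + (long)nx * (j + (long)ny * k);
          double centre = cur[idx];
          double acc = 0.0, wsum = 0.0;
          for (int dz = -rz; dz <= rz; ++dz) {
            int kk = mirror(k + dz, nz);
            double wzv = wz[dz + rz];
            for (int dy = -ry; dy <= ry; ++dy) {
              int jj = mirror(j + dy, ny);
              double wzy = wzv * wy[dy + ry];
              long row = (long)nx * (jj + (long)ny * kk);
              for (int dx = -rx; dx <= rx; ++dx) {
                int ii = mirror(i + dx, nx);
                double v = cur[row + ii];
                double d = v - centre;
                double w = wzy * wx[dx + rx] * std::exp(-d * d * inv2sr2);
                acc += w * v;
                wsum += w;
              }
            }
          }
          nxt[idx] = acc / wsum;
        }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// Perona-Malik anisotropic diffusion, flux form on the 6-neighbourhood with
// conductance exp(-(d/kappa)^2); mirror boundaries give zero boundary flux,
// so total intensity is conserved.
// [[Rcpp::export]]
NumericVector cpp_aniso_diffusion(NumericVector img, IntegerVector dim,
                                  int iterations, double kappa, double dt) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  std::vector<double> cur(img.begin(), img.end()), nxt(nvox);
  double invk2 = 1.0 / (kappa * kappa);
  long str[3] = {1, (long)nx, (long)nx * ny};
  int n[3] = {nx, ny, nz};
  for (int it = 0; it < iterations; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long idx = i + (long)nx * (j + (long)ny * k);
          int pos[3] = {i, j, k};
          double flux = 0.0;
          for (int axis = 0; axis < 3; ++axis) {
            for (int dir = -1; dir <= 1; dir += 2) {
              int p = pos[axis] + dir;
              if (p < 0 || p >= n[axis]) continue; // zero-flux boundary
              double d = cur[idx + dir * str[axis]] - cur[idx];
              flux += std::exp(-d * d * invk2) * d;
            }
          }
          nxt[idx] = cur[idx] + dt * flux;
        }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// One smoothing pass of the a-trous (undecimated) wavelet scheme:
// separable B3-spline kernel (1,4,6,4,1)/16 with `step`-spaced taps.
// [[Rcpp::export]]
NumericVector cpp_atrous_smooth(NumericVector img, IntegerVector dim, int step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> x(img.begin(), img.end());
  const double b3[5] = {1.0 / 16, 4.0 / 16, 6.0 / 16, 4.0 / 16, 1.0 / 16};
  for (int axis = 0; axis < 3; ++axis) {
    int radius = 2 * step;
    std::vector<double> w(2 * radius + 1, 0.0);
    for (int t = -2; t <= 2; ++t) w[t * step + radius] = b3[t + 2];
    conv_axis(x, nx, ny, nz, axis, w);
  }
  NumericVector out(x.begin(), x.end());
  out.attr("dim") = dim;
  return out;
}

// Felzenszwalb & Huttenlocher 1-D squared distance transform with
// anisotropic sample spacing, applied per axis: exact Euclidean distances.
static void dt1d(std::vector<double>& f, double w) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int kk = 0;
  v[0] = 0; z[0] = -HUGE_VAL; z[1] = HUGE_VAL;
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q; z[kk] = s; z[kk + 1] = HUGE_VAL;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = (double)(q - v[kk]) * w;
    d[q] = dq * dq + f[v[kk]];
  }
  f = d;
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel of `mask`. All-false mask gives +Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  // large finite sentinel keeps the parabola arithmetic well defined on
  // lines that have no mask voxel yet
  const double BIG = 1e20;
  std::vector<double> d(nvox);
  for (long i = 0; i < nvox; ++i) d[i] = mask[i] ? 0.0 : BIG;
  int n[3] = {nx, ny, nz};
  long str[3] = {1, (long)nx, (long)nx * ny};
  std::vector<double> line;
  for (int axis = 0; axis < 3; ++axis) {
    int len = n[axis];
    line.resize(len);
    int na = n[(axis + 1) % 3], nb = n[(axis + 2) % 3];
    long sa = str[(axis + 1) % 3], sb = str[(axis + 2) % 3], s = str[axis];
    for (int b = 0; b < nb; ++b)
      for (int a = 0; a < na; ++a) {
        long base = a * sa + b * sb;
        bool any_finite = false;
        for (int i = 0; i < len; ++i) {
          line[i] = d[base + i * s];
          if (line[i] < 0.5e20) any_finite = true;
        }
        if (!any_finite) continue;
        dt1d(line, spacing[axis]);
        for (int i = 0; i < len; ++i) d[base + i * s] = line[i];
      }
  }
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = dim;
  return out;
}

// One explicit level-set update: phi <- phi - dt*[ Fb_upwind + Fc_central ]
// with balloon force Fb = g*nu (Godunov upwinding of |grad phi|) and
// curvature force speed -g*eps*kappa using central differences. Gradients
// are taken in mm. Returns updated phi, flipped-voxel count and the largest
// absolute update (for CFL checking).
// [[Rcpp::export]]
List cpp_levelset_step(NumericVector phi, NumericVector g, IntegerVector dim,
                       NumericVector spacing, double nu, double eps, double dt) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = dim;
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  long sx = 1, sy = nx, sz = (long)nx * ny;
  long flipped = 0;
  double max_upd = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long idx = i + (long)nx * (j + (long)ny * k);
        long ixm = mirror(i - 1, nx) + (long)nx * (j + (long)ny * k);
        long ixp = mirror(i + 1, nx) + (long)nx * (j + (long)ny * k);
        long iym = i + (long)nx * (mirror(j - 1, ny) + (long)ny * k);
        long iyp = i + (long)nx * (mirror(j + 1, ny) + (long)ny * k);
        long izm = i + (long)nx * (j + (long)ny * mirror(k - 1, nz));
        long izp = i + (long)nx * (j + (long)ny * mirror(k + 1, nz));
        double p0 = phi[idx];
        double pxm = phi[ixm], pxp = phi[ixp];
        double pym = phi[iym], pyp = phi[iyp];
        double pzm = phi[izm], pzp = phi[izp];
        // one-sided differences
        double Dxm = (p0 - pxm) / hx, Dxp = (pxp - p0) / hx;
        double Dym = (p0 - pym) / hy, Dyp = (pyp - p0) / hy;
        double Dzm = (p0 - pzm) / hz, Dzp = (pzp - p0) / hz;
        // central first derivatives
        double px = 0.5 * (Dxm + Dxp), py = 0.5 * (Dym + Dyp), pz = 0.5 * (Dzm + Dzp);
        double grad2 = px * px + py * py + pz * pz;
        double gradc = std::sqrt(grad2);
        // curvature from central differences
        double kap = 0.0;
        if (grad2 > 1e-12) {
          double pxx = (pxp - 2.0 * p0 + pxm) / (hx * hx);
          double pyy = (pyp - 2.0 * p0 + pym) / (hy * hy);
          double pzz = (pzp - 2.0 * p0 + pzm) / (hz * hz);
          double pxy = (phi[mirror(i + 1, nx) + (long)nx * (mirror(j + 1, ny) + (long)ny * k)]
                      - phi[mirror(i + 1, nx) + (long)nx * (mirror(j - 1, ny) + (long)ny * k)]
                      - phi[mirror(i - 1, nx) + (long)nx * (mirror(j + 1, ny) + (long)ny * k)]
                      + phi[mirror(i - 1, nx) + (long)nx * (mirror(j - 1, ny) + (long)ny * k)]) / (4.0 * hx * hy);
          double pxz = (phi[mirror(i + 1, nx) + (long)nx * (j + (long)ny * mirror(k + 1, nz))]
                      - phi[mirror(i + 1, nx) + (long)nx * (j + (long)ny * mirror(k - 1, nz))]
                      - phi[mirror(i - 1, nx) + (long)nx * (j + (long)ny * mirror(k + 1, nz))]
                      + phi[mirror(i - 1, nx) + (long)nx * (j + (long)ny * mirror(k - 1, nz))]) / (4.0 * hx * hz);
          double pyz = (phi[i + (long)nx * (mirror(j + 1, ny) + (long)ny * mirror(k + 1, nz))]
                      - phi[i + (long)nx * (mirror(j + 1, ny) + (long)ny * mirror(k - 1, nz))]
                      - phi[i + (long)nx * (mirror(j - 1, ny) + (long)ny * mirror(k + 1, nz))]
                      + phi[i + (long)nx * (mirror(j - 1, ny) + (long)ny * mirror(k - 1, nz))]) / (4.0 * hy * hz);
          kap = (pxx * (py * py + pz * pz) + pyy * (px * px + pz * pz) + pzz * (px * px + py * py)
                 - 2.0 * (px * py * pxy + px * pz * pxz + py * pz * pyz)) / (grad2 * gradc);
          // clamp to the grid-resolvable curvature to keep the explicit
          // scheme stable where phi is kinked
          double kmax = 1.0 / std::min(hx, std::min(hy, hz));
          if (kap > kmax) kap = kmax;
          if (kap < -kmax) kap = -kmax;
        }
        double Fb = g[idx] * nu;
        double gplus = std::sqrt(std::max(Dxm, 0.0) * std::max(Dxm, 0.0) + std::min(Dxp, 0.0) * std::min(Dxp, 0.0)
                               + std::max(Dym, 0.0) * std::max(Dym, 0.0) + std::min(Dyp, 0.0) * std::min(Dyp, 0.0)
                               + std::max(Dzm, 0.0) * std::max(Dzm, 0.0) + std::min(Dzp, 0.0) * std::min(Dzp, 0.0));
        double gminus = std::sqrt(std::max(Dxp, 0.0) * std::max(Dxp, 0.0) + std::min(Dxm, 0.0) * std::min(Dxm, 0.0)
                                + std::max(Dyp, 0.0) * std::max(Dyp, 0.0) + std::min(Dym, 0.0) * std::min(Dym, 0.0)
                                + std::max(Dzp, 0.0) * std::max(Dzp, 0.0) + std::min(Dzm, 0.0) * std::min(Dzm, 0.0));
        double adv = (Fb > 0.0) ? Fb * gplus : Fb * gminus;
        double curv = -g[idx] * eps * kap * gradc;
        double upd = -dt * (adv + curv);
        double pnew = p0 + upd;
        if (std::fabs(upd) > max_upd) max_upd = std::fabs(upd);
        if ((pnew < 0.0) != (p0 < 0.0)) ++flipped;
        out[idx] = pnew;
      }
  return List::create(_["phi"] = out, _["flipped"] = (double)flipped,
                      _["max_update"] = max_upd);
}

// Fuzzy c-means alternating updates (memberships implicit): returns the
// fitted centroids, per-iteration objective trace and convergence info.
// Semantics match the R driver: per-class channel weights in the distance,
// u_ik = d_ik^(-1/(b-1)) normalized, exact-hit voxels get membership 1,
// near-duplicate centroids are jittered apart before each iteration.
// [[Rcpp::export]]
List cpp_fcm_fit(NumericMatrix x, NumericMatrix cen0, NumericMatrix w,
                 double b, double tol, int max_iter) {
  int N = x.nrow(), C = x.ncol(), K = cen0.nrow();
  NumericMatrix cen(clone(cen0));
  double p = 1.0 / (b - 1.0);
  bool reseeded = false, converged = false;
  std::vector<double> obj;
  double scale_ref = 1e-12;
  for (int c = 0; c < C; ++c) {
    double lo = x(0, c), hi = x(0, c);
    for (int i = 1; i < N; ++i) {
      if (x(i, c) < lo) lo = x(i, c);
      if (x(i, c) > hi) hi = x(i, c);
    }
    if (hi - lo > scale_ref) scale_ref = hi - lo;
  }
  std::vector<double> d2(K), u(K), num(K * C), den(K);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // jitter near-duplicate centroids apart
    int ndup = 0;
    for (int k = 1; k < K; ++k)
      for (int l = 0; l < k; ++l) {
        bool same = true;
        for (int c = 0; c < C; ++c)
          if (std::fabs(cen(k, c) - cen(l, c)) > 1e-9 * scale_ref) { same = false; break; }
        if (same) {
          ++ndup;
          for (int c = 0; c < C; ++c) cen(k, c) += 1e-4 * scale_ref * ndup;
          reseeded = true;
          break;
        }
      }
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    double J = 0.0;
    for (int i = 0; i < N; ++i) {
      int hit = -1;
      double dmin = R_PosInf;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int c = 0; c < C; ++c) {
          double wv = w(k, c);
          if (wv != 0.0) { double d = x(i, c) - cen(k, c); acc += wv * d * d; }
        }
        d2[k] = acc;
        if (acc < dmin) { dmin = acc; hit = k; }
      }
      if (dmin < 1e-24) {
        for (int k = 0; k < K; ++k) u[k] = (k == hit) ? 1.0 : 0.0;
      } else {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          double inv = (b == 2.0) ? 1.0 / d2[k] : std::pow(d2[k], -p);
          u[k] = inv; s += inv;
        }
        for (int k = 0; k < K; ++k) u[k] /= s;
      }
      for (int k = 0; k < K; ++k) {
        double ub = (b == 2.0) ? u[k] * u[k] : std::pow(u[k], b);
        J += ub * d2[k];
        den[k] += ub;
        for (int c = 0; c < C; ++c) num[k * C + c] += ub * x(i, c);
      }
    }
    obj.push_back(J);
    double shift = 0.0;
    for (int k = 0; k < K; ++k)
      for (int c = 0; c < C; ++c) {
        double nc = num[k * C + c] / den[k];
        double dsh = std::fabs(nc - cen(k, c));
        if (dsh > shift) shift = dsh;
        cen(k, c) = nc;
      }
    if (shift < tol) { converged = true; break; }
  }
  return List::create(_["centroids"] = cen, _["objective"] = wrap(obj),
                      _["iterations"] = std::min(it, max_iter),
                      _["converged"] = converged, _["reseeded"] = reseeded);
}

// Fill cavities: background (6-connected) not reachable from the array
// border becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  std::vector<char> outside(nvox, 0);
  std::queue<long> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        long idx = i + (long)nx * (j + (long)ny * k);
        if (!mask[idx] && !outside[idx]) { outside[idx] = 1; q.push(idx); }
      }
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    long idx = q.front(); q.pop();
    int i = idx % nx, j = (idx / nx) % ny, k = idx / ((long)nx * ny);
    for (auto& d : d6) {
      int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      long nidx = ii + (long)nx * (jj + (long)ny * kk);
      if (!mask[nidx] && !outside[nidx]) { outside[nidx] = 1; q.push(nidx); }
    }
  }
  LogicalVector out(nvox);
  out.attr("dim") = dim;
  for (long v = 0; v < nvox; ++v) out[v] = mask[v] || !outside[v];
  return out;
}

// 26-connected component of `mask` containing the (0-based) seed voxel.
// [[Rcpp::export]]
LogicalVector cpp_seed_component(LogicalVector mask, IntegerVector dim, int seed) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long nvox = (long)nx * ny * nz;
  LogicalVector out(nvox);
  out.attr("dim") = dim;
  if (seed < 0 || seed >= nvox || !mask[seed]) return out;
  std::vector<char> visited(nvox, 0);
  std::queue<long> q;
  q.push(seed);
  visited[seed] = 1;
  while (!q.empty()) {
    long idx = q.front(); q.pop();
    out[idx] = true;
    int i = idx % nx, j = (idx / nx) % ny, k = idx / ((long)nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          long nidx = ii + (long)nx * (jj + (long)ny * kk);
          if (!visited[nidx] && mask[nidx]) { visited[nidx] = 1; q.push(nidx); }
        }
  }
  return out;
}
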