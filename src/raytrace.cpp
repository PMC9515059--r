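// Ray tracing on CT-like volumes (offset-1000 gray scale, water = 1000):
// water-equivalent (radiological) depth, viewport gray statistics,
// the pencil-cone dose matrix, and per-beam projection feature images.
//
// Volume layout: R array dim c(nx, ny, nz), column-major; the centre of
// voxel (i, j, k) (0-based) is origin + (i, j, k) * spacing.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Vol {
  const double *v;
  int nx, ny, nz;
  double sx, sy, sz, ox, oy, oz;
};

inline double tri(const Vol &V, double x, double y, double z) {
  // trilinear interpolation; outside the grid counts as air (0)
  double gx = (x - V.ox) / V.sx, gy = (y - V.oy) / V.sy, gz = (z - V.oz) / V.sz;
  if (gx < -0.5 || gy < -0.5 || gz < -0.5 ||
      gx > V.nx - 0.5 || gy > V.ny - 0.5 || gz > V.nz - 0.5)
    return 0.0;
  gx = std::min(std::max(gx, 0.0), V.nx - 1.0);
  gy = std::min(std::max(gy, 0.0), V.ny - 1.0);
  gz = std::min(std::max(gz, 0.0), V.nz - 1.0);
  int i0 = std::min((int)gx, V.nx - 2), j0 = std::min((int)gy, V.ny - 2),
      k0 = std::min((int)gz, V.nz - 2);
  if (V.nx == 1) i0 = 0;
  if (V.ny == 1) j0 = 0;
  if (V.nz == 1) k0 = 0;
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  auto at = [&](int i, int j, int k) {
    return V.v[i + (size_t)V.nx * (j + (size_t)V.ny * k)];
  };
  int i1 = std::min(i0 + 1, V.nx - 1), j1 = std::min(j0 + 1, V.ny - 1),
      k1 = std::min(k0 + 1, V.nz - 1);
  double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
  double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
  double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
  double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

inline int nn_idx(const Vol &V, double x, double y, double z) {
  // 0-based linear index of nearest voxel, -1 outside
  int i = (int)std::lround((x - V.ox) / V.sx);
  int j = (int)std::lround((y - V.oy) / V.sy);
  int k = (int)std::lround((z - V.oz) / V.sz);
  if (i < 0 || j < 0 || k < 0 || i >= V.nx || j >= V.ny || k >= V.nz) return -1;
  return i + V.nx * (j + (size_t)V.ny * k);
}

inline Vol make_vol(const NumericVector &v, const IntegerVector &dim,
                    const NumericVector &spacing, const NumericVector &origin) {
  Vol V;
  V.v = REAL(v);
  V.nx = dim[0]; V.ny = dim[1]; V.nz = dim[2];
  V.sx = spacing[0]; V.sy = spacing[1]; V.sz = spacing[2];
  V.ox = origin[0]; V.oy = origin[1]; V.oz = origin[2];
  return V;
}

// sample-index range [qlo, qhi) of the midpoint samples t_q = (q + 0.5) h
// that can fall inside the volume's outer halo box (outside it the gray is
// 0 by construction, so those samples are skipped without changing the sum)
inline void clip_ray(const Vol &V, const double a[3], const double d[3],
                     double L, double h, int nseg, int &qlo, int &qhi) {
  double tlo = 0.0, thi = L;
  const double lo[3] = {V.ox - 0.5 * V.sx, V.oy - 0.5 * V.sy,
                        V.oz - 0.5 * V.sz};
  const double hi[3] = {V.ox + (V.nx - 0.5) * V.sx,
                        V.oy + (V.ny - 0.5) * V.sy,
                        V.oz + (V.nz - 0.5) * V.sz};
  for (int ax = 0; ax < 3; ++ax) {
    if (std::abs(d[ax]) < 1e-12) {
      if (a[ax] < lo[ax] || a[ax] > hi[ax]) { qlo = 0; qhi = 0; return; }
      continue;
    }
    double t1 = (lo[ax] - a[ax]) / d[ax], t2 = (hi[ax] - a[ax]) / d[ax];
    if (t1 > t2) std::swap(t1, t2);
    tlo = std::max(tlo, t1);
    thi = std::min(thi, t2);
  }
  if (thi <= tlo) { qlo = 0; qhi = 0; return; }
  qlo = std::max(0, (int)std::floor(tlo / h - 0.5));
  qhi = std::min(nseg, (int)std::ceil(thi / h + 0.5));
}

// midpoint-rule radiological depth along [a, b], density max(gray/1000, 0)
inline double rad_depth(const Vol &V, const double a[3], const double b[3],
                        double step) {
  double dx = b[0] - a[0], dy = b[1] - a[1], dz = b[2] - a[2];
  double L = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L <= 0) return 0.0;
  int nseg = std::max(1, (int)std::ceil(L / step));
  double h = L / nseg, s = 0.0;
  double dir[3] = {dx / L, dy / L, dz / L};
  int qlo = 0, qhi = nseg;
  clip_ray(V, a, dir, L, h, nseg, qlo, qhi);
  for (int q = qlo; q < qhi; ++q) {
    double t = (q + 0.5) * h / L;
    double g = tri(V, a[0] + t * dx, a[1] + t * dy, a[2] + t * dz);
    if (g > 0) s += g / 1000.0 * h;
  }
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".rad_depth_cpp")]]
double rad_depth_cpp(NumericVector vol, IntegerVector dim, NumericVector spacing,
                     NumericVector origin, NumericVector a, NumericVector b,
                     double step = 1.0) {
  Vol V = make_vol(vol, dim, spacing, origin);
  double aa[3] = {a[0], a[1], a[2]}, bb[3] = {b[0], b[1], b[2]};
  return rad_depth(V, aa, bb, step);
}

// Gray-value statistics along skin->centroid rays, nearest-voxel sampling at
// fixed step; the min-gray (gas) test skips the first skin_margin mm so the
// air/skin partial-volume boundary does not trip it.
// Returns S x 3: max_gray, min_gray, depth_mm.
// [[Rcpp::export(name = ".viewport_stats_cpp")]]
NumericMatrix viewport_stats_cpp(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix skin, NumericVector centroid,
                                 double step = 1.0, double skin_margin = 2.0) {
  Vol V = make_vol(vol, dim, spacing, origin);
  int S = skin.nrow();
  NumericMatrix out(S, 3);
  for (int s = 0; s < S; ++s) {
    double a[3] = {skin(s, 0), skin(s, 1), skin(s, 2)};
    double d[3] = {centroid[0] - a[0], centroid[1] - a[1], centroid[2] - a[2]};
    double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double gmax = -1e30, gmin = 1e30;
    int nseg = std::max(1, (int)std::ceil(L / step));
    double h = L / nseg;
    for (int q = 0; q < nseg; ++q) {
      double t = (q + 0.5) * h;
      int idx = nn_idx(V, a[0] + t / L * d[0], a[1] + t / L * d[1],
                       a[2] + t / L * d[2]);
      double g = idx < 0 ? 0.0 : V.v[idx];
      if (g > gmax) gmax = g;
      if (t >= skin_margin && g < gmin) gmin = g;
    }
    out(s, 0) = gmax;
    out(s, 1) = gmin;
    out(s, 2) = L;
  }
  return out;
}

// Pencil-cone dose model with central-axis radiological depth (the
// pencil-beam convention): for voxel p and beam (src, tgt, diam),
//   lateral(p) <= (diam/2) * |p - src| / sad  and p in front of the source
//   => dose/MU = D0 * exp(-mu * rd(t)) * (sad / |p - src|)^2,
// where rd(t) is the radiological depth from the source along the beam's
// central axis, linearly interpolated at the voxel's axis projection
// t = (p - src) . axis. One axis march serves all voxels of a beam.
// Returns sparse triplets (1-based voxel and beam indices).
// [[Rcpp::export(name = ".dose_matrix_cpp")]]
List dose_matrix_cpp(NumericVector vol, IntegerVector dim, NumericVector spacing,
                     NumericVector origin, NumericMatrix vox, NumericMatrix src,
                     NumericMatrix tgt, NumericVector diam, double mu,
                     double D0, double sad = 800.0, double step = 1.0) {
  Vol V = make_vol(vol, dim, spacing, origin);
  int nv = vox.nrow(), nb = src.nrow();
  std::vector<int> ii, jj;
  std::vector<double> xx;
  std::vector<double> cum;
  for (int b = 0; b < nb; ++b) {
    double S0[3] = {src(b, 0), src(b, 1), src(b, 2)};
    double u[3] = {tgt(b, 0) - S0[0], tgt(b, 1) - S0[1], tgt(b, 2) - S0[2]};
    double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    u[0] /= un; u[1] /= un; u[2] /= un;
    double half = diam[b] / 2.0;
    // cumulative axis depth at nodes t_k = k * step, midpoint-sampled
    double Lmax = 2.0 * sad;
    int K = (int)std::ceil(Lmax / step);
    cum.assign(K + 1, 0.0);
    {
      int qlo = 0, qhi = K;
      clip_ray(V, S0, u, Lmax, step, K, qlo, qhi);
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        if (k >= qlo && k < qhi) {
          double tmid = (k + 0.5) * step;
          double g = tri(V, S0[0] + tmid * u[0], S0[1] + tmid * u[1],
                         S0[2] + tmid * u[2]);
          if (g > 0) s += g / 1000.0 * step;
        }
        cum[k + 1] = s;
      }
    }
    for (int i = 0; i < nv; ++i) {
      double w[3] = {vox(i, 0) - S0[0], vox(i, 1) - S0[1], vox(i, 2) - S0[2]};
      double t = w[0] * u[0] + w[1] * u[1] + w[2] * u[2];
      if (t <= 0) continue;
      double r2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
      double lat2 = r2 - t * t;
      double dist = std::sqrt(r2);
      double rcone = half * dist / sad;
      if (lat2 > rcone * rcone) continue;
      double tk = std::min(t / step, (double)K - 1e-9);
      int k0 = (int)tk;
      double rd = cum[k0] + (tk - k0) * (cum[k0 + 1] - cum[k0]);
      double dose = D0 * std::exp(-mu * rd) * (sad / dist) * (sad / dist);
      ii.push_back(i + 1);
      jj.push_back(b + 1);
      xx.push_back(dose);
    }
  }
  return List::create(Named("i") = ii, Named("j") = jj, Named("x") = xx);
}

namespace {

// 7-channel beam feature image on the plane through `centre` perpendicular
// to source->centre, written into out[0 .. H*H*7).
void features_one(const Vol &V, const int *lab, const double *src,
                  const double *tgt, double diam, const double *centre,
                  int H, double pixel_mm, double step, double sad,
                  double overshoot, double *out) {
  int W = H;
  std::fill(out, out + (size_t)H * W * 7, 0.0);
  double n[3] = {centre[0] - src[0], centre[1] - src[1], centre[2] - src[2]};
  double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  if (nn < 1e-9)
    Rcpp::stop("beam source coincides with the projection-plane centre");
  for (int q = 0; q < 3; ++q) n[q] /= nn;
  // in-plane basis: up = patient-superior projected onto the plane
  double up[3] = {0 - n[0] * n[2], 0 - n[1] * n[2], 1 - n[2] * n[2]};
  double upn = std::sqrt(up[0] * up[0] + up[1] * up[1] + up[2] * up[2]);
  if (upn < 1e-6) { up[0] = 1 - n[0] * n[0]; up[1] = -n[1] * n[0]; up[2] = -n[2] * n[0];
    upn = std::sqrt(up[0] * up[0] + up[1] * up[1] + up[2] * up[2]); }
  for (int q = 0; q < 3; ++q) up[q] /= upn;
  double rt[3] = {up[1] * n[2] - up[2] * n[1], up[2] * n[0] - up[0] * n[2],
                  up[0] * n[1] - up[1] * n[0]};  // right = up x normal
  // beam axis for the aperture channel
  double ax[3] = {tgt[0] - src[0], tgt[1] - src[1], tgt[2] - src[2]};
  double axn = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  for (int q = 0; q < 3; ++q) ax[q] /= axn;

  size_t HW = (size_t)H * W;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double uoff = ((H - 1) / 2.0 - r) * pixel_mm;
      double roff = (c - (W - 1) / 2.0) * pixel_mm;
      double p[3];
      for (int q = 0; q < 3; ++q)
        p[q] = centre[q] + uoff * up[q] + roff * rt[q];
      // aperture: lateral distance from the beam axis at this pixel
      double w[3] = {p[0] - src[0], p[1] - src[1], p[2] - src[2]};
      double t = w[0] * ax[0] + w[1] * ax[1] + w[2] * ax[2];
      double r2 = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
      double lat2 = r2 - t * t;
      double rcone = (diam / 2.0) * std::sqrt(r2) / sad;
      size_t px = r + (size_t)H * c;
      if (t > 0 && lat2 <= rcone * rcone) out[px] = 1.0;
      // march source->pixel, extended past the plane, tracking per-structure
      // min/max cumulative radiological depth
      double L = std::sqrt(r2) + overshoot;
      double dirn[3] = {w[0] / std::sqrt(r2), w[1] / std::sqrt(r2),
                        w[2] / std::sqrt(r2)};
      int nseg = std::max(1, (int)std::ceil(L / step));
      double h = L / nseg, cum = 0.0;
      double mn[3] = {-1, -1, -1}, mx[3] = {-1, -1, -1};
      int qlo = 0, qhi = nseg;
      clip_ray(V, src, dirn, L, h, nseg, qlo, qhi);
      // nearest-voxel sampling with incremental voxel-space stepping: one
      // lookup yields both the gray value (cumulative depth) and the label
      double t0q = (qlo + 0.5) * h;
      double vx = (src[0] + t0q * dirn[0] - V.ox) / V.sx;
      double vy = (src[1] + t0q * dirn[1] - V.oy) / V.sy;
      double vz = (src[2] + t0q * dirn[2] - V.oz) / V.sz;
      double dvx = dirn[0] * h / V.sx, dvy = dirn[1] * h / V.sy,
             dvz = dirn[2] * h / V.sz;
      double hk = h / 1000.0;
      for (int qq = qlo; qq < qhi; ++qq, vx += dvx, vy += dvy, vz += dvz) {
        int i = (int)(vx + 0.5), j = (int)(vy + 0.5), k = (int)(vz + 0.5);
        if (vx < -0.5 || vy < -0.5 || vz < -0.5 ||
            i >= V.nx || j >= V.ny || k >= V.nz) continue;
        size_t idx = i + (size_t)V.nx * (j + (size_t)V.ny * k);
        double g = V.v[idx];
        if (g > 0) cum += g * hk;
        int lv = lab[idx];
        if (lv > 0 && lv <= 3) {
          int s = lv - 1;
          if (mn[s] < 0) mn[s] = cum;
          mx[s] = cum;
        }
      }
      for (int s = 0; s < 3; ++s) {
        if (mn[s] >= 0) {
          out[px + HW * (1 + 2 * s)] = mn[s];
          out[px + HW * (2 + 2 * s)] = mx[s];
        }
      }
    }
  }
}

}  // namespace

// Channels (layout of an R array dim c(H, H, 7)):
//   [,,1] binary aperture, [,,2:3] PTV min/max radiological depth,
//   [,,4:5] rectum min/max, [,,6:7] bladder min/max; 0 where not hit.
// labels: 0 none, 1 PTV, 2 rectum, 3 bladder (same lattice as vol).
// Returns a (H*H*7) x nbeams matrix, one feature image per column.
// [[Rcpp::export(name = ".beam_features_cpp")]]
NumericMatrix beam_features_cpp(NumericVector vol, IntegerVector labels,
                                IntegerVector dim, NumericVector spacing,
                                NumericVector origin, NumericMatrix src,
                                NumericMatrix tgt, NumericVector diam,
                                NumericVector centre, int H, double pixel_mm,
                                double step = 1.0, double sad = 800.0,
                                double overshoot = 120.0) {
  Vol V = make_vol(vol, dim, spacing, origin);
  const int *lab = INTEGER(labels);
  int nb = src.nrow();
  NumericMatrix out((size_t)H * H * 7, nb);
  for (int b = 0; b < nb; ++b) {
    double s0[3] = {src(b, 0), src(b, 1), src(b, 2)};
    double t0[3] = {tgt(b, 0), tgt(b, 1), tgt(b, 2)};
    features_one(V, lab, s0, t0, diam[b], centre.begin(), H, pixel_mm, step,
                 sad, overshoot, &out(0, b));
  }
  return out;
}

// Minimum distance from every voxel to the set of PTV voxel centres, up to
// maxdist; computed by stamping spherical neighbourhoods. Inf beyond maxdist.
// ptv_idx: n x 3 matrix of 0-based voxel indices.
// [[Rcpp::export(name = ".ptv_distance_cpp")]]
NumericVector ptv_distance_cpp(IntegerMatrix ptv_idx, IntegerVector dim,
                               NumericVector spacing, double maxdist) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  NumericVector out(N, R_PosInf);
  double *o = REAL(out);
  int ri = (int)std::floor(maxdist / spacing[0]);
  int rj = (int)std::floor(maxdist / spacing[1]);
  int rk = (int)std::floor(maxdist / spacing[2]);
  std::vector<int> di, dj, dk;
  std::vector<double> dd;
  for (int a = -ri; a <= ri; ++a)
    for (int b = -rj; b <= rj; ++b)
      for (int c = -rk; c <= rk; ++c) {
        double d = std::sqrt(a * spacing[0] * a * spacing[0] +
                             b * spacing[1] * b * spacing[1] +
                             c * spacing[2] * c * spacing[2]);
        if (d <= maxdist) { di.push_back(a); dj.push_back(b); dk.push_back(c);
                            dd.push_back(d); }
      }
  int n = ptv_idx.nrow(), noff = di.size();
  for (int p = 0; p < n; ++p) {
    int i0 = ptv_idx(p, 0), j0 = ptv_idx(p, 1), k0 = ptv_idx(p, 2);
    for (int q = 0; q < noff; ++q) {
      int i = i0 + di[q], j = j0 + dj[q], k = k0 + dk[q];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
      if (dd[q] < o[idx]) o[idx] = dd[q];
    }
  }
  return out;
}

// 6-connected flood fill of sub-threshold (air) voxels reachable from the
// volume boundary; distinguishes outside air from enclosed gas cavities.
// [[Rcpp::export(name = ".outside_air_cpp")]]
LogicalVector outside_air_cpp(NumericVector vol, IntegerVector dim,
                              double threshold = 500.0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t N = (size_t)nx * ny * nz;
  std::vector<char> out(N, 0);
  const double *v = REAL(vol);
  std::vector<size_t> stack;
  auto push = [&](int i, int j, int k) {
    size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
    if (!out[idx] && v[idx] < threshold) {
      out[idx] = 1;
      stack.push_back(idx);
    }
  };
  for (int j = 0; j < ny; ++j)
    for (int k = 0; k < nz; ++k) { push(0, j, k); push(nx - 1, j, k); }
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) { push(i, 0, k); push(i, ny - 1, k); }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) { push(i, j, 0); push(i, j, nz - 1); }
  while (!stack.empty()) {
    size_t idx = stack.back();
    stack.pop_back();
    int i = idx % nx, j = (idx / nx) % ny, k = idx / ((size_t)nx * ny);
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  LogicalVector res(N);
  for (size_t q = 0; q < N; ++q) res[q] = out[q] != 0;
  res.attr("dim") = dim;
  return res;
}
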