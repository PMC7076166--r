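// Monte-Carlo random-walk core: fixed-step diffusion with specular
// reflection against parallel-cylinder and triangle-mesh barriers, periodic
// boundaries for cylinder voxels, and PGSE phase accumulation.
//
// Determinism: one counter-seeded xoshiro256++ stream per particle, single
// threaded; results are bitwise reproducible for a fixed seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master * 0x9E3779B97F4A7C15ULL ^
                 (stream + 1) * 0xD1B54A32D192ED03ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {   // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  // uniform direction on the unit sphere (Marsaglia)
  inline void sphere(double &x, double &y, double &z) {
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = 2.0 * std::sqrt(1.0 - s2);
    x = u * f; y = v * f; z = 1.0 - 2.0 * s2;
  }
};

// ---------------------------------------------------------------------------
// 2D circle grid (parallel cylinders, optional periodic images)

struct CircleGrid {
  std::vector<double> cx, cy, r;
  std::vector<int> id;            // original cylinder index per (image) entry
  double x0, y0, h;
  int nx, ny;
  std::vector< std::vector<int> > cells;

  void build(const NumericMatrix &centers, const NumericVector &radii,
             double side, bool periodic, double margin) {
    int n = centers.nrow();
    double rmax = 0.0;
    for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)radii[i]);
    double lo = -margin, hi = side + margin;
    for (int i = 0; i < n; ++i) {
      for (int ox = -1; ox <= 1; ++ox) for (int oy = -1; oy <= 1; ++oy) {
        if (!periodic && (ox || oy)) continue;
        double x = centers(i, 0) + ox * side, y = centers(i, 1) + oy * side;
        if (x + radii[i] < lo || x - radii[i] > hi ||
            y + radii[i] < lo || y - radii[i] > hi) continue;
        cx.push_back(x); cy.push_back(y); r.push_back(radii[i]);
        id.push_back(i);
      }
    }
    x0 = lo; y0 = lo;
    double ext = hi - lo;
    h = std::max(2.0 * rmax, ext / 128.0);
    nx = std::max(1, (int)std::ceil(ext / h));
    ny = nx;
    cells.assign((size_t)nx * ny, {});
    for (size_t k = 0; k < cx.size(); ++k) {
      int ix0 = cell_of(cx[k] - r[k], x0), ix1 = cell_of(cx[k] + r[k], x0);
      int iy0 = cell_of(cy[k] - r[k], y0), iy1 = cell_of(cy[k] + r[k], y0);
      for (int ix = ix0; ix <= ix1; ++ix)
        for (int iy = iy0; iy <= iy1; ++iy)
          cells[(size_t)iy * nx + ix].push_back((int)k);
    }
  }
  inline int cell_of(double v, double o) const {
    int c = (int)std::floor((v - o) / h);
    return std::min(std::max(c, 0), nx - 1);
  }
  // iterate candidates for a segment bbox via callback
  template <class F>
  inline void query(double ax, double ay, double bx, double by, F f) const {
    int ix0 = cell_of(std::min(ax, bx), x0), ix1 = cell_of(std::max(ax, bx), x0);
    int iy0 = cell_of(std::min(ay, by), y0), iy1 = cell_of(std::max(ay, by), y0);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int k : cells[(size_t)iy * nx + ix]) f(k);
  }
};

// earliest intersection of segment p + t*v, t in (tmin, 1], with circle k.
// from_inside: take the far root (exit through the wall from inside).
static inline bool hit_circle(double px, double py, double vx, double vy,
                              double ccx, double ccy, double cr,
                              bool from_inside, double tmin, double &t) {
  double a = vx * vx + vy * vy;
  if (a <= 0.0) return false;
  double dx = px - ccx, dy = py - ccy;
  double b = 2.0 * (dx * vx + dy * vy);
  double c = dx * dx + dy * dy - cr * cr;
  double disc = b * b - 4.0 * a * c;
  if (disc < 0.0) return false;
  double sq = std::sqrt(disc);
  double cand = from_inside ? (-b + sq) / (2.0 * a) : (-b - sq) / (2.0 * a);
  if (cand > tmin && cand <= 1.0) { t = cand; return true; }
  return false;
}

// ---------------------------------------------------------------------------
// Triangle mesh with 3D uniform grid

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

struct MeshGrid {
  std::vector<Vec3> V;
  std::vector<int> F;              // 3 per face, 0-based
  double lo[3], hi[3], h[3];
  int n[3];
  std::vector< std::vector<int> > cells;
  mutable std::vector<int> stamp;
  mutable int stampval = 0;

  void build(const NumericMatrix &verts, const IntegerMatrix &faces) {
    int nv = verts.nrow(), nf = faces.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = {verts(i,0), verts(i,1), verts(i,2)};
    F.resize((size_t)nf * 3);
    for (int i = 0; i < nf; ++i)
      for (int j = 0; j < 3; ++j) F[(size_t)i*3+j] = faces(i, j) - 1;
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (auto &v : V) {
      lo[0] = std::min(lo[0], v.x); hi[0] = std::max(hi[0], v.x);
      lo[1] = std::min(lo[1], v.y); hi[1] = std::max(hi[1], v.y);
      lo[2] = std::min(lo[2], v.z); hi[2] = std::max(hi[2], v.z);
    }
    for (int d = 0; d < 3; ++d) {
      double pad = 1e-9 + 1e-6 * (hi[d] - lo[d]);
      lo[d] -= pad; hi[d] += pad;
    }
    double vol = (hi[0]-lo[0]) * (hi[1]-lo[1]) * (hi[2]-lo[2]);
    double hc = std::cbrt(vol / std::max(nf, 1)) * 2.0;
    for (int d = 0; d < 3; ++d) {
      n[d] = std::max(1, std::min(256, (int)std::ceil((hi[d]-lo[d]) / hc)));
      h[d] = (hi[d] - lo[d]) / n[d];
    }
    cells.assign((size_t)n[0] * n[1] * n[2], {});
    for (int i = 0; i < nf; ++i) {
      double blo[3] = {R_PosInf, R_PosInf, R_PosInf};
      double bhi[3] = {R_NegInf, R_NegInf, R_NegInf};
      for (int j = 0; j < 3; ++j) {
        const Vec3 &v = V[F[(size_t)i*3+j]];
        double c[3] = {v.x, v.y, v.z};
        for (int d = 0; d < 3; ++d) {
          blo[d] = std::min(blo[d], c[d]); bhi[d] = std::max(bhi[d], c[d]);
        }
      }
      int c0[3], c1[3];
      for (int d = 0; d < 3; ++d) {
        c0[d] = cell_of(blo[d], d); c1[d] = cell_of(bhi[d], d);
      }
      for (int ix = c0[0]; ix <= c1[0]; ++ix)
        for (int iy = c0[1]; iy <= c1[1]; ++iy)
          for (int iz = c0[2]; iz <= c1[2]; ++iz)
            cells[idx(ix, iy, iz)].push_back(i);
    }
    stamp.assign(nf, -1);
  }
  inline int cell_of(double v, int d) const {
    int c = (int)std::floor((v - lo[d]) / h[d]);
    return std::min(std::max(c, 0), n[d] - 1);
  }
  inline size_t idx(int ix, int iy, int iz) const {
    return ((size_t)iz * n[1] + iy) * n[0] + ix;
  }

  // Moller-Trumbore; dir unnormalized, returns t in segment units
  inline bool ray_tri(const Vec3 &o, const Vec3 &dir, int f,
                      double tmin, double tmax, double &t, Vec3 &nrm) const {
    const Vec3 &v0 = V[F[(size_t)f*3]];
    const Vec3 &v1 = V[F[(size_t)f*3+1]];
    const Vec3 &v2 = V[F[(size_t)f*3+2]];
    Vec3 e1 = vsub(v1, v0), e2 = vsub(v2, v0);
    Vec3 p = vcross(dir, e2);
    double det = vdot(e1, p);
    if (std::fabs(det) < 1e-300) return false;
    double inv = 1.0 / det;
    Vec3 tv = vsub(o, v0);
    double u = vdot(tv, p) * inv;
    if (u < -1e-12 || u > 1.0 + 1e-12) return false;
    Vec3 q = vcross(tv, e1);
    double v = vdot(dir, q) * inv;
    if (v < -1e-12 || u + v > 1.0 + 1e-12) return false;
    double tc = vdot(e2, q) * inv;
    if (tc <= tmin || tc > tmax) return false;
    t = tc;
    nrm = vcross(e1, e2);
    double l = std::sqrt(vdot(nrm, nrm));
    nrm = {nrm.x / l, nrm.y / l, nrm.z / l};
    return true;
  }

  // earliest hit of segment o -> o + v over grid cells covering its bbox
  bool segment_hit(const Vec3 &o, const Vec3 &v, double tmin,
                   double &t, Vec3 &nrm) const {
    double ax = o.x, bx = o.x + v.x, ay = o.y, by = o.y + v.y,
           az = o.z, bz = o.z + v.z;
    int c0[3] = {cell_of(std::min(ax,bx),0), cell_of(std::min(ay,by),1),
                 cell_of(std::min(az,bz),2)};
    int c1[3] = {cell_of(std::max(ax,bx),0), cell_of(std::max(ay,by),1),
                 cell_of(std::max(az,bz),2)};
    double best = R_PosInf; Vec3 bn{0,0,0};
    ++stampval;
    for (int ix = c0[0]; ix <= c1[0]; ++ix)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int iz = c0[2]; iz <= c1[2]; ++iz)
          for (int f : cells[idx(ix, iy, iz)]) {
            if (stamp[f] == stampval) continue;
            stamp[f] = stampval;
            double tf; Vec3 nf_;
            if (ray_tri(o, v, f, tmin, std::min(best, 1.0), tf, nf_)) {
              best = tf; bn = nf_;
            }
          }
    if (best <= 1.0) { t = best; nrm = bn; return true; }
    return false;
  }

  // parity of an infinite ray from p: 3D-DDA voxel traversal, triangles
  // deduped by stamp. Ray directions are deliberately tilted off-axis so
  // rays through exact edge/diagonal features have measure zero.
  int ray_parity(const Vec3 &p, const Vec3 &dir) const {
    int c[3] = {cell_of(p.x, 0), cell_of(p.y, 1), cell_of(p.z, 2)};
    double d[3] = {dir.x, dir.y, dir.z};
    double pc[3] = {p.x, p.y, p.z};
    double tMax[3], tDelta[3];
    int stepc[3];
    for (int k = 0; k < 3; ++k) {
      if (d[k] > 0) {
        stepc[k] = 1;
        tMax[k] = (lo[k] + (c[k] + 1) * h[k] - pc[k]) / d[k];
        tDelta[k] = h[k] / d[k];
      } else if (d[k] < 0) {
        stepc[k] = -1;
        tMax[k] = (lo[k] + c[k] * h[k] - pc[k]) / d[k];
        tDelta[k] = -h[k] / d[k];
      } else {
        stepc[k] = 0;
        tMax[k] = R_PosInf;
        tDelta[k] = R_PosInf;
      }
    }
    int count = 0;
    ++stampval;
    while (c[0] >= 0 && c[0] < n[0] && c[1] >= 0 && c[1] < n[1] &&
           c[2] >= 0 && c[2] < n[2]) {
      for (int f : cells[idx(c[0], c[1], c[2])]) {
        if (stamp[f] == stampval) continue;
        stamp[f] = stampval;
        double t; Vec3 nrm;
        if (ray_tri(p, dir, f, 1e-14, R_PosInf, t, nrm)) ++count;
      }
      int k = (tMax[0] < tMax[1])
                ? (tMax[0] < tMax[2] ? 0 : 2)
                : (tMax[1] < tMax[2] ? 1 : 2);
      c[k] += stepc[k];
      tMax[k] += tDelta[k];
    }
    return count & 1;
  }
  bool inside(const Vec3 &p) const {
    // three skew rays, majority vote (robust at triangle edges)
    const Vec3 d1{0.9130918283233424, 0.3057631954749519, 0.2690907040874279};
    const Vec3 d2{0.2871226655296943, 0.9139482173382074, 0.2867102289398209};
    const Vec3 d3{0.2609913048171814, 0.3082117052787391, 0.9148011159548694};
    int votes = ray_parity(p, d1) + ray_parity(p, d2) + ray_parity(p, d3);
    return votes >= 2;
  }
};

// ---------------------------------------------------------------------------
// walker advance with specular reflection

// cylinders: returns bounce count used, or -1 on overflow (position reverted)
static int advance_cylinders(double p[3], double up[3],
                             const CircleGrid &grid, double side, bool periodic,
                             int label, // >=0: intra (own circle), -1: extra
                             double vx, double vy, double vz,
                             int max_bounces) {
  double sp[3] = {p[0], p[1], p[2]};
  double sup[3] = {up[0], up[1], up[2]};
  int bounces = 0;
  double tmin = 0.0;  // surface nudging handles re-intersection
  while (true) {
    double bt = R_PosInf; int bk = -1;
    if (label >= 0) {
      // intra: only the walls of the owning circle can be hit (from inside)
      grid.query(p[0], p[1], p[0] + vx, p[1] + vy, [&](int k) {
        if (grid.id[k] != label) return;
        double t;
        if (hit_circle(p[0], p[1], vx, vy, grid.cx[k], grid.cy[k], grid.r[k],
                       true, tmin, t) && t < bt) { bt = t; bk = k; }
      });
    } else {
      grid.query(p[0], p[1], p[0] + vx, p[1] + vy, [&](int k) {
        double t;
        if (hit_circle(p[0], p[1], vx, vy, grid.cx[k], grid.cy[k], grid.r[k],
                       false, tmin, t) && t < bt) { bt = t; bk = k; }
      });
    }
    if (bk < 0) {
      p[0] += vx; p[1] += vy; p[2] += vz;
      up[0] += vx; up[1] += vy; up[2] += vz;
      break;
    }
    if (++bounces > max_bounces) {
      for (int d = 0; d < 3; ++d) { p[d] = sp[d]; up[d] = sup[d]; }
      return -1;
    }
    // move to the wall
    p[0] += bt * vx; p[1] += bt * vy; p[2] += bt * vz;
    up[0] += bt * vx; up[1] += bt * vy; up[2] += bt * vz;
    double nx_ = (p[0] - grid.cx[bk]) / grid.r[bk];
    double ny_ = (p[1] - grid.cy[bk]) / grid.r[bk];
    double nl = std::sqrt(nx_ * nx_ + ny_ * ny_);
    nx_ /= nl; ny_ /= nl;
    // remaining step, reflected about the (xy) surface normal
    double rx = (1.0 - bt) * vx, ry = (1.0 - bt) * vy, rz = (1.0 - bt) * vz;
    double dn = rx * nx_ + ry * ny_;
    rx -= 2.0 * dn * nx_; ry -= 2.0 * dn * ny_;
    // nudge off the surface on the side the walker belongs to
    double push = (label >= 0) ? -1e-12 : 1e-12;
    p[0] += push * nx_; p[1] += push * ny_;
    up[0] += push * nx_; up[1] += push * ny_;
    vx = rx; vy = ry; vz = rz;
  }
  if (periodic && label < 0) {
    for (int d = 0; d < 2; ++d) {
      if (p[d] < 0)      p[d] += side * std::ceil(-p[d] / side);
      else if (p[d] >= side) p[d] -= side * std::floor(p[d] / side);
    }
  }
  return bounces;
}

// mesh (+ optional reflective box walls for 'all'/extra modes)
static int advance_mesh(double p[3], double up[3], const MeshGrid &mesh,
                        bool box_walls,
                        double vx, double vy, double vz, int max_bounces) {
  double sp[3] = {p[0], p[1], p[2]};
  double sup[3] = {up[0], up[1], up[2]};
  int bounces = 0;
  while (true) {
    Vec3 o{p[0], p[1], p[2]}, v{vx, vy, vz};
    double t; Vec3 nrm;
    bool hit = mesh.segment_hit(o, v, 0.0, t, nrm);
    // box walls (treated as additional planes)
    if (box_walls) {
      double co[3] = {o.x, o.y, o.z}, cv[3] = {v.x, v.y, v.z};
      for (int d = 0; d < 3; ++d) {
        if (cv[d] == 0.0) continue;
        for (int sgn = 0; sgn < 2; ++sgn) {
          double wall = sgn ? mesh.hi[d] : mesh.lo[d];
          double tw = (wall - co[d]) / cv[d];
          if (tw > 0.0 && tw <= 1.0 && (!hit || tw < t)) {
            hit = true; t = tw;
            nrm = {0, 0, 0};
            if (d == 0) nrm.x = 1; else if (d == 1) nrm.y = 1; else nrm.z = 1;
          }
        }
      }
    }
    if (!hit) {
      p[0] += vx; p[1] += vy; p[2] += vz;
      up[0] += vx; up[1] += vy; up[2] += vz;
      return bounces;
    }
    if (++bounces > max_bounces) {
      for (int d = 0; d < 3; ++d) { p[d] = sp[d]; up[d] = sup[d]; }
      return -1;
    }
    p[0] += t * vx; p[1] += t * vy; p[2] += t * vz;
    up[0] += t * vx; up[1] += t * vy; up[2] += t * vz;
    double rx = (1.0 - t) * vx, ry = (1.0 - t) * vy, rz = (1.0 - t) * vz;
    double dn = rx * nrm.x + ry * nrm.y + rz * nrm.z;
    rx -= 2.0 * dn * nrm.x; ry -= 2.0 * dn * nrm.y; rz -= 2.0 * dn * nrm.z;
    // push back to the incoming side
    double side_ = (vx * nrm.x + vy * nrm.y + vz * nrm.z) > 0 ? -1.0 : 1.0;
    p[0] += side_ * 1e-12 * nrm.x;
    p[1] += side_ * 1e-12 * nrm.y;
    p[2] += side_ * 1e-12 * nrm.z;
    up[0] += side_ * 1e-12 * nrm.x;
    up[1] += side_ * 1e-12 * nrm.y;
    up[2] += side_ * 1e-12 * nrm.z;
    vx = rx; vy = ry; vz = rz;
  }
}

// ---------------------------------------------------------------------------
// per-shell, per-step gradient weights: exact overlap of each step interval
// with the two pulse windows (sign +1 first pulse, -1 second). Sums to zero
// over the echo, so a static spin refocuses to machine precision.

static std::vector<double> shell_weights(double delta, double Delta,
                                         double TE, int Nt) {
  double dt = TE / Nt;
  double t1 = (TE - Delta - delta) / 2.0;
  std::vector<double> w(Nt);
  auto overlap = [](double a0, double a1, double b0, double b1) {
    return std::max(0.0, std::min(a1, b1) - std::max(a0, b0));
  };
  for (int k = 0; k < Nt; ++k) {
    double a0 = k * dt, a1 = (k + 1) * dt;
    w[k] = overlap(a0, a1, t1, t1 + delta) -
           overlap(a0, a1, t1 + Delta, t1 + Delta + delta);
  }
  return w;
}

// [[Rcpp::export]]
NumericVector cpp_shell_weights(double delta, double Delta, double TE, int Nt) {
  std::vector<double> w = shell_weights(delta, Delta, TE, Nt);
  return NumericVector(w.begin(), w.end());
}

// ---------------------------------------------------------------------------
// main simulation entry

// [[Rcpp::export]]
List cpp_run_simulation(int substrate_type, List substrate,
                        NumericMatrix dirs, IntegerVector shell_id,
                        NumericMatrix shells, double TE,
                        double D, int Ns, int Nt, double gamma,
                        int init_mode, double seed, int max_bounces,
                        bool return_positions, bool return_msd) {
  const int n_meas = dirs.nrow();
  const int n_shells = shells.nrow();
  const double dt = TE / Nt;
  const double step_len = std::sqrt(6.0 * D * dt);

  // substrate setup
  CircleGrid cgrid;
  MeshGrid mgrid;
  double side = 0.0;
  bool periodic = false;
  double box_lo[3] = {0, 0, 0}, box_hi[3] = {0, 0, 0};
  NumericMatrix centers;
  NumericVector radii;
  if (substrate_type == 1) {
    centers = as<NumericMatrix>(substrate["centers"]);
    radii = as<NumericVector>(substrate["radii"]);
    side = as<double>(substrate["voxel_side"]);
    periodic = as<bool>(substrate["periodic"]);
    double rmax = 0.0;
    for (int i = 0; i < radii.size(); ++i) rmax = std::max(rmax, (double)radii[i]);
    cgrid.build(centers, radii, side, periodic,
                rmax + 4.0 * step_len + 1e-9);
    for (int d = 0; d < 3; ++d) { box_lo[d] = 0; box_hi[d] = side; }
  } else if (substrate_type == 2) {
    mgrid.build(as<NumericMatrix>(substrate["vertices"]),
                as<IntegerMatrix>(substrate["faces"]));
    for (int d = 0; d < 3; ++d) { box_lo[d] = mgrid.lo[d]; box_hi[d] = mgrid.hi[d]; }
  } else {
    for (int d = 0; d < 3; ++d) { box_lo[d] = 0; box_hi[d] = 1e-6; }
  }

  // gradient weights per shell/step
  std::vector< std::vector<double> > W(n_shells);
  for (int s = 0; s < n_shells; ++s)
    W[s] = shell_weights(shells(s, 1), shells(s, 2), TE, Nt);
  // steps where any shell has weight (gradient-on sparsity)
  std::vector< std::vector<int> > active(n_shells);
  for (int s = 0; s < n_shells; ++s)
    for (int k = 0; k < Nt; ++k)
      if (W[s][k] != 0.0) active[s].push_back(k);

  // phase accumulators
  std::vector<double> sum_re(3 * n_meas, 0.0), sum_im(3 * n_meas, 0.0);
  long long n_comp[3] = {0, 0, 0};   // total, intra, extra counts
  std::vector<double> acc(3 * n_shells);

  // msd checkpoints
  const int n_check = return_msd ? std::min(10, Nt) : 0;
  std::vector<int> check_steps(n_check);
  std::vector<double> msd(n_check, 0.0);
  for (int c = 0; c < n_check; ++c)
    check_steps[c] = (int)std::round((double)(c + 1) * Nt / n_check);

  NumericMatrix init_pos(return_positions ? Ns : 0, 3);
  IntegerVector labels_out(return_positions ? Ns : 0);

  long long bounce_overflows = 0;
  double max_penetration = R_NegInf;
  uint64_t master = (uint64_t)seed;
  Xoshiro rng;

  for (int i = 0; i < Ns; ++i) {
    rng.seed(master, (uint64_t)i);
    // --- initialization ------------------------------------------------
    double p[3];
    int label = -1;                 // -1 extra, >=0 intra compartment id
    bool ok = false;
    for (int trial = 0; trial < 100000 && !ok; ++trial) {
      for (int d = 0; d < 3; ++d)
        p[d] = box_lo[d] + (box_hi[d] - box_lo[d]) * rng.unif();
      if (substrate_type == 1) {
        label = -1;
        double best = R_PosInf;
        cgrid.query(p[0], p[1], p[0], p[1], [&](int k) {
          double dx = p[0] - cgrid.cx[k], dy = p[1] - cgrid.cy[k];
          double d2 = dx * dx + dy * dy;
          if (d2 < cgrid.r[k] * cgrid.r[k] && d2 < best) {
            best = d2; label = cgrid.id[k];
          }
        });
      } else if (substrate_type == 2) {
        label = mgrid.inside({p[0], p[1], p[2]}) ? 0 : -1;
      } else label = -1;
      ok = (init_mode == 0) || (init_mode == 1 && label >= 0) ||
           (init_mode == 2 && label < 0);
    }
    if (!ok) stop("initialization failed: requested compartment appears to have zero volume");
    if (return_positions) {
      init_pos(i, 0) = p[0]; init_pos(i, 1) = p[1]; init_pos(i, 2) = p[2];
      labels_out[i] = label;
    }
    int comp = (label >= 0) ? 1 : 2;
    ++n_comp[0]; ++n_comp[comp];

    // intra cylinder walkers collide only with their own circle: track its
    // center/radius directly (periodic images share the id)
    double up[3] = {0.0, 0.0, 0.0};   // unwrapped displacement from start
    std::fill(acc.begin(), acc.end(), 0.0);
    std::vector<int> next_active(n_shells, 0);

    // --- random walk ----------------------------------------------------
    for (int k = 0; k < Nt; ++k) {
      if (D > 0.0) {
        double sx, sy, sz;
        rng.sphere(sx, sy, sz);
        int b;
        if (substrate_type == 1) {
          b = advance_cylinders(p, up, cgrid, side, periodic, label,
                                step_len * sx, step_len * sy, step_len * sz,
                                max_bounces);
        } else if (substrate_type == 2) {
          b = advance_mesh(p, up, mgrid, init_mode != 1 || label < 0,
                           step_len * sx, step_len * sy, step_len * sz,
                           max_bounces);
        } else {
          p[0] += step_len * sx; p[1] += step_len * sy; p[2] += step_len * sz;
          up[0] += step_len * sx; up[1] += step_len * sy; up[2] += step_len * sz;
          b = 0;
        }
        if (b < 0) ++bounce_overflows;
      }
      // phase accumulation: acc_s += w_k * x(t_k), end-of-step displacement
      for (int s = 0; s < n_shells; ++s) {
        int &na = next_active[s];
        if (na < (int)active[s].size() && active[s][na] == k) {
          double w = W[s][k];
          acc[3 * s] += w * up[0];
          acc[3 * s + 1] += w * up[1];
          acc[3 * s + 2] += w * up[2];
          ++na;
        }
      }
      if (return_msd) {
        for (int c = 0; c < n_check; ++c)
          if (check_steps[c] == k + 1)
            msd[c] += up[0] * up[0] + up[1] * up[1] + up[2] * up[2];
      }
    }
    if (substrate_type == 1 && label >= 0) {
      // containment diagnostic: distance to own axis minus radius
      double dx = p[0] - centers(label, 0), dy = p[1] - centers(label, 1);
      max_penetration = std::max(max_penetration,
        std::sqrt(dx * dx + dy * dy) - (double)radii[label]);
    }

    // --- per-measurement phase ------------------------------------------
    for (int m = 0; m < n_meas; ++m) {
      int s = shell_id[m] - 1;
      double G = shells(s, 0);
      double phi = gamma * G * (dirs(m, 0) * acc[3 * s] +
                                dirs(m, 1) * acc[3 * s + 1] +
                                dirs(m, 2) * acc[3 * s + 2]);
      if (!std::isfinite(phi)) stop("NaN/Inf phase encountered");
      double cr = std::cos(phi), ci = -std::sin(phi);
      sum_re[m] += cr; sum_im[m] += ci;
      sum_re[comp * n_meas + m] += cr; sum_im[comp * n_meas + m] += ci;
    }
  }

  NumericVector sig(n_meas), sig_in(n_meas), sig_ex(n_meas);
  for (int m = 0; m < n_meas; ++m) {
    sig[m] = std::sqrt(sum_re[m] * sum_re[m] + sum_im[m] * sum_im[m]) / n_comp[0];
    sig_in[m] = n_comp[1] ? std::sqrt(sum_re[n_meas + m] * sum_re[n_meas + m] +
                                      sum_im[n_meas + m] * sum_im[n_meas + m]) / n_comp[1]
                          : NA_REAL;
    sig_ex[m] = n_comp[2] ? std::sqrt(sum_re[2 * n_meas + m] * sum_re[2 * n_meas + m] +
                                      sum_im[2 * n_meas + m] * sum_im[2 * n_meas + m]) / n_comp[2]
                          : NA_REAL;
  }
  // label-weighted complex mixture equals the total by construction; expose
  // the compartment complex means so tests can assert it exactly
  NumericMatrix cmean_re(n_meas, 3), cmean_im(n_meas, 3);
  for (int m = 0; m < n_meas; ++m)
    for (int c = 0; c < 3; ++c) {
      double denom = n_comp[c] ? (double)n_comp[c] : NA_REAL;
      cmean_re(m, c) = sum_re[c * n_meas + m] / denom;
      cmean_im(m, c) = sum_im[c * n_meas + m] / denom;
    }
  List out = List::create(
    _["signal"] = sig, _["signal_intra"] = sig_in, _["signal_extra"] = sig_ex,
    _["n_intra"] = (double)n_comp[1], _["n_extra"] = (double)n_comp[2],
    _["bounce_overflows"] = (double)bounce_overflows,
    _["max_penetration"] = max_penetration,
    _["step_length"] = step_len,
    _["complex_re"] = cmean_re, _["complex_im"] = cmean_im);
  if (return_msd) {
    NumericVector mv(n_check), tv(n_check);
    for (int c = 0; c < n_check; ++c) {
      mv[c] = msd[c] / Ns;
      tv[c] = check_steps[c] * dt;
    }
    out["msd"] = mv; out["msd_times"] = tv;
  }
  if (return_positions) {
    out["init_positions"] = init_pos;
    out["labels"] = labels_out;
  }
  return out;
}

// ---------------------------------------------------------------------------
// small exported helpers for tests and R-level operations

// [[Rcpp::export]]
IntegerVector cpp_points_in_cylinders(NumericMatrix centers, NumericVector radii,
                                      double side, bool periodic,
                                      NumericMatrix pts) {
  CircleGrid g;
  g.build(centers, radii, side, periodic, 1e-9);
  IntegerVector lab(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    int best = -1; double bd = R_PosInf;
    double x = pts(i, 0), y = pts(i, 1);
    g.query(x, y, x, y, [&](int k) {
      double dx = x - g.cx[k], dy = y - g.cy[k];
      double d2 = dx * dx + dy * dy;
      if (d2 < g.r[k] * g.r[k] && d2 < bd) { bd = d2; best = g.id[k]; }
    });
    lab[i] = best;
  }
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix verts, IntegerMatrix faces,
                                 NumericMatrix pts) {
  MeshGrid g;
  g.build(verts, faces);
  LogicalVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = g.inside({pts(i, 0), pts(i, 1), pts(i, 2)});
  return out;
}

// one-step advance against a cylinder population (unit-test surface)
// [[Rcpp::export]]
List cpp_advance_cylinders_once(NumericVector pos, NumericVector step,
                                NumericMatrix centers, NumericVector radii,
                                double side, bool periodic, int label,
                                int max_bounces) {
  CircleGrid g;
  double rmax = 0.0, sl = std::sqrt(step[0]*step[0] + step[1]*step[1] + step[2]*step[2]);
  for (int i = 0; i < radii.size(); ++i) rmax = std::max(rmax, (double)radii[i]);
  g.build(centers, radii, side, periodic, rmax + 4.0 * sl + 1e-9);
  double p[3] = {pos[0], pos[1], pos[2]};
  double up[3] = {0, 0, 0};
  int b = advance_cylinders(p, up, g, side, periodic, label,
                            step[0], step[1], step[2], max_bounces);
  return List::create(_["position"] = NumericVector::create(p[0], p[1], p[2]),
                      _["displacement"] = NumericVector::create(up[0], up[1], up[2]),
                      _["bounces"] = b);
}

// one-step advance against a mesh (unit-test surface)
// [[Rcpp::export]]
List cpp_advance_mesh_once(NumericVector pos, NumericVector step,
                           NumericMatrix verts, IntegerMatrix faces,
                           bool box_walls, int max_bounces) {
  MeshGrid g;
  g.build(verts, faces);
  double p[3] = {pos[0], pos[1], pos[2]};
  double up[3] = {0, 0, 0};
  int b = advance_mesh(p, up, g, box_walls, step[0], step[1], step[2],
                       max_bounces);
  return List::create(_["position"] = NumericVector::create(p[0], p[1], p[2]),
                      _["displacement"] = NumericVector::create(up[0], up[1], up[2]),
                      _["bounces"] = b);
}
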