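#ifndef PLASMIDSIM_H
#define PLASMIDSIM_H

#include <cmath>
#include <cfloat>
#include <cstdint>
#include <algorithm>

// Self-contained counter-seeded RNG for the stepping kernel (xoshiro256++
// seeded via splitmix64, Box-Muller normals). Keeps per-repeat substreams
// independent of R's global RNG state and of execution order, and is several
// times faster than drawing through R's inversion sampler in a tight loop.
struct KernelRNG {
  std::uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  static std::uint64_t splitmix(std::uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    std::uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit KernelRNG(std::uint64_t seed) {
    std::uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  std::uint64_t next() {
    std::uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    double u2 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
};

// Composite nuclear geometry: two prolate spheroids (mother at negative x,
// daughter at positive x) tip-to-tip with a cylindrical bridge spanning
// [-bh, bh] on the division axis. The cylinder is extended 1% of bh into
// each spheroid so the union stays connected at the zero-measure junctions.
// All lengths in micrometres.
struct Frame {
  double ma, mb;   // mother semi-long (x) / semi-equatorial axes
  double da, db;   // daughter semi-axes
  double bh, br;   // bridge half-length, radius
  double mcx, dcx; // derived spheroid centres (tip contact)
  double hext;     // extended cylinder half-length
};

inline Frame make_frame(const double *p) {
  Frame f;
  f.ma = p[0]; f.mb = p[1]; f.da = p[2]; f.db = p[3]; f.bh = p[4]; f.br = p[5];
  f.mcx = -(f.bh + f.ma);
  f.dcx =  (f.bh + f.da);
  f.hext = 1.01 * f.bh;
  return f;
}

// Closest point on the ellipse u^2/a^2 + v^2/b^2 = 1 to (u, v) with
// u, v >= 0. Returns the distance; foot point in (fu, fv). Newton/bisection
// hybrid on the standard Lagrange parameter; on-axis points (inside the
// evolute) are handled by the closed-form off-axis foot.
inline double ellipse_closest(double u, double v, double a, double b,
                              double &fu, double &fv) {
  const double ca = 1e-12 * a, cb = 1e-12 * b;
  if (v <= cb) { // on the major (x) axis of the meridional plane
    if (a > b && u < (a * a - b * b) / a) {
      fu = a * a * u / (a * a - b * b);
      double t = 1.0 - fu * fu / (a * a);
      fv = b * std::sqrt(t > 0 ? t : 0.0);
      return std::hypot(u - fu, fv);
    }
    fu = a; fv = 0.0;
    return std::fabs(u - a);
  }
  if (u <= ca) {
    if (b > a && v < (b * b - a * a) / b) {
      fv = b * b * v / (b * b - a * a);
      double t = 1.0 - fv * fv / (b * b);
      fu = a * std::sqrt(t > 0 ? t : 0.0);
      return std::hypot(fu, v - fv);
    }
    fu = 0.0; fv = b;
    return std::fabs(v - b);
  }
  // General case: solve F(t) = (au/(t+a^2))^2 + (bv/(t+b^2))^2 - 1 = 0,
  // root unique in (-min(a,b)^2, inf), F decreasing there.
  const double au = a * u, bv = b * v;
  const double minsq = std::min(a * a, b * b);
  double lo = -minsq, hi;
  {
    // expand lo upward until F(lo) > 0 (it diverges at -minsq)
    double step = 1e-12 * minsq + 1e-300;
    lo = -minsq + step;
    hi = std::max(std::max(au * M_SQRT2 - a * a, bv * M_SQRT2 - b * b), 0.0) + 1.0;
  }
  auto F = [&](double t) {
    double r1 = au / (t + a * a), r2 = bv / (t + b * b);
    return r1 * r1 + r2 * r2 - 1.0;
  };
  while (F(lo) < 0.0) lo = -minsq + (lo + minsq) * 1e-3; // v or u tiny
  double t = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    double r1 = au / (t + a * a), r2 = bv / (t + b * b);
    double f = r1 * r1 + r2 * r2 - 1.0;
    if (std::fabs(f) < 1e-14) break; // converged: keep the evaluated t
    if (f > 0) lo = t; else hi = t;
    if (hi - lo < 1e-15 * (1.0 + std::fabs(t))) { t = 0.5 * (lo + hi); break; }
    double df = -2.0 * (r1 * r1 / (t + a * a) + r2 * r2 / (t + b * b));
    double tn = t - f / df;
    t = (tn > lo && tn < hi) ? tn : 0.5 * (lo + hi);
  }
  fu = a * a * u / (t + a * a);
  fv = b * b * v / (t + b * b);
  return std::hypot(u - fu, v - fv);
}

// Signed clearance of meridional point (u, v), u,v >= 0, w.r.t. the spheroid:
// + distance to surface if inside, - distance if outside.
inline double spheroid_clearance(double u, double v, double a, double b) {
  double fu, fv;
  double d = ellipse_closest(u, v, a, b, fu, fv);
  double q = (u / a) * (u / a) + (v / b) * (v / b);
  return q <= 1.0 ? d : -d;
}

// Signed clearance w.r.t. the (extended) bridge cylinder.
inline double cylinder_clearance(double x, double v, double br, double hext) {
  if (br <= 0.0 || hext <= 0.0) return -DBL_MAX;
  double dx = std::fabs(x) - hext, dv = v - br;
  if (dx <= 0.0 && dv <= 0.0) return std::min(-dx, -dv);
  double ox = dx > 0 ? dx : 0.0, ov = dv > 0 ? dv : 0.0;
  return -std::hypot(ox, ov);
}

inline double frame_clearance(const Frame &f, double x, double y, double z) {
  double v = std::hypot(y, z);
  double c = cylinder_clearance(x, v, f.br, f.hext);
  double cm = spheroid_clearance(std::fabs(x - f.mcx), v, f.ma, f.mb);
  if (cm > c) c = cm;
  double cd = spheroid_clearance(std::fabs(x - f.dcx), v, f.da, f.db);
  if (cd > c) c = cd;
  return c;
}

// Sphere of radius r fits in the spheroid around meridional point (u, v)?
// Cheap gradient bounds avoid the Newton solve away from the r-contour:
// (1 - sqrt(q)) * min(a,b) <= dist-to-surface <= (1 - sqrt(q)) * max(a,b).
inline bool spheroid_fits(double u, double v, double a, double b, double r) {
  double mn = std::min(a, b);
  if (r > mn) return false;
  double s = (u / a) * (u / a) + (v / b) * (v / b);
  if (s > 1.0) return false;
  double margin = 1.0 - std::sqrt(s);
  if (margin * mn >= r) return true;
  if (margin * std::max(a, b) < r) return false;
  double fu, fv;
  return ellipse_closest(u, v, a, b, fu, fv) >= r;
}

inline bool cylinder_fits(double x, double v, double br, double hext, double r) {
  return br > 0.0 && hext > 0.0 && v <= br - r && std::fabs(x) <= hext - r;
}

// A particle of radius r is admitted iff its centre sphere fits entirely
// within at least one primitive (union-of-erosions convention).
inline bool frame_contains(const Frame &f, double x, double y, double z, double r) {
  double v = std::hypot(y, z);
  if (cylinder_fits(x, v, f.br, f.hext, r)) return true;
  if (spheroid_fits(std::fabs(x - f.mcx), v, f.ma, f.mb, r)) return true;
  return spheroid_fits(std::fabs(x - f.dcx), v, f.da, f.db, r);
}

// Projection onto the r-erosion of one spheroid (a convex set), in the
// meridional plane. Foot-normal construction with a scanned fallback where
// the inward normal offset leaves the erosion (offset-curve cusp region near
// high-curvature tips). eps nudges strictly inside so frame_contains holds
// on the result. Returns squared... returns distance, point in (qu, qv).
inline bool spheroid_project(double u, double v, double a, double b, double r,
                             double &qu, double &qv) {
  const double eps = 1e-7; // inward nudge > foot-point solver error, so the
                           // validity check fails only at genuine cusps
  if (r >= std::min(a, b) - eps) return false; // erosion (essentially) empty
  double fu, fv;
  ellipse_closest(u, v, a, b, fu, fv);
  double nx = fu / (a * a), ny = fv / (b * b);
  double nn = std::hypot(nx, ny);
  qu = fu - (r + eps) * nx / nn;
  qv = fv - (r + eps) * ny / nn;
  if (qv < 0) qv = 0;
  if (spheroid_clearance(std::fabs(qu), qv, a, b) >= r) return true;
  // cusp fallback: constrained scan over the ellipse parameter
  double blo = 0.0, bhi = M_PI_2, bestd = DBL_MAX, bphi = -1.0;
  for (int pass = 0; pass < 3; ++pass) {
    int n = pass == 0 ? 128 : 32;
    double nlo = blo, nhi = bhi, bl = blo, bh_ = bhi;
    for (int i = 0; i <= n; ++i) {
      double phi = bl + (bh_ - bl) * i / n;
      double su = a * std::cos(phi), sv = b * std::sin(phi);
      double mx = su / (a * a), my = sv / (b * b), mm = std::hypot(mx, my);
      double cu = su - (r + eps) * mx / mm, cv = sv - (r + eps) * my / mm;
      if (cv < 0) cv = 0;
      if (spheroid_clearance(std::fabs(cu), cv, a, b) < r) continue;
      double d = std::hypot(u - cu, v - cv);
      if (d < bestd) {
        bestd = d; bphi = phi; qu = cu; qv = cv;
        nlo = bl + (bh_ - bl) * (i - 1.0) / n;
        nhi = bl + (bh_ - bl) * (i + 1.0) / n;
      }
    }
    if (bphi < 0) return false;
    blo = std::max(0.0, nlo); bhi = std::min(M_PI_2, nhi);
  }
  return true;
}

// Projection onto the union of the r-eroded primitives. Each eroded
// primitive is convex, so the union projection is the best per-primitive
// candidate. Returns false when no primitive admits radius r.
inline bool frame_project(const Frame &f, double r,
                          double &x, double &y, double &z) {
  const double eps = 1e-9;
  if (frame_contains(f, x, y, z, r)) return true;
  double v = std::hypot(y, z);
  double ey = 1.0, ez = 0.0; // meridional unit vector in the (y,z) plane
  if (v > 0) { ey = y / v; ez = z / v; }
  double bx = 0, bv = 0, bestd = DBL_MAX;
  bool ok = false;
  // bridge cylinder: erosion is a clamp
  if (f.br - r > eps && f.hext - r > eps) {
    double cx = std::min(std::max(x, -(f.hext - r - eps)), f.hext - r - eps);
    double cv = std::min(v, f.br - r - eps);
    double d = std::hypot(x - cx, v - cv);
    if (d < bestd) { bestd = d; bx = cx; bv = cv; ok = true; }
  }
  // spheroids
  for (int s = 0; s < 2; ++s) {
    double cx0 = s == 0 ? f.mcx : f.dcx;
    double a = s == 0 ? f.ma : f.da, b = s == 0 ? f.mb : f.db;
    double u = x - cx0;
    double qu, qv;
    if (spheroid_project(std::fabs(u), v, a, b, r, qu, qv)) {
      double px = cx0 + (u >= 0 ? qu : -qu);
      double d = std::hypot(x - px, v - qv);
      if (d < bestd) { bestd = d; bx = px; bv = qv; ok = true; }
    }
  }
  if (!ok) return false;
  x = bx; y = bv * ey; z = bv * ez;
  return true;
}

#endif
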