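#include <Rcpp.h>
#include "plasmidsim.h"
using namespace Rcpp;

// Frame parameter vectors are length 6: (ma, mb, da, db, bh, br) in um;
// spheroid centres follow from tip contact with the bridge ends.

// [[Rcpp::export]]
NumericVector cpp_clearance(NumericVector frame6, NumericMatrix pts) {
  Frame f = make_frame(frame6.begin());
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = frame_clearance(f, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_contains(NumericVector frame6, NumericMatrix pts, double r) {
  Frame f = make_frame(frame6.begin());
  int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = frame_contains(f, pts(i, 0), pts(i, 1), pts(i, 2), r);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector frame6, NumericMatrix pts, double r) {
  Frame f = make_frame(frame6.begin());
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (!frame_project(f, r, x, y, z))
      stop("no primitive of the geometry admits a particle of radius %f um", r);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}

static void frame_bbox(const Frame &f, double *lo, double *hi) {
  lo[0] = f.mcx - f.ma; hi[0] = f.dcx + f.da;
  double w = std::max(std::max(f.mb, f.db), f.br);
  lo[1] = -w; hi[1] = w; lo[2] = -w; hi[2] = w;
}

// Rejection sampling of particle centres from the axis-aligned bounding box.
// compartment: 0 = anywhere, 1 = mother (x <= 0), 2 = daughter (x > 0).
// [[Rcpp::export]]
NumericMatrix cpp_sample_uniform(NumericVector frame6, int n, double r,
                                 int compartment) {
  Frame f = make_frame(frame6.begin());
  double lo[3], hi[3];
  frame_bbox(f, lo, hi);
  NumericMatrix out(n, 3);
  long tries = 0, kept = 0;
  const long max_tries = std::max(10000L * (long)n, 1000000L);
  while (kept < n) {
    if (++tries > max_tries)
      stop("degenerate geometry: rejection acceptance rate below 1e-4");
    double x = lo[0] + unif_rand() * (hi[0] - lo[0]);
    double y = lo[1] + unif_rand() * (hi[1] - lo[1]);
    double z = lo[2] + unif_rand() * (hi[2] - lo[2]);
    if (!frame_contains(f, x, y, z, r)) continue;
    if (compartment == 1 && x > 0) continue;
    if (compartment == 2 && x <= 0) continue;
    out(kept, 0) = x; out(kept, 1) = y; out(kept, 2) = z;
    ++kept;
  }
  return out;
}

// Monte-Carlo lobe volumes: counts of bounding-box samples falling inside
// the union, split at the bridge midpoint (x <= 0 -> mother). Returns
// (n_mother, n_daughter, bbox_volume).
// [[Rcpp::export]]
NumericVector cpp_mc_lobes(NumericVector frame6, int n) {
  Frame f = make_frame(frame6.begin());
  double lo[3], hi[3];
  frame_bbox(f, lo, hi);
  long nm = 0, nd = 0;
  for (int i = 0; i < n; ++i) {
    double x = lo[0] + unif_rand() * (hi[0] - lo[0]);
    double y = lo[1] + unif_rand() * (hi[1] - lo[1]);
    double z = lo[2] + unif_rand() * (hi[2] - lo[2]);
    if (!frame_contains(f, x, y, z, 0.0)) continue;
    if (x <= 0) ++nm; else ++nd;
  }
  double vol = (hi[0] - lo[0]) * (hi[1] - lo[1]) * (hi[2] - lo[2]);
  return NumericVector::create((double)nm, (double)nd, vol);
}
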