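#include <Rcpp.h>
#include "plasmidsim.h"
using namespace Rcpp;

// Linear interpolation of the six geometric parameters between measured
// frames; spheroid centres are re-derived from tip contact afterwards.
struct SeriesInterp {
  const NumericMatrix &fr; // columns: time, ma, mb, da, db, bh, br
  int k;
  SeriesInterp(const NumericMatrix &m) : fr(m), k(0) {}
  Frame at(double t) {
    int n = fr.nrow();
    while (k < n - 2 && fr(k + 1, 0) < t) ++k;
    while (k > 0 && fr(k, 0) > t) --k;
    double t0 = fr(k, 0), t1 = fr(k + 1, 0);
    double w = (t - t0) / (t1 - t0);
    if (w < 0) w = 0; if (w > 1) w = 1;
    double p[6];
    for (int j = 0; j < 6; ++j)
      p[j] = (1 - w) * fr(k, j + 1) + w * fr(k + 1, j + 1);
    return make_frame(p);
  }
};

// One plasmid through one anaphase. Per step: advance the clock, interpolate
// the geometry and remap the particle if the moving boundary overtook it;
// propagate by independent Gaussian increments (variance 2*D*dt per axis);
// remap to the closest admissible point if the step left the domain.
// Occupancy labels (0 = mother, 1 = daughter, bridge midpoint x = 0 tied to
// mother) are recorded at the first step boundary at/after each record time.
// Each run draws from its own counter-seeded stream, so ensembles are
// order-independent and do not perturb R's global RNG.
// [[Rcpp::export]]
List cpp_simulate_particle(NumericMatrix frames, double D, double r,
                           double dt, NumericVector record_times,
                           int init_compartment, bool record_positions,
                           double seed) {
  KernelRNG rng((std::uint64_t)seed);
  int nrec = record_times.size();
  IntegerVector labels(nrec);
  NumericMatrix pos;
  if (record_positions) pos = NumericMatrix(nrec, 3);
  SeriesInterp interp(frames);
  double t0 = frames(0, 0), tend = frames(frames.nrow() - 1, 0);

  Frame f = interp.at(t0);
  // initial position: uniform over the admissible volume at anaphase onset
  double lo0 = f.mcx - f.ma, hi0 = f.dcx + f.da;
  double w0 = std::max(std::max(f.mb, f.db), f.br);
  double x = 0, y = 0, z = 0;
  long tries = 0;
  for (;;) {
    if (++tries > 1000000L)
      stop("degenerate geometry at t=%g: cannot place particle of radius %g",
           t0, r);
    x = lo0 + rng.unif() * (hi0 - lo0);
    y = -w0 + rng.unif() * 2 * w0;
    z = -w0 + rng.unif() * 2 * w0;
    if (!frame_contains(f, x, y, z, r)) continue;
    if (init_compartment == 1 && x > 0) continue;
    if (init_compartment == 2 && x <= 0) continue;
    break;
  }

  int ri = 0;
  double t = t0;
  auto record_upto = [&](double tnow) {
    while (ri < nrec && record_times[ri] <= tnow + 1e-9) {
      labels[ri] = (x <= 0) ? 0 : 1;
      if (record_positions) { pos(ri, 0) = x; pos(ri, 1) = y; pos(ri, 2) = z; }
      ++ri;
    }
  };
  record_upto(t0);

  while (t < tend - 1e-12) {
    double h = std::min(dt, tend - t);
    t += h;
    Frame fc = interp.at(t);
    if (!frame_contains(fc, x, y, z, r) && !frame_project(fc, r, x, y, z))
      stop("geometry too narrow for particle radius %g at t=%g s", r, t);
    double sd = std::sqrt(2.0 * D * h);
    x += sd * rng.norm();
    y += sd * rng.norm();
    z += sd * rng.norm();
    if (!frame_contains(fc, x, y, z, r) && !frame_project(fc, r, x, y, z))
      stop("geometry too narrow for particle radius %g at t=%g s", r, t);
    record_upto(t);
  }
  // any record times at/after the final frame take the terminal state
  while (ri < nrec) {
    labels[ri] = (x <= 0) ? 0 : 1;
    if (record_positions) { pos(ri, 0) = x; pos(ri, 1) = y; pos(ri, 2) = z; }
    ++ri;
  }
  List out = List::create(_["labels"] = labels,
                          _["final"] = NumericVector::create(x, y, z));
  if (record_positions) out["positions"] = pos;
  return out;
}
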