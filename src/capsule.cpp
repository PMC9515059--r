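// Capsule-vs-beam-cone clearance for beam-blocking decisions.
// A beam is blocked when some capsule comes closer to the beam axis segment
// (source -> target) than capsule radius + local cone radius + safety margin.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// closest points between segments p1+s*d1 (s in [0,1]) and p2+t*d2;
// returns squared distance, writes the axis parameter s of segment 1
double seg_seg_dist2(const double p1[3], const double q1[3], const double p2[3],
                     const double q2[3], double &s_out) {
  double d1[3], d2[3], r[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = q1[i] - p1[i];
    d2[i] = q2[i] - p2[i];
    r[i] = p1[i] - p2[i];
  }
  double a = d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2];
  double e = d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2];
  double f = d2[0]*r[0] + d2[1]*r[1] + d2[2]*r[2];
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(std::max(f / e, 0.0), 1.0); }
  else {
    double c = d1[0]*r[0] + d1[1]*r[1] + d1[2]*r[2];
    if (e <= EPS) { t = 0.0; s = std::min(std::max(-c / a, 0.0), 1.0); }
    else {
      double b = d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2];
      double denom = a * e - b * b;
      s = denom > EPS ? std::min(std::max((b * f - c * e) / denom, 0.0), 1.0)
                      : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(std::max(-c / a, 0.0), 1.0); }
      else if (t > 1) { t = 1; s = std::min(std::max((b - c) / a, 0.0), 1.0); }
    }
  }
  double cp[3];
  double d2v = 0;
  for (int i = 0; i < 3; ++i) {
    cp[i] = p1[i] + s * d1[i] - (p2[i] + t * d2[i]);
    d2v += cp[i] * cp[i];
  }
  s_out = s;
  return d2v;
}

}  // namespace

// [[Rcpp::export(name = ".seg_seg_dist_cpp")]]
double seg_seg_dist_cpp(NumericVector p1, NumericVector q1, NumericVector p2,
                        NumericVector q2) {
  double a[3] = {p1[0], p1[1], p1[2]}, b[3] = {q1[0], q1[1], q1[2]};
  double c[3] = {p2[0], p2[1], p2[2]}, d[3] = {q2[0], q2[1], q2[2]};
  double s;
  return std::sqrt(seg_seg_dist2(a, b, c, d, s));
}

// Per-beam clearance slack: min over capsules of
//   dist(axis segment, capsule segment) - capsule_r - cone_r(at closest) - margin.
// Blocked <=> slack < 0.
// [[Rcpp::export(name = ".beam_clearance_cpp")]]
NumericVector beam_clearance_cpp(NumericMatrix src, NumericMatrix tgt,
                                 NumericVector diam, NumericMatrix capA,
                                 NumericMatrix capB, NumericVector capR,
                                 double margin, double sad = 800.0) {
  int nb = src.nrow(), nc = capA.nrow();
  NumericVector slack(nb);
  for (int b = 0; b < nb; ++b) {
    double p1[3] = {src(b, 0), src(b, 1), src(b, 2)};
    double q1[3] = {tgt(b, 0), tgt(b, 1), tgt(b, 2)};
    double seglen = std::sqrt((q1[0]-p1[0])*(q1[0]-p1[0]) +
                              (q1[1]-p1[1])*(q1[1]-p1[1]) +
                              (q1[2]-p1[2])*(q1[2]-p1[2]));
    double best = R_PosInf;
    for (int c = 0; c < nc; ++c) {
      double p2[3] = {capA(c, 0), capA(c, 1), capA(c, 2)};
      double q2[3] = {capB(c, 0), capB(c, 1), capB(c, 2)};
      double s;
      double d = std::sqrt(seg_seg_dist2(p1, q1, p2, q2, s));
      double rcone = (diam[b] / 2.0) * (s * seglen) / sad;
      double sl = d - capR[c] - rcone - margin;
      if (sl < best) best = sl;
    }
    slack[b] = best;
  }
  return slack;
}
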