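// Dense bounded-variable two-phase revised simplex.
//
// Solves  min c'x  s.t.  A x (<=|=|>=) b,  l <= x <= u  (u may be +Inf).
// Intended for the planning LPs produced by the row-generation wrapper in
// R/planning.R (hundreds to a few thousand rows). Only structural columns
// are stored densely; slack and artificial columns are unit vectors priced
// in O(1). Explicit basis inverse with rank-1 updates and periodic
// refactorization; Dantzig pricing with a Bland fallback on stalls; the
// caller may hint an initial basis (one column per row), which lets the
// stage-1 planning LP start primal feasible and skip phase 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

constexpr double kInf = std::numeric_limits<double>::infinity();

struct Tab {
  // columns: [0, n) structural, [n, n + m) slacks (fixed at 0 for equality
  // rows), [n + m, n + 2m) artificials (fixed at 0 unless activated)
  mat A;                  // m x n structural block
  vec b, cost, lo, hi, x; // over all ntot columns
  std::vector<double> unit_coef;  // coefficient of each unit column
  uvec basis;
  std::vector<char> in_basis;
  mat Binv;
  int m = 0, n = 0, ntot = 0;

  int rowof(int j) const { return (j - n) % m; }
  // Binv * column_j
  vec bcol(int j) const {
    if (j < n) return Binv * A.col(j);
    return Binv.col(rowof(j)) * unit_coef[j - n];
  }
};

void refactor(Tab &t) {
  mat B(t.m, t.m, fill::zeros);
  for (int i = 0; i < t.m; ++i) {
    int j = t.basis[i];
    if (j < t.n) B.col(i) = t.A.col(j);
    else B(t.rowof(j), i) = t.unit_coef[j - t.n];
  }
  if (!inv(t.Binv, B)) {
    // numerically singular basis (tiny pivot slipped in): nudge and retry
    B.diag() += 1e-9;
    if (!inv(t.Binv, B)) Rcpp::stop("basis factorization failed");
  }
  vec rhs = t.b;
  for (int j = 0; j < t.n; ++j) {
    if (!t.in_basis[j] && t.x[j] != 0.0) rhs -= t.A.col(j) * t.x[j];
  }
  for (int j = t.n; j < t.ntot; ++j) {
    if (!t.in_basis[j] && t.x[j] != 0.0)
      rhs[t.rowof(j)] -= t.unit_coef[j - t.n] * t.x[j];
  }
  vec xb = t.Binv * rhs;
  for (int i = 0; i < t.m; ++i) t.x[t.basis[i]] = xb[i];
}

// returns: 0 optimal, 1 unbounded, 2 iteration limit
int simplex_phase(Tab &t, int max_iter, double tol, int &iter_count) {
  const int m = t.m, n = t.n, ntot = t.ntot;
  int stall = 0, since_refactor = 0;
  double last_obj = kInf;
  bool bland = false;

  for (int it = 0; it < max_iter; ++it) {
    ++iter_count;
    vec cB(m);
    for (int i = 0; i < m; ++i) cB[i] = t.cost[t.basis[i]];
    vec y = (cB.t() * t.Binv).t();
    rowvec yA = y.t() * t.A;  // structural pricing in one gemv

    int enter = -1, dir = 0;
    double best = -tol;
    for (int j = 0; j < ntot; ++j) {
      if (t.in_basis[j] || t.lo[j] == t.hi[j]) continue;
      double dj = t.cost[j] -
          (j < n ? yA[j] : y[t.rowof(j)] * t.unit_coef[j - n]);
      bool at_lo = std::abs(t.x[j] - t.lo[j]) < 1e-9;
      double viol;
      int dj_dir;
      if (at_lo && dj < -tol) { viol = dj; dj_dir = +1; }
      else if (!at_lo && dj > tol) { viol = -dj; dj_dir = -1; }
      else continue;
      if (bland) { enter = j; dir = dj_dir; break; }
      if (viol < best) { best = viol; enter = j; dir = dj_dir; }
    }
    if (enter < 0) return 0;  // optimal

    vec w = t.bcol(enter);

    double step = (t.hi[enter] < kInf) ? (t.hi[enter] - t.lo[enter]) : kInf;
    int leave = -1;
    double piv_abs = 0;
    for (int i = 0; i < m; ++i) {
      double wi = w[i] * dir;
      int bi = t.basis[i];
      double room;
      if (wi > 1e-9) room = (t.x[bi] - t.lo[bi]) / wi;
      else if (wi < -1e-9 && t.hi[bi] < kInf) room = (t.hi[bi] - t.x[bi]) / (-wi);
      else continue;
      if (room < -1e-12) room = 0;
      bool better;
      if (room < step - 1e-12) better = true;
      else if (room < step + 1e-12 && leave >= 0) {
        // tie-break: Bland mode -> lowest basic index (anti-cycling),
        // otherwise largest pivot magnitude (stability)
        better = bland ? ((unsigned)bi < t.basis[leave])
                       : (std::abs(w[i]) > piv_abs);
      } else better = false;
      if (better) { step = room; leave = i; piv_abs = std::abs(w[i]); }
    }
    if (step == kInf) return 1;  // unbounded
    if (step < 0) step = 0;

    t.x[enter] += dir * step;
    for (int i = 0; i < m; ++i) t.x[t.basis[i]] -= w[i] * dir * step;

    if (leave >= 0) {
      int out = t.basis[leave];
      double wl = w[leave] * dir;
      t.x[out] = (wl > 0) ? t.lo[out] : t.hi[out];
      t.in_basis[out] = 0;
      t.in_basis[enter] = 1;
      t.basis[leave] = enter;
      double piv = w[leave];
      rowvec br = t.Binv.row(leave) / piv;
      vec wcorr = w;
      wcorr[leave] = 0.0;
      t.Binv -= wcorr * br;
      t.Binv.row(leave) = br;
      ++since_refactor;
      if (since_refactor >= 500 || std::abs(piv) < 1e-6) {
        refactor(t);
        since_refactor = 0;
      }
    }

    double obj = dot(t.cost, t.x);
    if (obj < last_obj - 1e-10) { last_obj = obj; stall = 0; bland = false; }
    else if (++stall > 2 * m + 200) bland = true;
  }
  return 2;
}

}  // namespace

// basis0: optional 1-based column hint per row (0 = auto: the row's slack).
// [[Rcpp::export(name = ".lp_solve_cpp")]]
Rcpp::List lp_solve_cpp(const arma::mat &A, const arma::vec &b,
                        Rcpp::IntegerVector sense, const arma::vec &cc,
                        const arma::vec &lo, const arma::vec &hi,
                        Rcpp::Nullable<Rcpp::IntegerVector> basis0 = R_NilValue,
                        int max_iter = 0, double tol = 1e-9,
                        bool perturb = false) {
  const int m = A.n_rows, n = A.n_cols;
  Rcpp::IntegerVector hint =
      basis0.isNotNull() ? Rcpp::IntegerVector(basis0) : Rcpp::IntegerVector(0);

  Tab t;
  t.m = m;
  t.n = n;
  t.ntot = n + 2 * m;
  t.A = A;
  t.b = b;
  vec b_exact = t.b;
  if (perturb) {
    // deterministic tiny expansion of the feasible region against
    // degenerate pivoting; removed again before the final cleanup solve
    unsigned h = 2166136261u;
    for (int i = 0; i < m; ++i) {
      h = (h ^ (unsigned)(i + 1)) * 16777619u;
      double u = (double)(h & 0xffffff) / (double)0x1000000;  // [0,1)
      double scale = 1e-8 * (1.0 + std::abs(t.b[i]));
      if (sense[i] < 0) t.b[i] += scale * (0.5 + u);
      else if (sense[i] > 0) t.b[i] -= scale * (0.5 + u);
    }
  }
  t.cost.zeros(t.ntot);
  t.lo.zeros(t.ntot);
  t.hi.zeros(t.ntot);
  t.x.zeros(t.ntot);
  t.in_basis.assign(t.ntot, 0);
  t.unit_coef.assign(2 * m, 0.0);

  for (int j = 0; j < n; ++j) { t.lo[j] = lo[j]; t.hi[j] = hi[j]; }
  for (int j = 0; j < n; ++j) {
    if (std::isfinite(t.lo[j])) t.x[j] = t.lo[j];
    else if (std::isfinite(t.hi[j])) t.x[j] = t.hi[j];
    else t.x[j] = 0.0;
  }
  // slack columns for inequality rows; artificial slots stay fixed at 0
  for (int i = 0; i < m; ++i) {
    int sj = n + i;
    if (sense[i] != 0) {
      t.unit_coef[i] = (sense[i] < 0) ? 1.0 : -1.0;
      t.lo[sj] = 0.0;
      t.hi[sj] = kInf;
    } else {
      t.lo[sj] = t.hi[sj] = 0.0;
    }
    t.lo[n + m + i] = t.hi[n + m + i] = 0.0;
  }

  t.basis.set_size(m);
  double art_needed = 0.0;
  bool have_hint = hint.size() == m;

  bool hint_ok = false;
  if (have_hint) {
    hint_ok = true;
    std::vector<char> used(t.ntot, 0);
    for (int i = 0; i < m && hint_ok; ++i) {
      int j = hint[i] - 1;
      if (j < 0) {
        if (sense[i] == 0) { hint_ok = false; break; }
        j = n + i;
      }
      if (j >= t.ntot || used[j] || t.lo[j] == t.hi[j]) { hint_ok = false; break; }
      used[j] = 1;
      t.basis[i] = j;
    }
    if (hint_ok) {
      for (int i = 0; i < m; ++i) t.in_basis[t.basis[i]] = 1;
      refactor(t);
      // rows whose hinted basic value is infeasible fall back to an
      // artificial; phase 1 then repairs just those rows
      for (int rep = 0; rep < 3; ++rep) {
        std::vector<int> bad;
        for (int i = 0; i < m; ++i) {
          int bi = t.basis[i];
          if (t.x[bi] < t.lo[bi] - 1e-7 ||
              (std::isfinite(t.hi[bi]) && t.x[bi] > t.hi[bi] + 1e-7)) {
            if (bi >= n + m) {  // already an artificial: flip its sign
              t.unit_coef[bi - n] = -t.unit_coef[bi - n];
              t.Binv.row(i) *= -1.0;
              t.x[bi] = -t.x[bi];
            } else {
              bad.push_back(i);
            }
          }
        }
        if (bad.empty()) break;
        for (int i : bad) {
          int bi = t.basis[i];
          t.in_basis[bi] = 0;
          t.x[bi] = std::isfinite(t.lo[bi]) ? t.lo[bi]
                    : (std::isfinite(t.hi[bi]) ? t.hi[bi] : 0.0);
          int aj = n + m + i;
          t.unit_coef[m + i] = 1.0;
          t.lo[aj] = 0.0;
          t.hi[aj] = kInf;
          t.basis[i] = aj;
          t.in_basis[aj] = 1;
        }
        refactor(t);
      }
      for (int i = 0; i < m; ++i) {
        int aj = n + m + i;
        if (t.in_basis[aj]) art_needed += std::abs(t.x[aj]);
      }
    }
  }

  if (!hint_ok) {
    vec r = t.b - t.A * t.x.subvec(0, n - 1);
    for (int i = 0; i < m; ++i) {
      int sj = n + i;
      bool use_slack = false;
      if (sense[i] != 0) {
        double sv = r[i] * t.unit_coef[i];
        if (sv >= 0) {
          t.x[sj] = sv;
          t.basis[i] = sj;
          t.in_basis[sj] = 1;
          use_slack = true;
        }
      }
      if (!use_slack) {  // activate the row's artificial
        int aj = n + m + i;
        t.unit_coef[m + i] = (r[i] >= 0) ? 1.0 : -1.0;
        t.lo[aj] = 0.0;
        t.hi[aj] = kInf;
        t.x[aj] = std::abs(r[i]);
        t.basis[i] = aj;
        t.in_basis[aj] = 1;
        art_needed += std::abs(r[i]);
      }
    }
    refactor(t);
  }

  if (max_iter <= 0) max_iter = 30 * (m + n) + 10000;
  int iters = 0;
  std::string status = "optimal";

  if (art_needed > tol) {  // phase 1: drive artificials out
    for (int i = 0; i < m; ++i) {
      if (t.hi[n + m + i] > 0) t.cost[n + m + i] = 1.0;
    }
    int rc = simplex_phase(t, max_iter, tol, iters);
    double p1 = dot(t.cost, t.x);
    if (rc == 2) status = "iteration_limit";
    else if (p1 > 1e-7) status = "infeasible";
    t.cost.zeros();
    for (int i = 0; i < m; ++i) {  // pin artificials at zero
      int aj = n + m + i;
      t.hi[aj] = t.lo[aj] = 0.0;
      if (!t.in_basis[aj]) t.x[aj] = 0.0;
    }
  }
  if (status == "optimal") {  // phase 2
    for (int j = 0; j < n; ++j) t.cost[j] = cc[j];
    int rc = simplex_phase(t, max_iter, tol, iters);
    if (rc == 1) status = "unbounded";
    else if (rc == 2) status = "iteration_limit";
  }
  if (perturb && status == "optimal") {
    // restore the exact right-hand side and re-optimize from the
    // perturbed-optimal basis (usually a handful of pivots)
    t.b = b_exact;
    refactor(t);
    simplex_phase(t, max_iter, tol, iters);
  }

  refactor(t);
  vec xs = t.x.subvec(0, n - 1);
  vec cB(m);
  for (int i = 0; i < m; ++i) cB[i] = t.cost[t.basis[i]];
  vec y = (cB.t() * t.Binv).t();

  // basis report: 1-based structural / slack column per row (artificial -> 0)
  Rcpp::IntegerVector basis_out(m);
  for (int i = 0; i < m; ++i) {
    int j = t.basis[i];
    basis_out[i] = (j < n + m) ? j + 1 : 0;
  }

  return Rcpp::List::create(
      Rcpp::Named("status") = status,
      Rcpp::Named("x") = xs,
      Rcpp::Named("objective") = dot(cc, xs),
      Rcpp::Named("dual") = y,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("basis") = basis_out);
}
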