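#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Bounded-variable two-phase primal simplex (full tableau).
//
// Solves   max c'x   s.t.  A x = b,  lb <= x <= ub
// with all bounds finite (the FBA layer guarantees this: every flux is
// confined to [-U, U]).  Phase 1 introduces one artificial variable per
// row; phase 2 optimizes the true objective.  Dantzig pricing with a
// switch to Bland's rule after an iteration threshold guards against
// cycling on degenerate vertices.
//
// Status codes: 0 = optimal, 1 = infeasible, 2 = iteration limit.

static const double PIVOT_TOL = 1e-10;
static const double RC_TOL = 1e-9;
static const double RATIO_TOL = 1e-9;
static const double FEAS_TOL = 1e-7;
static const double BIG = std::numeric_limits<double>::infinity();

namespace {

struct Tableau {
  int m, n_real, ncols;           // ncols = n_real + m artificials
  std::vector<double> T;          // m x ncols, row-major: B^{-1} A
  std::vector<double> xB;         // values of basic variables (shifted space)
  std::vector<double> d;          // upper bound of shifted variable (>= 0)
  std::vector<int> basis;         // column in basis for each row
  std::vector<int> status;        // 0 at lower, 1 at upper, 2 basic
  std::vector<bool> banned;       // artificials barred from re-entering
  std::vector<double> rc;         // reduced costs c - c_B' T

  double &at(int i, int j) { return T[(size_t)i * ncols + j]; }
};

// recompute reduced costs from scratch for cost vector c (length ncols)
void price_all(Tableau &tb, const std::vector<double> &c) {
  for (int j = 0; j < tb.ncols; ++j) tb.rc[j] = c[j];
  for (int i = 0; i < tb.m; ++i) {
    double cb = c[tb.basis[i]];
    if (cb != 0.0) {
      for (int j = 0; j < tb.ncols; ++j) tb.rc[j] -= cb * tb.at(i, j);
    }
  }
}

// one simplex phase; returns true normally, false on iteration limit
bool run_phase(Tableau &tb, int max_iter) {
  int iter = 0;
  const int bland_after = max_iter / 2;
  while (iter++ < max_iter) {
    bool bland = iter > bland_after;
    // --- pricing: pick entering column ---
    int jin = -1, dir = 0;
    double best = RC_TOL;
    for (int j = 0; j < tb.ncols; ++j) {
      if (tb.status[j] == 2 || tb.banned[j] || tb.d[j] <= RATIO_TOL) continue;
      double r = tb.rc[j];
      if (tb.status[j] == 0 && r > RC_TOL) {
        if (bland) { jin = j; dir = +1; break; }
        if (r > best) { best = r; jin = j; dir = +1; }
      } else if (tb.status[j] == 1 && r < -RC_TOL) {
        if (bland) { jin = j; dir = -1; break; }
        if (-r > best) { best = -r; jin = j; dir = -1; }
      }
    }
    if (jin < 0) return true;  // optimal for this phase

    // --- ratio test ---
    double tmax = tb.d[jin];   // bound-flip limit (finite unless artificial)
    int rleave = -1;           // -1 => bound flip
    int leave_to = 0;          // 0 leaves to lower, 1 to upper
    double tstar = tmax;
    for (int i = 0; i < tb.m; ++i) {
      double w = tb.at(i, jin) * dir;
      if (w > PIVOT_TOL) {                       // basic var decreases -> 0
        double t = tb.xB[i] / w;
        if (t < tstar - RATIO_TOL ||
            (rleave >= 0 && std::fabs(t - tstar) <= RATIO_TOL && bland &&
             tb.basis[i] < tb.basis[rleave])) {
          tstar = t; rleave = i; leave_to = 0;
        }
      } else if (w < -PIVOT_TOL) {               // basic var increases -> ub
        double db = tb.d[tb.basis[i]];
        if (db == BIG) continue;
        double t = (db - tb.xB[i]) / (-w);
        if (t < tstar - RATIO_TOL ||
            (rleave >= 0 && std::fabs(t - tstar) <= RATIO_TOL && bland &&
             tb.basis[i] < tb.basis[rleave])) {
          tstar = t; rleave = i; leave_to = 1;
        }
      }
    }
    if (tstar >= BIG) return true;  // cannot happen with finite bounds
    if (tstar < 0) tstar = 0;

    // --- update basic values ---
    for (int i = 0; i < tb.m; ++i) {
      tb.xB[i] -= dir * tstar * tb.at(i, jin);
      if (tb.xB[i] < 0 && tb.xB[i] > -1e-11) tb.xB[i] = 0;
    }
    if (rleave < 0) {
      // bound flip, basis unchanged
      tb.status[jin] = (tb.status[jin] == 0) ? 1 : 0;
      continue;
    }
    int jout = tb.basis[rleave];
    double enter_val = (tb.status[jin] == 0) ? tstar : tb.d[jin] - tstar;
    tb.status[jout] = leave_to;
    tb.status[jin] = 2;
    tb.basis[rleave] = jin;
    tb.xB[rleave] = enter_val;

    // --- pivot the tableau on (rleave, jin) ---
    double piv = tb.at(rleave, jin);
    double inv = 1.0 / piv;
    for (int j = 0; j < tb.ncols; ++j) tb.at(rleave, j) *= inv;
    for (int i = 0; i < tb.m; ++i) {
      if (i == rleave) continue;
      double f = tb.at(i, jin);
      if (f != 0.0) {
        for (int j = 0; j < tb.ncols; ++j) tb.at(i, j) -= f * tb.at(rleave, j);
        tb.at(i, jin) = 0.0;
      }
    }
    double fr = tb.rc[jin];
    if (fr != 0.0) {
      for (int j = 0; j < tb.ncols; ++j) tb.rc[j] -= fr * tb.at(rleave, j);
      tb.rc[jin] = 0.0;
    }
  }
  return false;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".simplex_solve")]]
List simplex_solve(NumericVector obj, NumericMatrix A, NumericVector rhs,
                   NumericVector lower, NumericVector upper,
                   bool maximize = true, int max_iter = 20000) {
  int m = A.nrow(), n = A.ncol();
  if (obj.size() != n || lower.size() != n || upper.size() != n ||
      rhs.size() != m)
    stop("simplex: inconsistent dimensions");

  Tableau tb;
  tb.m = m; tb.n_real = n; tb.ncols = n + m;
  tb.T.assign((size_t)m * tb.ncols, 0.0);
  tb.xB.assign(m, 0.0);
  tb.d.assign(tb.ncols, 0.0);
  tb.basis.assign(m, 0);
  tb.status.assign(tb.ncols, 0);
  tb.banned.assign(tb.ncols, false);
  tb.rc.assign(tb.ncols, 0.0);

  // shifted variables y = x - lb in [0, d]; rhs' = b - A lb
  std::vector<double> rhs2(m);
  for (int j = 0; j < n; ++j) {
    double dj = upper[j] - lower[j];
    if (dj < -1e-9) stop("simplex: lower bound exceeds upper bound");
    tb.d[j] = dj < 0 ? 0 : dj;
  }
  for (int i = 0; i < m; ++i) {
    double s = rhs[i];
    for (int j = 0; j < n; ++j) s -= A(i, j) * lower[j];
    rhs2[i] = s;
  }
  // copy A with row signs making rhs' >= 0; artificial identity
  for (int i = 0; i < m; ++i) {
    double sgn = (rhs2[i] < 0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) tb.at(i, j) = sgn * A(i, j);
    tb.at(i, n + i) = 1.0;
    tb.xB[i] = sgn * rhs2[i];
    tb.basis[i] = n + i;
    tb.status[n + i] = 2;
    tb.d[n + i] = BIG;
  }

  // ---- phase 1: maximize -(sum of artificials) ----
  std::vector<double> c1(tb.ncols, 0.0);
  for (int i = 0; i < m; ++i) c1[n + i] = -1.0;
  price_all(tb, c1);
  if (!run_phase(tb, max_iter))
    return List::create(_["status"] = 2, _["z"] = NA_REAL,
                        _["x"] = NumericVector(n));
  double art_sum = 0.0;
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] >= n) art_sum += tb.xB[i];
  if (art_sum > FEAS_TOL)
    return List::create(_["status"] = 1, _["z"] = NA_REAL,
                        _["x"] = NumericVector(n));

  // drive residual basic artificials out (degenerate rows)
  for (int i = 0; i < m; ++i) {
    if (tb.basis[i] < n) continue;
    int jp = -1;
    double bestp = PIVOT_TOL;
    for (int j = 0; j < n; ++j) {
      if (tb.status[j] != 0) continue;  // only at-lower columns enter at 0
      double a = std::fabs(tb.at(i, j));
      if (a > bestp) { bestp = a; jp = j; }
    }
    if (jp >= 0) {
      int jout = tb.basis[i];
      double piv = tb.at(i, jp), inv = 1.0 / piv;
      for (int j = 0; j < tb.ncols; ++j) tb.at(i, j) *= inv;
      for (int k = 0; k < m; ++k) {
        if (k == i) continue;
        double f = tb.at(k, jp);
        if (f != 0.0) {
          for (int j = 0; j < tb.ncols; ++j) tb.at(k, j) -= f * tb.at(i, j);
          tb.at(k, jp) = 0.0;
        }
      }
      // entering at value 0 (row was degenerate)
      tb.status[jout] = 0; tb.banned[jout] = true;
      tb.basis[i] = jp; tb.status[jp] = 2; tb.xB[i] = 0.0;
    }
    // else: redundant row, artificial stays basic at 0 (harmless)
  }
  for (int i = 0; i < m; ++i) {
    tb.banned[n + i] = true;
    tb.d[n + i] = 0.0;  // a residual basic artificial may never re-inflate
  }
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] >= n && tb.xB[i] < FEAS_TOL) tb.xB[i] = 0.0;

  // ---- phase 2 ----
  std::vector<double> c2(tb.ncols, 0.0);
  double sign = maximize ? 1.0 : -1.0;
  for (int j = 0; j < n; ++j) c2[j] = sign * obj[j];
  price_all(tb, c2);
  if (!run_phase(tb, max_iter))
    return List::create(_["status"] = 2, _["z"] = NA_REAL,
                        _["x"] = NumericVector(n));

  // ---- recover solution ----
  NumericVector x(n);
  for (int j = 0; j < n; ++j)
    x[j] = lower[j] + (tb.status[j] == 1 ? tb.d[j] : 0.0);
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] < n) x[tb.basis[i]] = lower[tb.basis[i]] + tb.xB[i];
  double z = 0.0;
  for (int j = 0; j < n; ++j) z += obj[j] * x[j];
  return List::create(_["status"] = 0, _["z"] = z, _["x"] = x);
}
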