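// Bounded-variable two-phase revised simplex, dense basis inverse, sparse
// constraint matrix (CSC).  Solves
//     maximize  c'v   subject to   A v = 0,   lb <= v <= ub
// which is the shape of every feasibility / FBA program in this package
// (mass balance is homogeneous; environment composition enters through the
// bounds).  Variables with lb > 0 or ub < 0 are handled by an internal shift
// and a phase-1 with artificial columns.
//
// Sizes here are small (hundreds of rows/columns), so a dense m x m basis
// inverse with periodic refactorisation is both simple and fast; pricing and
// column extraction use the sparse structure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TOL = 1e-9;

struct Csc {
  const int *p;    // n+1 column pointers
  const int *i;    // row indices
  const double *x; // values
};

// y' A_j for sparse column j
static inline double col_dot(const Csc &A, int j, const arma::vec &y) {
  double s = 0.0;
  for (int k = A.p[j]; k < A.p[j + 1]; ++k) s += A.x[k] * y[A.i[k]];
  return s;
}

// [[Rcpp::export(name = ".simplex_lp_cpp")]]
List simplex_lp_cpp(int m, int n,
                    IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                    NumericVector lb, NumericVector ub, NumericVector obj,
                    double early_stop = NA_REAL, int max_iter = 0) {
  Csc A{Ap.begin(), Ai.begin(), Ax.begin()};
  const int N = n + m; // structural + artificial columns
  if (max_iter <= 0) max_iter = 200 * (m + n) + 2000;

  // shift so that 0 is feasible for every structural variable
  arma::vec ref(n, arma::fill::zeros), l(N), u(N);
  for (int j = 0; j < n; ++j) {
    if (lb[j] > 0) ref[j] = lb[j];
    else if (ub[j] < 0) ref[j] = ub[j];
    l[j] = lb[j] - ref[j];
    u[j] = ub[j] - ref[j];
  }
  arma::vec b(m, arma::fill::zeros); // rhs in shifted coordinates: -A ref
  for (int j = 0; j < n; ++j)
    if (ref[j] != 0.0)
      for (int k = A.p[j]; k < A.p[j + 1]; ++k) b[A.i[k]] -= A.x[k] * ref[j];

  bool phase1 = arma::any(arma::abs(b) > TOL);
  // artificial bounds: span the initial residual during phase 1
  for (int iart = 0; iart < m; ++iart) {
    l[n + iart] = std::min(b[iart], 0.0);
    u[n + iart] = std::max(b[iart], 0.0);
  }

  // cost vectors (both phases maximize)
  arma::vec cost1(N, arma::fill::zeros), cost2(N, arma::fill::zeros);
  for (int iart = 0; iart < m; ++iart)
    cost1[n + iart] = (b[iart] > 0) ? -1.0 : ((b[iart] < 0) ? 1.0 : 0.0);
  for (int j = 0; j < n; ++j) cost2[j] = obj[j];

  std::vector<int> basis(m);
  std::vector<int> pos(N, -1); // position in basis, -1 if nonbasic
  arma::vec xval(N, arma::fill::zeros); // values of nonbasic columns
  arma::vec xB(m);
  for (int iart = 0; iart < m; ++iart) {
    basis[iart] = n + iart;
    pos[n + iart] = iart;
    xB[iart] = b[iart];
  }
  arma::mat Binv(m, m, arma::fill::eye);

  int phase = phase1 ? 1 : 2;
  if (phase == 2)
    for (int iart = 0; iart < m; ++iart) { l[n + iart] = 0.0; u[n + iart] = 0.0; }

  auto column_into = [&](int j, arma::vec &out) {
    out.zeros();
    if (j >= n) out[j - n] = 1.0;
    else for (int k = A.p[j]; k < A.p[j + 1]; ++k) out[A.i[k]] = A.x[k];
  };

  auto refactor = [&]() {
    arma::mat B(m, m, arma::fill::zeros);
    arma::vec colbuf(m);
    for (int k = 0; k < m; ++k) { column_into(basis[k], colbuf); B.col(k) = colbuf; }
    arma::mat Bi;
    if (!arma::inv(Bi, B)) return false;
    Binv = Bi;
    // recompute basic values from nonbasic ones to wash out drift
    arma::vec r = b;
    for (int j = 0; j < N; ++j) {
      if (pos[j] >= 0 || xval[j] == 0.0) continue;
      if (j >= n) r[j - n] -= xval[j];
      else for (int k = A.p[j]; k < A.p[j + 1]; ++k) r[A.i[k]] -= A.x[k] * xval[j];
    }
    xB = Binv * r;
    return true;
  };

  arma::vec w(m), cB(m), y(m);
  bool bland = false;
  int stall = 0, iter = 0, status = 3;
  double objcur = 0.0; // phase-2 objective of the current shifted point

  auto current_obj2 = [&]() {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += cost2[basis[k]] * xB[k];
    for (int j = 0; j < n; ++j) if (pos[j] < 0 && xval[j] != 0.0) s += cost2[j] * xval[j];
    return s;
  };
  objcur = current_obj2();
  // objective contribution of the shift (constant)
  double shiftobj = 0.0;
  for (int j = 0; j < n; ++j) shiftobj += obj[j] * ref[j];

  for (iter = 0; iter < max_iter; ++iter) {
    const arma::vec &cost = (phase == 1) ? cost1 : cost2;
    for (int k = 0; k < m; ++k) cB[k] = cost[basis[k]];
    y = Binv.t() * cB;

    // pricing
    int e = -1, sig = 0;
    double best = 0.0;
    for (int j = 0; j < N; ++j) {
      if (pos[j] >= 0) continue;
      if (u[j] - l[j] < TOL) continue; // fixed (includes retired artificials)
      double d = cost[j] - ((j >= n) ? y[j - n] : col_dot(A, j, y));
      int s = 0;
      if (d > TOL && xval[j] < u[j] - TOL) s = 1;
      else if (d < -TOL && xval[j] > l[j] + TOL) s = -1;
      if (!s) continue;
      if (bland) { e = j; sig = s; break; }
      if (std::fabs(d) > best) { best = std::fabs(d); e = j; sig = s; }
    }

    if (e < 0) { // optimal for this phase
      if (phase == 1) {
        double infeas = 0.0;
        for (int k = 0; k < m; ++k)
          if (basis[k] >= n) infeas += std::fabs(xB[k]);
        if (infeas > 1e-7) { status = 1; break; }
        for (int iart = 0; iart < m; ++iart) { l[n + iart] = 0.0; u[n + iart] = 0.0; xval[n + iart] = 0.0; }
        phase = 2; bland = false; stall = 0;
        objcur = current_obj2();
        continue;
      }
      status = 0; break;
    }

    column_into(e, w);
    w = Binv * w;

    // ratio test: entering moves by t >= 0 in direction sig
    double tmax = (sig > 0) ? (u[e] - xval[e]) : (xval[e] - l[e]);
    int leave = -1;
    for (int k = 0; k < m; ++k) {
      double wk = sig * w[k]; // basic k changes by -wk * t
      double lim;
      if (wk > TOL) lim = (xB[k] - l[basis[k]]) / wk;
      else if (wk < -TOL) lim = (u[basis[k]] - xB[k]) / (-wk);
      else continue;
      if (lim < 0) lim = 0;
      if (lim < tmax - TOL) { tmax = lim; leave = k; }
      else if (lim <= tmax + TOL) {
        // tie: Bland wants the smallest index; otherwise the largest pivot
        if (leave < 0) { if (lim < tmax) tmax = lim; leave = k; }
        else if (bland ? (basis[k] < basis[leave])
                       : (std::fabs(w[k]) > std::fabs(w[leave]))) {
          if (lim < tmax) tmax = lim;
          leave = k;
        }
      }
    }
    if (!std::isfinite(tmax)) { status = 2; break; } // unbounded
    if (tmax < 0) tmax = 0;

    for (int k = 0; k < m; ++k) xB[k] -= sig * tmax * w[k];
    xval[e] += sig * tmax;
    if (phase == 2) {
      double d2 = cost2[e] - ((e >= n) ? y[e - n] : col_dot(A, e, y));
      objcur += d2 * sig * tmax;
    }

    if (leave >= 0) {
      int Lcol = basis[leave];
      // leaving variable lands exactly on the bound it hit
      xval[Lcol] = (sig * w[leave] > 0) ? l[Lcol] : u[Lcol];
      pos[Lcol] = -1;
      basis[leave] = e;
      pos[e] = leave;
      xB[leave] = xval[e];
      double piv = w[leave];
      Binv.row(leave) /= piv;
      for (int k = 0; k < m; ++k) {
        if (k == leave) continue;
        double f = w[k];
        if (f != 0.0) Binv.row(k) -= f * Binv.row(leave);
      }
    }
    // anti-cycling: switch to Bland's rule after a long degenerate stretch
    if (tmax > TOL) stall = 0; else if (++stall > 2 * (m + n) + 50) bland = true;

    if ((iter + 1) % 128 == 0) {
      if (!refactor()) { status = 4; break; }
      objcur = current_obj2();
    }

    if (phase == 2 && R_finite(early_stop) && objcur + shiftobj > early_stop) {
      status = 0; break; // primal feasible throughout; objective already suffices
    }
  }

  // extract structural solution (unshifted)
  NumericVector x(n);
  for (int j = 0; j < n; ++j)
    x[j] = ((pos[j] >= 0) ? xB[pos[j]] : xval[j]) + ref[j];
  double objval = 0.0;
  for (int j = 0; j < n; ++j) objval += obj[j] * x[j];

  return List::create(_["status"] = status, _["objval"] = objval,
                      _["x"] = x, _["iter"] = iter);
}
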