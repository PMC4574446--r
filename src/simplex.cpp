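// Bounded-variable primal simplex for the small dense LPs arising in
// flux balance analysis:  min/max c'x  s.t.  A x = b,  lb <= x <= ub.
//
// Two phases with artificial variables, Bland's pivoting rule throughout
// (guarantees termination on the highly degenerate LPs produced by pinned
// fluxes).  Basic solutions are recomputed from the basis factorization at
// every iteration rather than updated incrementally; problem sizes here are
// tens of variables, so stability is worth more than speed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double RC_TOL = 1e-9;     // reduced-cost tolerance
static const double FEAS_TOL = 1e-7;   // phase-1 residual tolerance
static const int MAX_ITER = 20000;

namespace {

struct SimplexState {
  mat A;            // m x N (structurals + artificials)
  vec c, lb, ub;    // length N
  uvec basis;       // m basic variable indices
  ivec nstat;       // 0 basic, -1 at lb, +1 at ub
  vec x;            // current point, length N
  int m, N;
};

// recompute basic components: x_B = B^{-1} (b - A_N x_N)
static bool recompute_basics(SimplexState &st, const vec &b) {
  vec rhs = b;
  for (int j = 0; j < st.N; ++j)
    if (st.nstat[j] != 0 && st.x[j] != 0.0) rhs -= st.A.col(j) * st.x[j];
  mat B = st.A.cols(st.basis);
  vec xB;
  if (!solve(xB, B, rhs, solve_opts::no_approx)) return false;
  for (int i = 0; i < st.m; ++i) st.x[st.basis[i]] = xB[i];
  return true;
}

// one phase of bounded simplex; minimizes st.c' x.  Returns 0 optimal,
// 1 singular basis, 2 iteration limit.
static int simplex_phase(SimplexState &st, const vec &b) {
  for (int iter = 0; iter < MAX_ITER; ++iter) {
    mat B = st.A.cols(st.basis);
    vec cB(st.m);
    for (int i = 0; i < st.m; ++i) cB[i] = st.c[st.basis[i]];
    vec y;
    if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 1;

    // Bland: smallest eligible entering index
    int enter = -1;
    double d_enter = 0.0;
    for (int j = 0; j < st.N; ++j) {
      if (st.nstat[j] == 0) continue;
      double dj = st.c[j] - dot(y, st.A.col(j));
      if (st.nstat[j] == -1 && dj < -RC_TOL) { enter = j; d_enter = dj; break; }
      if (st.nstat[j] == +1 && dj > RC_TOL)  { enter = j; d_enter = dj; break; }
    }
    (void)d_enter;
    if (enter < 0) return 0;  // optimal

    double dir = (st.nstat[enter] == -1) ? +1.0 : -1.0;  // entering moves up/down
    vec w;
    if (!solve(w, B, st.A.col(enter), solve_opts::no_approx)) return 1;
    // basic vars move by -t * dir * w

    double t_max = st.ub[enter] - st.lb[enter];  // bound flip distance (may be inf)
    int leave = -1;                              // position in basis, -1 => bound flip
    int leave_to = 0;                            // -1: leaving to lb, +1: to ub
    for (int i = 0; i < st.m; ++i) {
      double wi = dir * w[i];
      int bi = st.basis[i];
      double t_i = datum::inf;
      int to = 0;
      if (wi > 1e-11) {         // basic decreases towards lb
        t_i = (st.x[bi] - st.lb[bi]) / wi; to = -1;
      } else if (wi < -1e-11) { // basic increases towards ub
        if (std::isfinite(st.ub[bi])) { t_i = (st.ub[bi] - st.x[bi]) / (-wi); to = +1; }
      }
      if (t_i < -1e-12) t_i = 0.0;
      // Bland tie-break on the leaving variable index
      if (t_i < t_max - 1e-12 ||
          (t_i < t_max + 1e-12 && leave >= 0 && bi < (int)st.basis[leave])) {
        t_max = std::max(t_i, 0.0); leave = i; leave_to = to;
      }
    }
    if (!std::isfinite(t_max)) return 0;  // unbounded ray: only possible in a
                                          // phase bounded below, treat as optimal
                                          // (caller validates the solution)
    // apply step
    for (int i = 0; i < st.m; ++i) st.x[st.basis[i]] -= t_max * dir * w[i];
    st.x[enter] += t_max * dir;
    if (leave < 0) {
      st.nstat[enter] = -st.nstat[enter];  // bound flip
    } else {
      int out = st.basis[leave];
      st.x[out] = (leave_to < 0) ? st.lb[out] : st.ub[out];
      st.nstat[out] = (leave_to < 0) ? -1 : +1;
      st.basis[leave] = enter;
      st.nstat[enter] = 0;
    }
    if (!recompute_basics(st, b)) return 1;
  }
  return 2;
}

}  // namespace

// [[Rcpp::export(name = ".simplex_bounded")]]
Rcpp::List simplex_bounded(const arma::mat &A, const arma::vec &b,
                           const arma::vec &lb, const arma::vec &ub,
                           const arma::vec &cobj, bool maximize) {
  const int m = A.n_rows, n = A.n_cols;
  SimplexState st;
  st.m = m; st.N = n + m;
  st.A = join_rows(A, eye(m, m));
  st.lb = join_cols(lb, zeros(m));
  st.ub = join_cols(ub, vec(m, fill::value(datum::inf)));
  st.x = zeros(st.N);
  st.nstat = ivec(st.N, fill::zeros);

  // structurals nonbasic at the finite bound of smaller magnitude
  // (a nonbasic variable must sit exactly at a bound)
  for (int j = 0; j < n; ++j) {
    bool at_lb = std::fabs(lb[j]) <= std::fabs(ub[j]);
    st.nstat[j] = at_lb ? -1 : +1;
    st.x[j] = at_lb ? lb[j] : ub[j];
  }
  // artificial columns absorb the residual
  vec r = b;
  for (int j = 0; j < n; ++j) if (st.x[j] != 0.0) r -= A.col(j) * st.x[j];
  st.basis = uvec(m);
  for (int i = 0; i < m; ++i) {
    if (r[i] < 0) st.A(i, n + i) = -1.0;
    st.x[n + i] = std::fabs(r[i]);
    st.basis[i] = n + i;
  }

  // phase 1: minimize artificial mass
  st.c = join_cols(zeros(n), ones(m));
  int code = simplex_phase(st, b);
  double art = 0.0;
  for (int i = 0; i < m; ++i) art += st.x[n + i];
  std::string status;
  if (code == 1) status = "singular";
  else if (code == 2) status = "maxit";
  else if (art > FEAS_TOL * std::max(1.0, norm(b, "inf"))) status = "infeasible";
  else {
    // phase 2: pin artificials at zero, optimize the true objective
    for (int i = 0; i < m; ++i) st.ub[n + i] = 0.0;
    st.c = join_cols(maximize ? vec(-cobj) : vec(cobj), zeros(m));
    code = simplex_phase(st, b);
    status = (code == 0) ? "optimal" : (code == 1 ? "singular" : "maxit");
  }

  vec xs = st.x.head(n);
  double obj = dot(cobj, xs);
  return Rcpp::List::create(Rcpp::Named("status") = status,
                            Rcpp::Named("x") = xs,
                            Rcpp::Named("objval") = obj,
                            Rcpp::Named("artificial") = art);
}
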