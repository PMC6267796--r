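// Per-frame static-optimization solver.
//
// Each frame is the convex quadratic program
//   minimize   sum_i (F_i / w_i)^2
//   subject to A F = b,   0 <= F_i <= u_i
// with diagonal Hessian (w_i > 0 are the objective weights: F_MAX for the
// activation-squared objective, PCSA for the stress-squared objective),
// A the signed moment-arm matrix (n_joints x n_muscles) and b the joint
// moments to reproduce. Muscles with u_i <= 0 (or w_i <= 0) are fixed at 0.
//
// The solver maximizes the concave dual
//   q(lambda) = min_{0<=F<=u} [ sum d_i F_i^2 / 2 - lambda' (A F - b) ],
//   d_i = 2 / w_i^2 (any positive scaling of the objective),
// whose inner minimizer is the clipped F_i(lambda) = clip(w_i^2/2 *
// (A'lambda)_i * 2/..., 0, u_i); gradient is b - A F(lambda). Newton ascent
// with Armijo backtracking converges for this piecewise-quadratic concave
// function. If the program is infeasible the dual is unbounded; a bounded
// least-squares pass (cyclic coordinate descent on ||AF - b||^2 over the
// box) certifies infeasibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static bool solve3(const double J[3][3], const double g[3], double out[3]) {
  // solve J * out = g for symmetric 3x3 J via Cramer/adjugate
  double det =
    J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
    J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
    J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
  if (std::fabs(det) < 1e-300) return false;
  double inv[3][3];
  inv[0][0] =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]) / det;
  inv[0][1] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]) / det;
  inv[0][2] =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]) / det;
  inv[1][0] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]) / det;
  inv[1][1] =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]) / det;
  inv[1][2] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]) / det;
  inv[2][0] =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]) / det;
  inv[2][1] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]) / det;
  inv[2][2] =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]) / det;
  for (int r = 0; r < 3; ++r)
    out[r] = inv[r][0] * g[0] + inv[r][1] * g[1] + inv[r][2] * g[2];
  return true;
}

// [[Rcpp::export]]
List qp_solve_batch(NumericMatrix A, NumericMatrix bmat, NumericMatrix umat,
                    NumericMatrix wmat, double tol = 1e-9, int max_iter = 200) {
  const int nj = A.nrow();        // joints (<= 3)
  const int nm = A.ncol();        // muscles
  const int N = bmat.ncol();      // frames
  if (nj > 3) stop("at most 3 equality constraints supported");
  if (bmat.nrow() != nj || umat.nrow() != nm || wmat.nrow() != nm ||
      umat.ncol() != N || wmat.ncol() != N)
    stop("inconsistent problem dimensions");

  NumericMatrix F(nm, N);
  LogicalVector feasible(N);
  NumericVector objective(N);
  NumericVector residual(N);

  std::vector<double> a(nj * nm);
  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < nm; ++i) a[j * nm + i] = A(j, i);

  std::vector<double> w2(nm), u(nm), f(nm);
  std::vector<bool> fixed(nm);

  for (int n = 0; n < N; ++n) {
    double b[3] = {0, 0, 0};
    double bscale = 1.0;
    for (int j = 0; j < nj; ++j) {
      b[j] = bmat(j, n);
      bscale = std::max(bscale, std::fabs(b[j]));
    }
    const double gtol = tol * bscale;

    for (int i = 0; i < nm; ++i) {
      u[i] = umat(i, n);
      double w = wmat(i, n);
      fixed[i] = !(u[i] > 0.0) || !(w > 0.0);
      w2[i] = fixed[i] ? 0.0 : 0.5 * w * w;   // F_i = clip(w2 * s_i, 0, u)
    }

    double lam[3] = {0, 0, 0};
    // dual objective value at lambda for Armijo
    auto eval = [&](const double l[3], double g[3]) {
      double q = l[0] * b[0] + (nj > 1 ? l[1] * b[1] : 0.0) +
                 (nj > 2 ? l[2] * b[2] : 0.0);
      for (int j = 0; j < nj; ++j) g[j] = b[j];
      for (int i = 0; i < nm; ++i) {
        if (fixed[i]) { f[i] = 0.0; continue; }
        double s = 0.0;
        for (int j = 0; j < nj; ++j) s += a[j * nm + i] * l[j];
        double fi = w2[i] * s;
        if (fi < 0.0) fi = 0.0; else if (fi > u[i]) fi = u[i];
        f[i] = fi;
        // inner Lagrangian term: fi^2/(2*w2) - s*fi  (d = 1/w2)
        q += (w2[i] > 0.0 ? fi * fi / (2.0 * w2[i]) : 0.0) - s * fi;
        for (int j = 0; j < nj; ++j) g[j] -= a[j * nm + i] * fi;
      }
      return q;
    };

    double g[3];
    double q = eval(lam, g);
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      double gmax = 0.0;
      for (int j = 0; j < nj; ++j) gmax = std::max(gmax, std::fabs(g[j]));
      if (gmax <= gtol) { ok = true; break; }

      // generalized Hessian of -q: sum over strictly-free muscles
      double J[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      double trace = 0.0;
      for (int i = 0; i < nm; ++i) {
        if (fixed[i] || f[i] <= 0.0 || f[i] >= u[i]) continue;
        for (int j = 0; j < nj; ++j)
          for (int k = 0; k < nj; ++k)
            J[j][k] += w2[i] * a[j * nm + i] * a[k * nm + i];
      }
      for (int j = 0; j < nj; ++j) trace += J[j][j];
      double reg = 1e-10 * (trace > 0 ? trace : 1.0);
      for (int j = 0; j < nj; ++j) J[j][j] += reg;
      // pad unused dimensions for the 3x3 solve
      for (int j = nj; j < 3; ++j) J[j][j] = 1.0;

      double dir[3] = {0, 0, 0};
      double grhs[3] = {g[0], nj > 1 ? g[1] : 0.0, nj > 2 ? g[2] : 0.0};
      if (!solve3(J, grhs, dir)) { for (int j = 0; j < nj; ++j) dir[j] = g[j]; }

      double slope = 0.0;
      for (int j = 0; j < nj; ++j) slope += g[j] * dir[j];
      if (slope <= 0.0) { for (int j = 0; j < nj; ++j) dir[j] = g[j];
        slope = g[0] * g[0] + g[1] * g[1] + g[2] * g[2]; }

      double step = 1.0, qn;
      double lnew[3];
      double gn[3];
      bool moved = false;
      for (int ls = 0; ls < 60; ++ls) {
        for (int j = 0; j < nj; ++j) lnew[j] = lam[j] + step * dir[j];
        qn = eval(lnew, gn);
        if (qn >= q + 1e-4 * step * slope) { moved = true; break; }
        step *= 0.5;
      }
      if (!moved) break;  // numerically stuck at a kink; classify below
      for (int j = 0; j < nj; ++j) { lam[j] = lnew[j]; g[j] = gn[j]; }
      q = qn;
    }

    if (!ok) {
      // bounded least squares ||AF - b||^2 over the box by cyclic
      // coordinate descent, to separate infeasibility from a solver stall
      std::vector<double> x(nm, 0.0);
      double r[3] = {b[0], nj > 1 ? b[1] : 0.0, nj > 2 ? b[2] : 0.0};
      for (int sweep = 0; sweep < 20000; ++sweep) {
        double change = 0.0;
        for (int i = 0; i < nm; ++i) {
          if (fixed[i] && !(u[i] > 0.0)) continue;
          double num = 0.0, den = 0.0;
          for (int j = 0; j < nj; ++j) {
            num += a[j * nm + i] * r[j];
            den += a[j * nm + i] * a[j * nm + i];
          }
          if (den <= 0.0) continue;
          double xi = x[i] + num / den;
          if (xi < 0.0) xi = 0.0; else if (xi > u[i]) xi = u[i];
          double dx = xi - x[i];
          if (dx != 0.0) {
            for (int j = 0; j < nj; ++j) r[j] -= a[j * nm + i] * dx;
            x[i] = xi;
            change += std::fabs(dx);
          }
        }
        if (change <= 1e-14 * bscale) break;
      }
      double rmax = 0.0;
      for (int j = 0; j < nj; ++j) rmax = std::max(rmax, std::fabs(r[j]));
      if (rmax <= 1e-6 * std::max(1.0, bscale)) {
        // feasible but the dual ascent stalled: extremely rare; report the
        // BLS point as a non-optimal feasible fallback flagged infeasible=false
        for (int i = 0; i < nm; ++i) f[i] = x[i];
        ok = true;
      }
    }

    double obj = 0.0, rr = 0.0;
    double res[3] = {b[0], nj > 1 ? b[1] : 0.0, nj > 2 ? b[2] : 0.0};
    for (int i = 0; i < nm; ++i) {
      F(i, n) = ok ? f[i] : NA_REAL;
      if (ok) {
        double w = wmat(i, n);
        if (w > 0.0) obj += (f[i] / w) * (f[i] / w);
        for (int j = 0; j < nj; ++j) res[j] -= a[j * nm + i] * f[i];
      }
    }
    for (int j = 0; j < nj; ++j) rr = std::max(rr, std::fabs(res[j]));
    feasible[n] = ok;
    objective[n] = ok ? obj : NA_REAL;
    residual[n] = ok ? rr : NA_REAL;
  }

  return List::create(_["F"] = F, _["feasible"] = feasible,
                      _["objective"] = objective, _["residual"] = residual);
}
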