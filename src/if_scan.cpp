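// Grid scan for the intrinsic-frequency L2 solver.
//
// For fixed (omega1, omega2) the objective is linear-least-squares in
// (a1, b1, a2, b2, c) subject to two linear equality constraints
// (continuity at the notch, periodicity over the unit cycle). The scan
// eliminates a1 and b1 through the constraints and solves the reduced 3x3
// normal equations at every frequency pair, reusing per-frequency trig
// moments so a full rectangle costs O(n_grid * n_samples + n_pairs).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Moments {
  // sums over one regime's samples for a single omega
  double cc, cs, ss, c, s, pc, ps;
};

Moments regime_moments(const vec& tau, const vec& p, double w) {
  Moments m{};
  const uword n = tau.n_elem;
  for (uword k = 0; k < n; ++k) {
    const double ck = std::cos(w * tau[k]);
    const double sk = std::sin(w * tau[k]);
    m.cc += ck * ck;
    m.cs += ck * sk;
    m.ss += sk * sk;
    m.c += ck;
    m.s += sk;
    m.pc += p[k] * ck;
    m.ps += p[k] * sk;
  }
  return m;
}

// Elimination matrix M (5x3) expressing theta = (a1,b1,a2,b2,c) through
// gamma = (a2,b2,c):
//   a1 = a2*cos(w2) + b2*sin(w2)                       (periodicity, T=1)
//   b1 = [a2*(cos(w2*T0) - cos(w2)*cos(w1*T0))
//        + b2*(sin(w2*T0) - sin(w2)*cos(w1*T0))] / sin(w1*T0)
bool elimination(double w1, double w2, double T0, mat& M) {
  const double s1T0 = std::sin(w1 * T0);
  if (std::abs(s1T0) < 1e-8) return false;
  const double c1T0 = std::cos(w1 * T0);
  const double cw2 = std::cos(w2), sw2 = std::sin(w2);
  const double c2T0 = std::cos(w2 * T0), s2T0 = std::sin(w2 * T0);
  M.zeros(5, 3);
  M(0, 0) = cw2;
  M(0, 1) = sw2;
  M(1, 0) = (c2T0 - cw2 * c1T0) / s1T0;
  M(1, 1) = (s2T0 - sw2 * c1T0) / s1T0;
  M(2, 0) = 1.0;
  M(3, 1) = 1.0;
  M(4, 2) = 1.0;
  return true;
}

// Constraint matrix for the generic nullspace fallback (sin(w1*T0) ~ 0).
mat constraint_matrix(double w1, double w2, double T0) {
  mat C(2, 5, fill::zeros);
  C(0, 0) = std::cos(w1 * T0);
  C(0, 1) = std::sin(w1 * T0);
  C(0, 2) = -std::cos(w2 * T0);
  C(0, 3) = -std::sin(w2 * T0);
  C(1, 0) = 1.0;
  C(1, 2) = -std::cos(w2);
  C(1, 3) = -std::sin(w2);
  return C;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_if_scan(const arma::vec& values, const arma::vec& tau,
                       double T0, const arma::vec& w1s, const arma::vec& w2s,
                       bool return_grid = false) {
  const uvec sys = find(tau < T0);
  const uvec dia = find(tau >= T0);
  const vec tau_s = tau.elem(sys), p_s = values.elem(sys);
  const vec tau_d = tau.elem(dia), p_d = values.elem(dia);
  const double n_s = static_cast<double>(tau_s.n_elem);
  const double n_d = static_cast<double>(tau_d.n_elem);
  const double sum_p = accu(p_s) + accu(p_d);
  const double sum_pp = dot(p_s, p_s) + dot(p_d, p_d);

  std::vector<Moments> ms(w1s.n_elem), md(w2s.n_elem);
  for (uword i = 0; i < w1s.n_elem; ++i) ms[i] = regime_moments(tau_s, p_s, w1s[i]);
  for (uword j = 0; j < w2s.n_elem; ++j) md[j] = regime_moments(tau_d, p_d, w2s[j]);

  double best_obj = datum::inf;
  double best_w1 = w1s[0], best_w2 = w2s[0];
  mat A(5, 5), M, B;
  vec g(5), h, gam, theta;
  long n_flagged = 0;
  mat grid;
  if (return_grid) grid.set_size(w1s.n_elem, w2s.n_elem);

  for (uword i = 0; i < w1s.n_elem; ++i) {
    const Moments& S = ms[i];
    for (uword j = 0; j < w2s.n_elem; ++j) {
      const Moments& D = md[j];
      A.zeros();
      A(0, 0) = S.cc; A(0, 1) = S.cs; A(0, 4) = S.c;
      A(1, 0) = S.cs; A(1, 1) = S.ss; A(1, 4) = S.s;
      A(2, 2) = D.cc; A(2, 3) = D.cs; A(2, 4) = D.c;
      A(3, 2) = D.cs; A(3, 3) = D.ss; A(3, 4) = D.s;
      A(4, 0) = S.c;  A(4, 1) = S.s;  A(4, 2) = D.c; A(4, 3) = D.s;
      A(4, 4) = n_s + n_d;
      g[0] = S.pc; g[1] = S.ps; g[2] = D.pc; g[3] = D.ps; g[4] = sum_p;

      bool ok = elimination(w1s[i], w2s[j], T0, M);
      if (!ok) {
        mat C = constraint_matrix(w1s[i], w2s[j], T0);
        M = null(C);
        if (M.n_cols != 3) {
          ++n_flagged;
          if (return_grid) grid(i, j) = datum::inf;
          continue;
        }
      }
      B = M.t() * A * M;
      h = M.t() * g;
      if (!solve(gam, B, h, solve_opts::no_approx)) {
        gam = pinv(B) * h;
        ++n_flagged;
      }
      theta = M * gam;
      double obj = sum_pp - 2.0 * dot(g, theta) + dot(theta, A * theta);
      if (obj < 0) obj = 0;
      if (return_grid) grid(i, j) = obj;
      if (obj < best_obj) {
        best_obj = obj;
        best_w1 = w1s[i];
        best_w2 = w2s[j];
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("omega1_hat") = best_w1,
    Rcpp::Named("omega2_hat") = best_w2,
    Rcpp::Named("objective") = best_obj,
    Rcpp::Named("n_evals") = static_cast<double>(w1s.n_elem) * w2s.n_elem,
    Rcpp::Named("n_flagged") = n_flagged);
  if (return_grid) out["grid"] = grid;
  return out;
}
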