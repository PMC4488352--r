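// Core geometry kernels: helical-curve evaluation, closest-point search,
// Kabsch superposition, and the exhaustive (r, p) grid search that fits a
// helical curve to one quadruple of guide atoms.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Curve-frame point at phase tau for a helix with radius r, rise-per-residue
// p and turn angle t: (r sin tau, r cos tau, (p/t) tau).
static inline arma::vec3 frame_point(double r, double p, double t, double tau) {
  arma::vec3 q;
  q[0] = r * std::sin(tau);
  q[1] = r * std::cos(tau);
  q[2] = (p / t) * tau;
  return q;
}

static inline arma::vec3 world_point(double r, double p, double t,
                                     const arma::mat &R, const arma::vec &r0,
                                     double tau) {
  return r0 + R * frame_point(r, p, t, tau);
}

static inline double dist2_at(double r, double p, double t,
                              const arma::mat &R, const arma::vec &r0,
                              const arma::vec &q, double tau) {
  arma::vec3 d = world_point(r, p, t, R, r0, tau) - q;
  return arma::dot(d, d);
}

// Golden-section minimisation of the squared distance on [a, b].
static double golden_min(double r, double p, double t, const arma::mat &R,
                         const arma::vec &r0, const arma::vec &q,
                         double a, double b, double tol) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double x1 = b - gr * (b - a);
  double x2 = a + gr * (b - a);
  double f1 = dist2_at(r, p, t, R, r0, q, x1);
  double f2 = dist2_at(r, p, t, R, r0, q, x2);
  while ((b - a) > tol) {
    if (f1 <= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = dist2_at(r, p, t, R, r0, q, x1);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = dist2_at(r, p, t, R, r0, q, x2);
    }
  }
  return 0.5 * (a + b);
}

// Coarse scan + golden-section refinement on [lo, hi].
static void closest_on_window(double r, double p, double t,
                              const arma::mat &R, const arma::vec &r0,
                              const arma::vec &q, double lo, double hi,
                              int n_coarse, double tol,
                              double &best_tau, double &best_d2) {
  double h = (hi - lo) / n_coarse;
  best_tau = lo;
  best_d2 = dist2_at(r, p, t, R, r0, q, lo);
  for (int i = 1; i <= n_coarse; ++i) {
    double tau = lo + i * h;
    double d2 = dist2_at(r, p, t, R, r0, q, tau);
    if (d2 < best_d2) { best_d2 = d2; best_tau = tau; }
  }
  double a = std::max(lo, best_tau - h);
  double b = std::min(hi, best_tau + h);
  double tau = golden_min(r, p, t, R, r0, q, a, b, tol);
  double d2 = dist2_at(r, p, t, R, r0, q, tau);
  if (d2 < best_d2) { best_d2 = d2; best_tau = tau; }
}

// Kabsch: proper rotation R and translation s minimising ||R m_i + s - f_i||.
static void kabsch_core(const arma::mat &moving, const arma::mat &fixed,
                        arma::mat &R, arma::vec &s, double &rmsd,
                        bool &degenerate) {
  arma::rowvec cm = arma::mean(moving, 0);
  arma::rowvec cf = arma::mean(fixed, 0);
  arma::mat M = moving.each_row() - cm;
  arma::mat F = fixed.each_row() - cf;
  arma::mat H = M.t() * F;   // 3x3 covariance
  arma::mat U, V;
  arma::vec sv;
  arma::svd(U, sv, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0.0) ? -1.0 : 1.0;
  R = V * D * U.t();
  s = cf.t() - R * cm.t();
  // ambiguous when the two smallest singular values coincide (to scale)
  double scale = sv(0) > 0 ? sv(0) : 1.0;
  degenerate = (sv(1) - sv(2)) / scale < 1e-9 && d < 0.0;
  arma::mat res = (M * R.t()) - F;
  rmsd = std::sqrt(arma::accu(arma::square(res)) / fixed.n_rows);
}

// [[Rcpp::export(name = ".cpp_helix_points")]]
arma::mat cpp_helix_points(double r, double p, double t,
                           const arma::mat &R, const arma::vec &r0,
                           const arma::vec &phases) {
  arma::mat out(phases.n_elem, 3);
  for (arma::uword i = 0; i < phases.n_elem; ++i)
    out.row(i) = world_point(r, p, t, R, r0, phases[i]).t();
  return out;
}

// [[Rcpp::export(name = ".cpp_closest_point")]]
List cpp_closest_point(double r, double p, double t,
                       const arma::mat &R, const arma::vec &r0,
                       const arma::vec &query, double lo, double hi,
                       int n_per_turn, double tol) {
  double width = hi - lo;
  int n = std::max(32, (int)std::ceil(n_per_turn * width / (2.0 * M_PI)));
  double tau, d2;
  closest_on_window(r, p, t, R, r0, query, lo, hi, n, tol, tau, d2);
  arma::vec3 pt = world_point(r, p, t, R, r0, tau);
  return List::create(_["phase"] = tau, _["distance"] = std::sqrt(d2),
                      _["point"] = NumericVector(pt.begin(), pt.end()));
}

// Brute-force scan used as an independent oracle in tests: no refinement,
// just the minimum over n uniformly spaced phases.
// [[Rcpp::export(name = ".cpp_closest_point_brute")]]
List cpp_closest_point_brute(double r, double p, double t,
                             const arma::mat &R, const arma::vec &r0,
                             const arma::vec &query, double lo, double hi,
                             int n) {
  double best_tau = lo, best_d2 = dist2_at(r, p, t, R, r0, query, lo);
  double h = (hi - lo) / n;
  for (int i = 1; i <= n; ++i) {
    double tau = lo + i * h;
    double d2 = dist2_at(r, p, t, R, r0, query, tau);
    if (d2 < best_d2) { best_d2 = d2; best_tau = tau; }
  }
  return List::create(_["phase"] = best_tau,
                      _["distance"] = std::sqrt(best_d2));
}

// [[Rcpp::export(name = ".cpp_kabsch")]]
List cpp_kabsch(const arma::mat &moving, const arma::mat &fixed) {
  arma::mat R;
  arma::vec s;
  double rmsd;
  bool degenerate;
  kabsch_core(moving, fixed, R, s, rmsd, degenerate);
  return List::create(_["rotation"] = R, _["translation"] = s,
                      _["rmsd"] = rmsd, _["degenerate"] = degenerate);
}

// Exhaustive grid search over [r_m - dr, r_m + dr] x [p_m - dp, p_m + dp]
// (spacing `step`, grid centred on the analytic seed). For each feasible
// (r, p): turn angle from the mean consecutive distance, 4-point ideal helix
// at phases (0, t, 2t, 3t), Kabsch superposition onto the quadruple, then the
// closest-point RMSD d_q ranks the grid point. First strict minimum wins,
// scanning r then p in ascending order.
// [[Rcpp::export(name = ".cpp_fit_quadruple")]]
List cpp_fit_quadruple(const arma::mat &atoms, double r_m, double p_m,
                       double t_sign, double delta_r, double delta_p,
                       double step, int n_grid_coarse, int n_final_coarse,
                       double tol) {
  const int Kr = (int)std::round(delta_r / step);
  const int Kp = (int)std::round(delta_p / step);
  arma::vec3 d3;
  for (int k = 0; k < 3; ++k)
    d3[k] = arma::norm(atoms.row(k + 1) - atoms.row(k));
  const double dbar = arma::mean(d3);

  double best_dq = R_PosInf;
  double best_r = NA_REAL, best_p = NA_REAL, best_t = NA_REAL;
  arma::mat best_R;
  arma::vec best_s;
  double best_corr = NA_REAL;
  bool any_feasible = false;

  arma::mat ideal(4, 3);
  for (int ir = -Kr; ir <= Kr; ++ir) {
    double r = r_m + ir * step;
    if (r <= 1e-9) continue;
    for (int ip = -Kp; ip <= Kp; ++ip) {
      double p = p_m + ip * step;
      double u = dbar * dbar - p * p;
      if (u < 0.0) continue;                    // infeasible pitch
      double sarg = std::sqrt(u) / (2.0 * r);
      if (sarg > 1.0) continue;                 // infeasible radius
      double t_abs = 2.0 * std::asin(sarg);
      if (t_abs < 1e-8) continue;
      double t = t_sign * t_abs;
      for (int k = 0; k < 4; ++k) {
        ideal(k, 0) = r * std::sin(k * t);
        ideal(k, 1) = r * std::cos(k * t);
        ideal(k, 2) = p * k;
      }
      arma::mat R;
      arma::vec s;
      double corr_rmsd;
      bool degen;
      kabsch_core(ideal, atoms, R, s, corr_rmsd, degen);
      // closest-point RMSD of the 4 atoms on the placed curve
      double ss = 0.0;
      for (int k = 0; k < 4; ++k) {
        double tau, d2;
        closest_on_window(r, p, t, R, s, atoms.row(k).t(),
                          k * t - M_PI, k * t + M_PI, n_grid_coarse,
                          tol, tau, d2);
        ss += d2;
        if (ss >= 4.0 * best_dq * best_dq) break;  // cannot beat the best
      }
      double dq = std::sqrt(ss / 4.0);
      any_feasible = true;
      if (dq < best_dq) {
        best_dq = dq; best_r = r; best_p = p; best_t = t;
        best_R = R; best_s = s; best_corr = corr_rmsd;
      }
    }
  }
  if (!any_feasible)
    return List::create(_["ok"] = false);

  // final pass at the stated closest-point solver density
  arma::vec phases(4), dists(4);
  double ss = 0.0;
  for (int k = 0; k < 4; ++k) {
    double tau, d2;
    closest_on_window(best_r, best_p, best_t, best_R, best_s,
                      atoms.row(k).t(), k * best_t - M_PI, k * best_t + M_PI,
                      n_final_coarse, tol, tau, d2);
    phases[k] = tau;
    dists[k] = std::sqrt(d2);
    ss += d2;
  }
  return List::create(_["ok"] = true, _["r"] = best_r, _["p"] = best_p,
                      _["t"] = best_t, _["rotation"] = best_R,
                      _["origin"] = NumericVector(best_s.begin(), best_s.end()),
                      _["delta"] = std::sqrt(ss / 4.0),
                      _["corr_rmsd"] = best_corr,
                      _["atom_phases"] = NumericVector(phases.begin(), phases.end()),
                      _["atom_dists"] = NumericVector(dists.begin(), dists.end()));
}
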