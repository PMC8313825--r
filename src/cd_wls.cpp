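#include <Rcpp.h>
using namespace Rcpp;

// Weighted-least-squares lasso coordinate descent, the inner solver of the
// penalized Cox path. Minimizes (1/2n) sum_i w_i (z_i - x_i'beta)^2 +
// lambda * ||beta||_1 by cyclic descent over an active set, admitting new
// coordinates via a full KKT screen between cycles. The stopping criterion
// within a cycle is the largest weighted squared coefficient change, the
// natural objective-scale measure for a quadratic problem.
static void cd_wls_core(const double* X, int n, int p, const double* w,
                        const double* z, double* beta, double lambda,
                        double tol, int max_round, std::vector<double>& r,
                        std::vector<double>& wxx,
                        std::vector<int>& active,
                        std::vector<char>& in_active) {
  for (int i = 0; i < n; ++i) r[i] = z[i];
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double bj = beta[j];
      const double* xj = X + (size_t)j * n;
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * bj;
    }
  }
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = X + (size_t)j * n;
    for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
    wxx[j] = s / n;
  }
  active.clear();
  std::fill(in_active.begin(), in_active.end(), 0);
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) { active.push_back(j); in_active[j] = 1; }
  }
  for (int round = 0; round < max_round; ++round) {
    for (int sweep = 0; sweep < 2000; ++sweep) {
      double maxdel = 0.0;
      for (size_t a = 0; a < active.size(); ++a) {
        const int j = active[a];
        if (wxx[j] <= 0.0) continue;
        const double* xj = X + (size_t)j * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += w[i] * xj[i] * r[i];
        const double num = s / n + wxx[j] * beta[j];
        double bnew = 0.0;
        const double az = std::fabs(num) - lambda;
        if (az > 0.0) bnew = (num > 0.0 ? az : -az) / wxx[j];
        const double del = bnew - beta[j];
        if (del != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * del;
          beta[j] = bnew;
          const double wdel = wxx[j] * del * del;
          if (wdel > maxdel) maxdel = wdel;
        }
      }
      if (maxdel < tol || active.empty()) break;
    }
    // KKT screen over every zero coordinate
    bool added = false;
    for (int j = 0; j < p; ++j) {
      if (in_active[j] || beta[j] != 0.0) continue;
      const double* xj = X + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * xj[i] * r[i];
      if (std::fabs(s) / n > lambda * (1.0 + 1e-12) + 1e-12) {
        active.push_back(j);
        in_active[j] = 1;
        added = true;
      }
    }
    if (!added) break;
  }
}

// X is the standardized design (n x p), w the positive working weights,
// z the working response; beta0 is the warm start.
// [[Rcpp::export]]
NumericVector cd_wls(const NumericMatrix& X, const NumericVector& w,
                     const NumericVector& z, const NumericVector& beta0,
                     double lambda, double tol, int max_round) {
  const int n = X.nrow();
  const int p = X.ncol();
  NumericVector beta = clone(beta0);
  std::vector<double> r(n), wxx(p);
  std::vector<int> active;
  std::vector<char> in_active(p, 0);
  cd_wls_core(REAL(X), n, p, REAL(w), REAL(z), REAL(beta), lambda, tol,
              max_round, r, wxx, active, in_active);
  return beta;
}

// Breslow per-sample gradient g and diagonal Hessian h of the Cox log
// partial likelihood with respect to the linear predictor, on rows sorted
// by decreasing time. Returns the log partial likelihood. Index arrays are
// 0-based; grp maps each row to its tie group, gend holds the last row of
// each group, d the death count per group, eg the groups with deaths, and
// didx the rows that are deaths.
static double cox_eta_deriv_core(int n, int ngrp, const double* eta,
                                 const int* event, const int* grp,
                                 const int* gend, const int* d,
                                 const std::vector<int>& eg,
                                 const std::vector<int>& didx,
                                 std::vector<double>& w,
                                 std::vector<double>& S0,
                                 std::vector<double>& A,
                                 std::vector<double>& B,
                                 double* g, double* h) {
  double cc = eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > cc) cc = eta[i];
  double cw = 0.0;
  for (int i = 0; i < n; ++i) { w[i] = std::exp(eta[i] - cc); }
  {
    int k = 0;
    for (int i = 0; i < n; ++i) {
      cw += w[i];
      if (i == gend[k]) { S0[k] = cw; ++k; }
    }
  }
  std::fill(A.begin(), A.end(), 0.0);
  std::fill(B.begin(), B.end(), 0.0);
  for (size_t m = 0; m < eg.size(); ++m) {
    const int k = eg[m];
    A[k] = d[k] / S0[k];
    B[k] = d[k] / (S0[k] * S0[k]);
  }
  for (int k = ngrp - 2; k >= 0; --k) { A[k] += A[k + 1]; B[k] += B[k + 1]; }
  for (int i = 0; i < n; ++i) {
    const double wa = w[i] * A[grp[i]];
    g[i] = event[i] - wa;
    double hi = wa - w[i] * w[i] * B[grp[i]];
    h[i] = (hi > 1e-10) ? hi : 1e-10;
  }
  double ll = 0.0;
  for (size_t m = 0; m < didx.size(); ++m) ll += eta[didx[m]];
  for (size_t m = 0; m < eg.size(); ++m) {
    const int k = eg[m];
    ll -= d[k] * (std::log(S0[k]) + cc);
  }
  return ll;
}

// Full L1-penalized Cox coefficient path over a decreasing lambda grid,
// warm-starting each lambda at the previous solution. Each lambda is
// solved by outer quadratic approximation of the partial likelihood plus
// the inner weighted-least-squares coordinate descent above. The outer
// loop stops when the exact-subgradient condition holds on every zero
// coordinate and the coefficient step is below outer_tol, or when the
// penalized objective stalls. X is the standardized design in sorted-row
// order; index arguments are 1-based as produced by the R-side
// preparation.
// [[Rcpp::export]]
NumericMatrix lasso_path_cox(const NumericMatrix& X,
                             const IntegerVector& event,
                             const IntegerVector& grp,
                             const IntegerVector& gend,
                             const IntegerVector& d,
                             const IntegerVector& egroups,
                             const IntegerVector& death_idx,
                             const NumericVector& lambda,
                             double outer_tol, int max_outer,
                             double inner_tol, int inner_round) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int ngrp = gend.size();
  const int nlam = lambda.size();
  const double* Xp = REAL(X);

  std::vector<int> ev(n), gr(n), ge(ngrp), dd(ngrp), eg, didx;
  for (int i = 0; i < n; ++i) { ev[i] = event[i]; gr[i] = grp[i] - 1; }
  for (int k = 0; k < ngrp; ++k) { ge[k] = gend[k] - 1; dd[k] = d[k]; }
  for (int m = 0; m < egroups.size(); ++m) eg.push_back(egroups[m] - 1);
  for (int m = 0; m < death_idx.size(); ++m) didx.push_back(death_idx[m] - 1);

  std::vector<double> w(n), S0(ngrp), A(ngrp), B(ngrp);
  std::vector<double> g(n), h(n), z(n), eta(n, 0.0), r(n), wxx(p);
  std::vector<double> beta(p, 0.0), beta_old(p);
  std::vector<int> active;
  std::vector<char> in_active(p, 0);
  NumericMatrix out(p, nlam);

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    double obj_prev = R_PosInf;
    double delta = R_PosInf;
    for (int it = 0; it < max_outer; ++it) {
      const double ll = cox_eta_deriv_core(n, ngrp, eta.data(), ev.data(),
                                           gr.data(), ge.data(), dd.data(),
                                           eg, didx, w, S0, A, B,
                                           g.data(), h.data());
      double l1 = 0.0;
      for (int j = 0; j < p; ++j) l1 += std::fabs(beta[j]);
      const double obj = -ll / n + lam * l1;
      if (it > 0) {
        double viol0 = 0.0;
        for (int j = 0; j < p; ++j) {
          if (beta[j] != 0.0) continue;
          const double* xj = Xp + (size_t)j * n;
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += xj[i] * g[i];
          const double v = std::fabs(s) - lam * n;
          if (v > viol0) viol0 = v;
        }
        if ((viol0 <= 1e-9 * n && delta < outer_tol) ||
            std::fabs(obj_prev - obj) < 1e-9 * (std::fabs(obj) + 1.0)) break;
      }
      obj_prev = obj;
      for (int i = 0; i < n; ++i) z[i] = eta[i] + g[i] / h[i];
      std::copy(beta.begin(), beta.end(), beta_old.begin());
      cd_wls_core(Xp, n, p, h.data(), z.data(), beta.data(), lam,
                  inner_tol, inner_round, r, wxx, active, in_active);
      delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double dj = std::fabs(beta[j] - beta_old[j]);
        if (dj > delta) delta = dj;
      }
      std::fill(eta.begin(), eta.end(), 0.0);
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0) {
          const double* xj = Xp + (size_t)j * n;
          const double bj = beta[j];
          for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
        }
      }
    }
    for (int j = 0; j < p; ++j) out(j, l) = beta[j];
  }
  return out;
}

// Log partial likelihood, score, and observed information of the Cox model
// at beta with the Efron/Breslow tie correction expressed through
// per-death expansion rows (frac = l/d_k; all-zero frac gives Breslow).
// Rows of X are sorted by decreasing time; index arguments are 1-based.
// [[Rcpp::export]]
List cox_deriv_cpp(const NumericMatrix& X, const NumericVector& beta,
                   const IntegerVector& gend, const IntegerVector& kk,
                   const NumericVector& frac, const IntegerVector& death_idx,
                   const IntegerVector& death_grp, int ngrp,
                   bool want_info) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int nexp = kk.size();
  const int nd = death_idx.size();
  std::vector<double> eta(n, 0.0), w(n);
  for (int j = 0; j < p; ++j) {
    const double bj = beta[j];
    if (bj == 0.0) continue;
    for (int i = 0; i < n; ++i) eta[i] += X(i, j) * bj;
  }
  double cc = eta.empty() ? 0.0 : eta[0];
  for (int i = 1; i < n; ++i) if (eta[i] > cc) cc = eta[i];
  for (int i = 0; i < n; ++i) w[i] = std::exp(eta[i] - cc);
  std::vector<double> S0(ngrp), psi(ngrp, 0.0);
  {
    double c = 0.0; int k = 0;
    for (int i = 0; i < n; ++i) {
      c += w[i];
      if (k < ngrp && i == gend[k] - 1) { S0[k] = c; ++k; }
    }
  }
  for (int m = 0; m < nd; ++m) psi[death_grp[m] - 1] += w[death_idx[m] - 1];
  std::vector<double> denom(nexp);
  double ll = 0.0;
  for (int m = 0; m < nd; ++m) ll += eta[death_idx[m] - 1];
  for (int e = 0; e < nexp; ++e) {
    const int k = kk[e] - 1;
    denom[e] = S0[k] - frac[e] * psi[k];
    ll -= std::log(denom[e]) + cc;
  }
  if (p == 0) return List::create(Named("loglik") = ll);

  NumericVector U(p);
  std::vector<double> mu(static_cast<size_t>(nexp) * p);
  std::vector<double> S1(ngrp), s1(ngrp);
  for (int j = 0; j < p; ++j) {
    double c = 0.0; int k = 0;
    for (int i = 0; i < n; ++i) {
      c += w[i] * X(i, j);
      if (k < ngrp && i == gend[k] - 1) { S1[k] = c; ++k; }
    }
    std::fill(s1.begin(), s1.end(), 0.0);
    for (int m = 0; m < nd; ++m) {
      const int i = death_idx[m] - 1;
      s1[death_grp[m] - 1] += w[i] * X(i, j);
    }
    double usum = 0.0;
    for (int m = 0; m < nd; ++m) usum += X(death_idx[m] - 1, j);
    for (int e = 0; e < nexp; ++e) {
      const int k = kk[e] - 1;
      const double m_ej = (S1[k] - frac[e] * s1[k]) / denom[e];
      mu[static_cast<size_t>(e) * p + j] = m_ej;
      usum -= m_ej;
    }
    U[j] = usum;
  }
  if (!want_info) {
    return List::create(Named("loglik") = ll, Named("score") = U);
  }
  NumericMatrix info(p, p);
  std::vector<double> S2(ngrp), s2(ngrp);
  for (int j = 0; j < p; ++j) {
    for (int m2 = j; m2 < p; ++m2) {
      double c = 0.0; int k = 0;
      for (int i = 0; i < n; ++i) {
        c += w[i] * X(i, j) * X(i, m2);
        if (k < ngrp && i == gend[k] - 1) { S2[k] = c; ++k; }
      }
      std::fill(s2.begin(), s2.end(), 0.0);
      for (int m = 0; m < nd; ++m) {
        const int i = death_idx[m] - 1;
        s2[death_grp[m] - 1] += w[i] * X(i, j) * X(i, m2);
      }
      double acc = 0.0;
      for (int e = 0; e < nexp; ++e) {
        const int k = kk[e] - 1;
        acc += (S2[k] - frac[e] * s2[k]) / denom[e] -
               mu[static_cast<size_t>(e) * p + j] *
               mu[static_cast<size_t>(e) * p + m2];
      }
      info(j, m2) = acc;
      info(m2, j) = acc;
    }
  }
  return List::create(Named("loglik") = ll, Named("score") = U,
                      Named("info") = info);
}
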