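#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// State-dependent speciation-extinction (SSE) likelihood machinery.
//
// Joint ODE along a branch (time measured from the branch base toward the
// root), for each joint state i with speciation lambda_i, extinction mu_i
// and transition rates q_ij (diagonal zero):
//   dE_i/dt = mu_i - (lambda_i + mu_i + sum_j q_ij) E_i
//             + lambda_i E_i^2 + sum_j q_ij E_j
//   dD_i/dt = -(lambda_i + mu_i + sum_j q_ij) D_i
//             + 2 lambda_i E_i D_i + sum_j q_ij D_j
// Integrated with an adaptive Dormand-Prince 5(4) scheme; rates are
// constant along a branch so only the branch duration matters.

struct SSEPars {
  int m;
  std::vector<double> lam, mu, qrow; // qrow = row sums of Q
  std::vector<double> Q;             // m*m, Q[i + m*j] = rate i -> j
};

static void sse_rhs(const SSEPars& P, const double* y, double* dy) {
  const int m = P.m;
  const double* E = y;
  const double* D = y + m;
  for (int i = 0; i < m; ++i) {
    double sumQE = 0.0, sumQD = 0.0;
    for (int j = 0; j < m; ++j) {
      const double q = P.Q[i + m * j];
      if (q > 0.0) { sumQE += q * E[j]; sumQD += q * D[j]; }
    }
    const double tot = P.lam[i] + P.mu[i] + P.qrow[i];
    dy[i]     = P.mu[i] - tot * E[i] + P.lam[i] * E[i] * E[i] + sumQE;
    dy[m + i] = -tot * D[i] + 2.0 * P.lam[i] * E[i] * D[i] + sumQD;
  }
}

// Dormand-Prince 5(4). Returns false on step-size underflow / non-finite.
static bool dopri5(const SSEPars& P, std::vector<double>& y, double tlen,
                   double atol, double rtol) {
  const int n = 2 * P.m;
  if (tlen <= 0.0) return true;
  static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
  (void)c2; (void)c3; (void)c4; (void)c5;
  const double a21 = 1.0/5;
  const double a31 = 3.0/40,       a32 = 9.0/40;
  const double a41 = 44.0/45,      a42 = -56.0/15,      a43 = 32.0/9;
  const double a51 = 19372.0/6561, a52 = -25360.0/2187, a53 = 64448.0/6561,
               a54 = -212.0/729;
  const double a61 = 9017.0/3168,  a62 = -355.0/33,     a63 = 46732.0/5247,
               a64 = 49.0/176,     a65 = -5103.0/18656;
  const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
               b5 = -2187.0/6784, b6 = 11.0/84;
  // b - b* (embedded 4th order error weights, incl. k7 term)
  const double e1 = b1 - 5179.0/57600, e3 = b3 - 7571.0/16695,
               e4 = b4 - 393.0/640,    e5 = b5 + 92097.0/339200,
               e6 = b6 - 187.0/2100,   e7 = -1.0/40;

  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      yt(n), ynew(n);
  double t = 0.0;
  double h = tlen / 10.0;
  if (h > 1.0) h = 1.0;
  int iter = 0;
  while (t < tlen) {
    if (++iter > 1000000) return false;
    if (h > tlen - t) h = tlen - t;
    sse_rhs(P, y.data(), k1.data());
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    sse_rhs(P, yt.data(), k2.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sse_rhs(P, yt.data(), k3.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sse_rhs(P, yt.data(), k4.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    sse_rhs(P, yt.data(), k5.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    sse_rhs(P, yt.data(), k6.data());
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    sse_rhs(P, ynew.data(), k7.data());
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      const double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(ynew[i]));
      const double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);
    if (!std::isfinite(errnorm)) return false;
    if (errnorm <= 1.0) {
      t += h;
      y = ynew;
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-14 * tlen) return false;
  }
  // clamp tiny numerical overshoots
  for (int i = 0; i < P.m; ++i) {
    if (y[i] < 0.0) y[i] = 0.0;
    if (y[i] > 1.0) y[i] = 1.0;
    if (y[P.m + i] < 0.0) y[P.m + i] = 0.0;
  }
  return true;
}

static SSEPars make_pars(NumericVector lambda, NumericVector mu,
                         NumericMatrix Q) {
  SSEPars P;
  P.m = lambda.size();
  P.lam.assign(lambda.begin(), lambda.end());
  P.mu.assign(mu.begin(), mu.end());
  P.Q.assign(Q.begin(), Q.end());
  P.qrow.assign(P.m, 0.0);
  for (int i = 0; i < P.m; ++i)
    for (int j = 0; j < P.m; ++j)
      if (j != i) P.qrow[i] += P.Q[i + P.m * j];
  return P;
}

// Integrate one branch; exported for testing and for ancestral-state
// path recomputation.
// [[Rcpp::export]]
List sse_branch_solve_cpp(NumericVector E0, NumericVector D0,
                          NumericVector lambda, NumericVector mu,
                          NumericMatrix Q, double tlen,
                          double atol, double rtol) {
  SSEPars P = make_pars(lambda, mu, Q);
  std::vector<double> y(2 * P.m);
  for (int i = 0; i < P.m; ++i) { y[i] = E0[i]; y[P.m + i] = D0[i]; }
  bool ok = dopri5(P, y, tlen, atol, rtol);
  NumericVector E(P.m), D(P.m);
  for (int i = 0; i < P.m; ++i) { E[i] = y[i]; D[i] = y[P.m + i]; }
  return List::create(_["E"] = E, _["D"] = D, _["ok"] = ok);
}

// Full postorder pruning likelihood.
// edge: Nedge x 2 (parent, child), rows in postorder; node ids 1-based as
// in ape (tips 1..n_tip). tipD: m x n_tip initial D per tip. E0: length m
// initial extinction probabilities (1 - rho). root_mode: 0 = weights
// proportional to D ("obs"), 1 = flat. char_only: drop speciation node
// factors and survival conditioning (Mk character likelihood limit).
// [[Rcpp::export]]
List sse_loglik_cpp(IntegerMatrix edge, NumericVector edge_len, int n_tip,
                    NumericMatrix tipD, NumericVector E0,
                    NumericVector lambda, NumericVector mu, NumericMatrix Q,
                    int root_mode, bool cond_surv, bool char_only,
                    double atol, double rtol, bool store) {
  SSEPars P = make_pars(lambda, mu, Q);
  const int m = P.m, ne = edge.nrow();
  int ntot = n_tip;
  for (int i = 0; i < ne; ++i) {
    if (edge(i, 0) > ntot) ntot = edge(i, 0);
    if (edge(i, 1) > ntot) ntot = edge(i, 1);
  }
  std::vector<double> Dwork(ntot * m, 1.0), Ebase(ntot * m, 0.0),
      Dbase(ntot * m, 0.0);
  std::vector<bool> done(ntot, false);
  NumericMatrix topD;
  if (store) topD = NumericMatrix(m, ne);
  double loglik = 0.0;
  bool ok = true;

  std::vector<double> y(2 * m);
  for (int e = 0; e < ne && ok; ++e) {
    const int child = edge(e, 1) - 1, par = edge(e, 0) - 1;
    if (child < n_tip) {
      for (int i = 0; i < m; ++i) {
        Ebase[child * m + i] = E0[i];
        Dbase[child * m + i] = tipD(i, child);
      }
    } else if (!done[child]) {
      // finalize internal node: product of children branch tops x lambda
      for (int i = 0; i < m; ++i)
        Dbase[child * m + i] =
            Dwork[child * m + i] * (char_only ? 1.0 : P.lam[i]);
      done[child] = true;
    }
    for (int i = 0; i < m; ++i) {
      y[i] = Ebase[child * m + i];
      y[m + i] = Dbase[child * m + i];
    }
    if (!dopri5(P, y, edge_len[e], atol, rtol)) { ok = false; break; }
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += y[m + i];
    if (!(s > 0.0) || !std::isfinite(s)) { ok = false; break; }
    loglik += std::log(s);
    for (int i = 0; i < m; ++i) {
      const double d = y[m + i] / s;
      Dwork[par * m + i] *= d;
      Ebase[par * m + i] = y[i];
      if (store) topD(i, e) = d;
    }
  }

  double root_node = ne > 0 ? edge(ne - 1, 0) : NA_REAL;
  NumericVector droot(m);
  if (ok) {
    const int root = edge(ne - 1, 0) - 1;
    for (int i = 0; i < m; ++i) {
      double d = Dwork[root * m + i];
      if (!char_only) {
        if (cond_surv) {
          // node lambda factor cancels against the lambda_i in the
          // survival conditioning lambda_i (1 - E_i)^2
          const double surv = 1.0 - Ebase[root * m + i];
          d = (surv > 1e-150) ? d / (surv * surv) : 0.0;
        } else {
          d *= P.lam[i];
        }
      }
      droot[i] = d;
      Dbase[root * m + i] = d;
    }
    double L = 0.0, s = 0.0;
    for (int i = 0; i < m; ++i) s += droot[i];
    if (s > 0.0 && std::isfinite(s)) {
      if (root_mode == 0) {
        for (int i = 0; i < m; ++i) L += droot[i] * droot[i] / s;
      } else {
        L = s / m;
      }
      loglik += std::log(L);
    } else {
      ok = false;
    }
  }
  if (!ok) loglik = R_NegInf;

  List out = List::create(_["loglik"] = loglik, _["ok"] = ok,
                          _["root_node"] = root_node);
  if (store && ok) {
    NumericMatrix Eb(m, ntot), Db(m, ntot);
    for (int v = 0; v < ntot; ++v)
      for (int i = 0; i < m; ++i) {
        Eb(i, v) = Ebase[v * m + i];
        Db(i, v) = Dbase[v * m + i];
      }
    out["top_D"] = topD;
    out["node_E"] = Eb;
    out["node_D"] = Db;
  }
  return out;
}
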