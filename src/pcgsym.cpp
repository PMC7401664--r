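// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Generic SPD solver for an absorbed mixed-model system plus a dense
// single-step adjustment on the genotyped block:
//   (C + P' (Dg (x) I_m) P) x = rhs
// where C is a symmetric sparse matrix (full pattern, CSC), P selects the
// m consecutive unknowns of each genotyped animal (1-based base row
// gbase[k] for genotyped animal k, unknowns gbase[k]..gbase[k]+m-1), and
// Dg is the dense genomic adjustment. Solved by conjugate gradients with
// symmetric Gauss-Seidel (SSOR) preconditioning in Eisenstat form; the
// diagonal of Dg is folded into the sweep diagonal, its off-diagonal part
// is applied as a dense operator term. Convergence on the true relative
// residual.

// [[Rcpp::export]]
List cpp_solve_sym(IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
                   NumericVector rhs, IntegerVector gbase, int m,
                   NumericMatrix Dg, NumericVector x0, double tol,
                   int maxit) {
  const int n = rhs.size();
  const int *ai = INTEGER(Ai), *ap = INTEGER(Ap);
  const double *ax = REAL(Ax);
  const int ng = gbase.size();
  arma::mat Doff;
  arma::vec gdiag;
  if (ng > 0) {
    Doff = arma::mat(Dg.begin(), Dg.nrow(), Dg.ncol());
    gdiag = arma::vec(Doff.diag());
    Doff.diag().zeros();
  }
  // diagonal (C diag plus genomic diagonal)
  arma::vec D(n, arma::fill::zeros);
  for (int c = 0; c < n; c++)
    for (int k = ap[c]; k < ap[c + 1]; k++)
      if (ai[k] == c) D[c] += ax[k];
  for (int k = 0; k < ng; k++)
    for (int t = 0; t < m; t++) D[gbase[k] - 1 + t] += gdiag[k];
  arma::vec Dinv = 1.0 / D;

  auto gather = [&](const arma::vec &v, arma::mat &G) {
    for (int k = 0; k < ng; k++)
      for (int t = 0; t < m; t++) G.at(k, t) = v[gbase[k] - 1 + t];
  };
  arma::mat Gbuf(ng > 0 ? ng : 1, m), Gout(ng > 0 ? ng : 1, m);
  // E v: genomic off-diagonal only
  auto apply_E = [&](const arma::vec &v, arma::vec &e) {
    e.zeros();
    if (ng == 0) return;
    gather(v, Gbuf);
    Gout = Doff * Gbuf;
    for (int k = 0; k < ng; k++)
      for (int t = 0; t < m; t++) e[gbase[k] - 1 + t] = Gout.at(k, t);
  };
  // full operator (for residual checks)
  auto apply_C = [&](const arma::vec &v, arma::vec &q) {
    q.zeros();
    for (int c = 0; c < n; c++) {
      const double vc = v[c];
      for (int k = ap[c]; k < ap[c + 1]; k++) q[ai[k]] += ax[k] * vc;
    }
    if (ng > 0) {
      gather(v, Gbuf);
      Gout = Doff * Gbuf;
      for (int k = 0; k < ng; k++)
        for (int t = 0; t < m; t++) {
          q[gbase[k] - 1 + t] += Gout.at(k, t) + gdiag[k] * v[gbase[k] - 1 + t];
        }
    }
  };
  // forward solve (D + L) y = x in place (strict lower of C only; the
  // genomic off-diagonal stays in E)
  auto fwd_solve = [&](arma::vec &x) {
    for (int j = 0; j < n; j++) {
      const double yj = x[j] * Dinv[j];
      x[j] = yj;
      for (int k = ap[j]; k < ap[j + 1]; k++) {
        const int i = ai[k];
        if (i > j) x[i] -= ax[k] * yj;
      }
    }
  };
  auto bwd_solve = [&](arma::vec &x) {
    for (int j = n - 1; j >= 0; j--) {
      const double yj = x[j] * Dinv[j];
      x[j] = yj;
      for (int k = ap[j]; k < ap[j + 1]; k++) {
        const int i = ai[k];
        if (i < j) x[i] -= ax[k] * yj;
      }
    }
  };
  auto apply_Ft = [&](const arma::vec &u, arma::vec &w) {
    for (int j = 0; j < n; j++) w[j] = D[j] * u[j];
    for (int j = 0; j < n; j++) {
      for (int k = ap[j]; k < ap[j + 1]; k++) {
        const int i = ai[k];
        if (i > j) w[j] += ax[k] * u[i];
      }
    }
  };

  arma::vec rhsv(rhs.begin(), n);
  double rhsnorm = arma::norm(rhsv);
  if (rhsnorm <= 0) rhsnorm = 1.0;
  arma::vec u(x0.begin(), n);
  arma::vec w(n); apply_Ft(u, w);
  arma::vec q(n), rt(n), y(n), Ey(n), pdir(n);
  apply_C(u, q);
  rt = rhsv - q;
  double relres = arma::norm(rt) / rhsnorm;
  fwd_solve(rt);
  pdir = rt;
  double rz = arma::dot(rt, rt);
  int it = 0;
  const int check_every = 8;
  while (relres > tol && it < maxit) {
    y = pdir; bwd_solve(y);
    apply_E(y, Ey);
    Ey -= D % y;
    q = pdir + Ey;
    fwd_solve(q);
    q += y;
    double pq = arma::dot(pdir, q);
    if (pq <= 0) break;
    double alpha = rz / pq;
    w += alpha * pdir;
    rt -= alpha * q;
    double rznew = arma::dot(rt, rt);
    it++;
    if (std::sqrt(rznew) / rhsnorm < tol || it % check_every == 0) {
      u = w; bwd_solve(u);
      apply_C(u, q);
      relres = arma::norm(rhsv - q) / rhsnorm;
    }
    double beta = rznew / rz;
    rz = rznew;
    pdir = rt + beta * pdir;
  }
  u = w; bwd_solve(u);
  return List::create(_["x"] = wrap(u), _["iterations"] = it,
                      _["relres"] = relres);
}
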