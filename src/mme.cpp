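// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Multi-trait mixed model equations for one trait block, solved by a
// conjugate gradient with symmetric Gauss-Seidel (SSOR) preconditioning in
// Eisenstat form. Model per trait: y = mean + animal effect + residual,
// u ~ N(0, G0 (x) H), e ~ N(0, R0 within animal), records possibly missing
// per animal x trait. H^-1 is the sparse pedigree A^-1 (CSC arrays) plus an
// optional dense adjustment D on a genotyped subset (single-step GBLUP:
// H^-1 = A^-1 + P' (tau Gb^-1 - omega A22^-1) P).
//
// Internals: animal effects are decorrelated with the Cholesky factor of
// G0 (u = (I (x) Lg) u*), which turns the genetic penalty into I (x) H^-1
// (univariate-like conditioning; cross-animal couplings become scalar
// multiples of the identity). The per-trait means are eliminated by a
// Schur complement (a rank-m correction in the operator) and recovered
// after the solve. With C = D + L + L' + E (D = exact per-animal diagonal
// blocks including the single-step diagonal, L = strict lower pedigree
// couplings, E = genomic off-diagonal plus the mean correction), the
// SSOR-preconditioned system (D+L)^-1 C (D+L)^-T is applied with two
// triangular sweeps per iteration (Eisenstat trick). Convergence is
// declared on the true relative residual of the mixed model equations.
//
// Traits without any record anywhere have their mean frozen at zero; their
// EBVs are still propagated through the genetic covariance structure.

// [[Rcpp::export]]
List cpp_solve_mme(int n, IntegerVector Ai, IntegerVector Ap, NumericVector Ax,
                   NumericMatrix Y, NumericMatrix R0, NumericMatrix G0R,
                   IntegerVector geno, NumericMatrix Dg, NumericMatrix U0,
                   NumericVector b0, bool fit_mean, double tol, int maxit) {
  const int m = Y.ncol();
  if (n != Y.nrow()) stop("Y must have one row per animal");
  const int *ai = INTEGER(Ai), *ap = INTEGER(Ap);
  const double *ax = REAL(Ax);
  arma::mat G0(G0R.begin(), m, m);
  arma::mat R0a(R0.begin(), m, m);
  arma::mat Lg = arma::chol(G0, "lower");

  // residual patterns: W = zero-padded inverse of the observed R0 submatrix
  std::vector<arma::mat> Ws;   // Lg' W Lg (decorrelated diagonal blocks)
  std::vector<arma::mat> WL;   // W Lg (mean-to-effect coupling)
  Ws.push_back(arma::mat(m, m, arma::fill::zeros));
  WL.push_back(arma::mat(m, m, arma::fill::zeros));
  std::map<int, int> seen; seen[0] = 0;
  std::vector<int> pat(n);
  arma::mat Wsum(m, m, arma::fill::zeros);
  arma::vec rhsb(m, arma::fill::zeros);
  arma::mat rhsU(m, n, arma::fill::zeros);
  arma::vec nobs(m, arma::fill::zeros);
  {
    std::vector<arma::mat> Wraw(1, arma::mat(m, m, arma::fill::zeros));
    for (int i = 0; i < n; i++) {
      int code = 0;
      for (int t = 0; t < m; t++)
        if (R_finite(Y(i, t))) { code |= (1 << t); nobs[t] += 1; }
      std::map<int, int>::iterator it = seen.find(code);
      if (it == seen.end()) {
        std::vector<arma::uword> o;
        for (int t = 0; t < m; t++) if (code & (1 << t)) o.push_back(t);
        arma::uvec obs(o);
        arma::mat Wi(m, m, arma::fill::zeros);
        Wi.submat(obs, obs) = arma::inv_sympd(R0a.submat(obs, obs));
        Wraw.push_back(Wi);
        Ws.push_back(Lg.t() * Wi * Lg);
        WL.push_back(Wi * Lg);
        seen[code] = (int)Wraw.size() - 1;
        pat[i] = (int)Wraw.size() - 1;
      } else pat[i] = it->second;
      if (pat[i] > 0) {
        arma::vec yi(m, arma::fill::zeros);
        for (int t = 0; t < m; t++) if (R_finite(Y(i, t))) yi[t] = Y(i, t);
        arma::vec wy = Wraw[pat[i]] * yi;
        rhsU.col(i) = Lg.t() * wy;
        rhsb += wy;
        Wsum += Wraw[pat[i]];
      }
    }
  }
  arma::vec deadb(m);
  for (int t = 0; t < m; t++)
    deadb[t] = (!fit_mean || nobs[t] < 0.5) ? 1.0 : 0.0;
  for (int t = 0; t < m; t++) if (deadb[t] > 0.5) rhsb[t] = 0.0;

  // pseudo-inverse of the mean block on live traits
  arma::mat Pb(m, m, arma::fill::zeros);
  {
    std::vector<arma::uword> lv;
    for (int t = 0; t < m; t++) if (deadb[t] < 0.5) lv.push_back(t);
    if (lv.size() > 0) {
      arma::uvec l(lv);
      Pb.submat(l, l) = arma::inv_sympd(Wsum.submat(l, l));
    }
  }

  // genotyped adjustment: diagonal goes into the animal blocks, the
  // off-diagonal part stays in the explicit operator term
  arma::uvec gidx;
  arma::mat Doff;
  arma::vec gdiag;
  if (geno.size() > 0) {
    std::vector<arma::uword> g(geno.size());
    for (int k = 0; k < geno.size(); k++) g[k] = geno[k] - 1;
    gidx = arma::uvec(g);
    Doff = arma::mat(Dg.begin(), Dg.nrow(), Dg.ncol());
    gdiag = arma::vec(Doff.diag());
    Doff.diag().zeros();
  }
  std::vector<int> gpos(n, -1);
  const int ng = (int)gidx.n_elem;
  for (int k = 0; k < ng; k++) {
    if (k > 0 && gidx[k] <= gidx[k - 1])
      stop("genotyped indices must be strictly increasing");
    gpos[gidx[k]] = k;
  }
  arma::vec hdiag(n, arma::fill::zeros);
  for (int c = 0; c < n; c++)
    for (int k = ap[c]; k < ap[c + 1]; k++)
      if (ai[k] == c) hdiag[c] += ax[k];
  if (geno.size() > 0) {
    arma::mat Dfull(Dg.begin(), Dg.nrow(), Dg.ncol());
    for (arma::uword k = 0; k < gidx.n_elem; k++)
      hdiag[gidx[k]] += Dfull.at(k, k);
  }

  // exact per-animal diagonal blocks of the decorrelated system
  arma::cube Dblk(m, m, n), Dinv(m, m, n);
  arma::mat Im(m, m, arma::fill::eye);
  for (int i = 0; i < n; i++) {
    Dblk.slice(i) = Ws[pat[i]] + hdiag[i] * Im;
    Dinv.slice(i) = arma::inv_sympd(Dblk.slice(i));
  }

  double buf[32];
  // forward solve (Dblk + L) y = x in place (columns = animals)
  auto fwd_solve = [&](arma::mat &Xm) {
    double *T = Xm.memptr();
    for (int j = 0; j < n; j++) {
      double *tj = T + (size_t)j * m;
      const double *Di = Dinv.slice_memptr(j);
      for (int t = 0; t < m; t++) {
        double s = 0;
        for (int u = 0; u < m; u++) s += Di[t + u * m] * tj[u];
        buf[t] = s;
      }
      for (int t = 0; t < m; t++) tj[t] = buf[t];
      for (int k = ap[j]; k < ap[j + 1]; k++) {
        const int i = ai[k];
        if (i > j) {
          const double v = ax[k];
          double *ti = T + (size_t)i * m;
          for (int t = 0; t < m; t++) ti[t] -= v * tj[t];
        }
      }
    }
  };
  // backward solve (Dblk + L') y = x in place
  auto bwd_solve = [&](arma::mat &Xm) {
    double *T = Xm.memptr();
    for (int j = n - 1; j >= 0; j--) {
      double *tj = T + (size_t)j * m;
      const double *Di = Dinv.slice_memptr(j);
      for (int t = 0; t < m; t++) {
        double s = 0;
        for (int u = 0; u < m; u++) s += Di[t + u * m] * tj[u];
        buf[t] = s;
      }
      for (int t = 0; t < m; t++) tj[t] = buf[t];
      for (int k = ap[j]; k < ap[j + 1]; k++) {
        const int i = ai[k];
        if (i < j) {
          const double v = ax[k];
          double *ti = T + (size_t)i * m;
          for (int t = 0; t < m; t++) ti[t] -= v * tj[t];
        }
      }
    }
  };
  // (Dblk + L') u = w, i.e. apply F' to get w from u: w = (Dblk + L') u
  auto apply_Ft = [&](const arma::mat &U, arma::mat &Wm) {
    double *T = Wm.memptr();
    const double *S = U.memptr();
    for (int j = 0; j < n; j++) {
      const double *uj = S + (size_t)j * m;
      const double *Db = Dblk.slice_memptr(j);
      double *tj = T + (size_t)j * m;
      for (int t = 0; t < m; t++) {
        double s = 0;
        for (int u = 0; u < m; u++) s += Db[t + u * m] * uj[u];
        tj[t] = s;
      }
    }
    // add L' u: column j receives a_ij * u_i for i > j
    for (int j = 0; j < n; j++) {
      double *tj = T + (size_t)j * m;
      for (int k = ap[j]; k < ap[j + 1]; k++) {
        const int i = ai[k];
        if (i > j) {
          const double v = ax[k];
          const double *ui = S + (size_t)i * m;
          for (int t = 0; t < m; t++) tj[t] += v * ui[t];
        }
      }
    }
  };
  // E y = genomic off-diagonal minus the mean Schur correction
  auto apply_E = [&](const arma::mat &Ym, arma::mat &Em) {
    Em.zeros();
    if (ng > 0) {
      arma::mat Yg = Ym.cols(gidx);
      Em.cols(gidx) += Yg * Doff;
    }
    arma::vec agg(m, arma::fill::zeros);
    const double *S = Ym.memptr();
    for (int i = 0; i < n; i++) {
      const int p = pat[i];
      if (p == 0) continue;
      const double *yi = S + (size_t)i * m;
      const double *Wl = WL[p].memptr();
      for (int t = 0; t < m; t++) {
        double s = 0;
        for (int u = 0; u < m; u++) s += Wl[t + u * m] * yi[u];
        agg[t] += s;
      }
    }
    arma::vec z = Pb * agg;
    double *Tm = Em.memptr();
    for (int i = 0; i < n; i++) {
      const int p = pat[i];
      if (p == 0) continue;
      const double *Wl = WL[p].memptr();
      double *ei = Tm + (size_t)i * m;
      for (int t = 0; t < m; t++) {
        double s = 0;
        for (int u = 0; u < m; u++) s += Wl[u + t * m] * z[u];  // WL' z
        ei[t] -= s;
      }
    }
  };
  // full Schur operator C y (used for true-residual checks)
  arma::mat Vt(m, n);
  auto apply_C = [&](const arma::mat &U, arma::mat &Q) {
    Q.zeros();
    double *T = Q.memptr();
    const double *S = U.memptr();
    for (int c = 0; c < n; c++) {
      const double *uc = S + (size_t)c * m;
      for (int k = ap[c]; k < ap[c + 1]; k++) {
        const double v = ax[k];
        double *vc = T + (size_t)ai[k] * m;
        for (int t = 0; t < m; t++) vc[t] += v * uc[t];
      }
    }
    for (int i = 0; i < n; i++) {
      const int p = pat[i];
      if (p == 0) continue;
      const double *Wsb = Ws[p].memptr();
      const double *ui = S + (size_t)i * m;
      double *qi = T + (size_t)i * m;
      for (int t = 0; t < m; t++) {
        double s = 0;
        for (int u = 0; u < m; u++) s += Wsb[t + u * m] * ui[u];
        qi[t] += s;
      }
    }
    for (arma::uword k = 0; k < gidx.n_elem; k++) {
      const double v = gdiag[k];
      const double *ui = S + (size_t)gidx[k] * m;
      double *qi = T + (size_t)gidx[k] * m;
      for (int t = 0; t < m; t++) qi[t] += v * ui[t];
    }
    apply_E(U, Vt);
    Q += Vt;
  };

  // Schur-corrected right-hand side (eliminate the means)
  {
    arma::vec z = Pb * rhsb;
    for (int i = 0; i < n; i++) {
      const int p = pat[i];
      if (p == 0) continue;
      rhsU.col(i) -= WL[p].t() * z;
    }
  }
  double rhsnorm = std::sqrt(arma::accu(rhsU % rhsU));
  if (rhsnorm <= 0) rhsnorm = 1.0;

  // warm start in the decorrelated basis
  arma::mat U = arma::solve(arma::trimatl(Lg),
                            arma::trans(arma::mat(U0.begin(), n, m)));
  // CG in Eisenstat form on w = F' u
  arma::mat w(m, n); apply_Ft(U, w);
  arma::mat rt(m, n), q(m, n), y(m, n), pdir(m, n), Ey(m, n);
  // rt = F^-1 (rhs - C u)
  apply_C(U, q);
  rt = rhsU - q;
  double relres = std::sqrt(arma::accu(rt % rt)) / rhsnorm;
  fwd_solve(rt);
  pdir = rt;
  double rz = arma::accu(rt % rt);
  int it = 0;
  const int check_every = 6;
  while (relres > tol && it < maxit) {
    // q = Atilde p = y + F^-1 (p + (E - Dblk) y), y = F^-T p
    y = pdir; bwd_solve(y);
    apply_E(y, Ey);
    {
      double *T = Ey.memptr();
      const double *S = y.memptr();
      for (int j = 0; j < n; j++) {
        const double *Db = Dblk.slice_memptr(j);
        const double *yj = S + (size_t)j * m;
        double *tj = T + (size_t)j * m;
        for (int t = 0; t < m; t++) {
          double s = 0;
          for (int u = 0; u < m; u++) s += Db[t + u * m] * yj[u];
          tj[t] -= s;
        }
      }
    }
    q = pdir + Ey;
    fwd_solve(q);
    q += y;
    double pq = arma::accu(pdir % q);
    if (pq <= 0) break;
    double alpha = rz / pq;
    w += alpha * pdir;
    rt -= alpha * q;
    double rznew = arma::accu(rt % rt);
    it++;
    // surrogate indicates convergence: verify on the true residual
    if (std::sqrt(rznew) / rhsnorm < tol || it % check_every == 0) {
      U = w; bwd_solve(U);
      apply_C(U, q);
      q = rhsU - q;
      relres = std::sqrt(arma::accu(q % q)) / rhsnorm;
    }
    double beta = rznew / rz;
    rz = rznew;
    pdir = rt + beta * pdir;
  }
  U = w; bwd_solve(U);

  // recover the means: b = Pb (rhsb - sum_i WL_i' ... ) in trait basis
  arma::vec agg(m, arma::fill::zeros);
  for (int i = 0; i < n; i++) {
    const int p = pat[i];
    if (p == 0) continue;
    agg += WL[p] * U.col(i);
  }
  arma::vec b = Pb * (rhsb - agg);

  arma::mat Uout = arma::trans(Lg * U);
  return List::create(_["b"] = wrap(b), _["u"] = wrap(Uout),
                      _["iterations"] = it, _["relres"] = relres);
}
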