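// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Exact leaf absorption for the multi-trait animal-model MME. Animals
// without offspring in the evaluated pedigree ("leaves") are eliminated by
// a Schur complement: a leaf contributes a modified coupling between its
// parents and a right-hand-side carry; its EBV is recovered afterwards by
// back-substitution. The reduced system (non-leaf animals plus the trait
// means) is assembled in the decorrelated basis u* = (I (x) Lg^-1) u and
// returned as triplets for a sparse Cholesky solve.
//
// Inputs use the sub-pedigree indexing of the ancestor closure: sire/dam
// are sub-indices (0 = unknown), F holds the (full-pedigree) inbreeding
// coefficients of those animals, nonleaf flags the animals kept in the
// reduced system, Y is the phenotype matrix (NA = missing).

static void mk_patterns(const NumericMatrix &Y, const arma::mat &R0a,
                        const arma::mat &Lg, std::vector<int> &pat,
                        std::vector<arma::mat> &Wraw,
                        std::vector<arma::mat> &Ws,
                        std::vector<arma::mat> &LW) {
  int n = Y.nrow(), m = Y.ncol();
  std::map<int, int> seen; seen[0] = 0;
  Wraw.assign(1, arma::mat(m, m, arma::fill::zeros));
  Ws.assign(1, arma::mat(m, m, arma::fill::zeros));
  LW.assign(1, arma::mat(m, m, arma::fill::zeros));
  pat.resize(n);
  for (int i = 0; i < n; i++) {
    int code = 0;
    for (int t = 0; t < m; t++) if (R_finite(Y(i, t))) code |= (1 << t);
    std::map<int, int>::iterator it = seen.find(code);
    if (it == seen.end()) {
      std::vector<arma::uword> o;
      for (int t = 0; t < m; t++) if (code & (1 << t)) o.push_back(t);
      arma::uvec obs(o);
      arma::mat Wi(m, m, arma::fill::zeros);
      Wi.submat(obs, obs) = arma::inv_sympd(R0a.submat(obs, obs));
      Wraw.push_back(Wi);
      Ws.push_back(Lg.t() * Wi * Lg);
      LW.push_back(Lg.t() * Wi);  // couples u*-equations to the means
      seen[code] = (int)Wraw.size() - 1;
      pat[i] = (int)Wraw.size() - 1;
    } else pat[i] = it->second;
  }
}

// mendelian sampling precision of animal i given parent inbreeding
static double msprec(int s, int d, const NumericVector &F) {
  double v = 1.0;
  if (s > 0) v -= 0.25 * (1.0 + F[s - 1]);
  if (d > 0) v -= 0.25 * (1.0 + F[d - 1]);
  return 1.0 / v;
}

// [[Rcpp::export]]
List cpp_absorb_build(IntegerVector sire, IntegerVector dam, NumericVector F,
                      LogicalVector nonleaf, NumericMatrix Y,
                      NumericMatrix R0, NumericMatrix G0R, bool fit_mean) {
  const int n = Y.nrow(), m = Y.ncol();
  arma::mat G0(G0R.begin(), m, m), R0a(R0.begin(), m, m);
  arma::mat Lg = arma::chol(G0, "lower");
  std::vector<int> pat;
  std::vector<arma::mat> Wraw, Ws, LW;
  mk_patterns(Y, R0a, Lg, pat, Wraw, Ws, LW);

  // reduced indexing
  std::vector<int> map(n + 1, 0);
  int nl = 0;
  for (int i = 0; i < n; i++) if (nonleaf[i]) map[i + 1] = ++nl;
  arma::vec nobs(m, arma::fill::zeros);
  for (int i = 0; i < n; i++)
    for (int t = 0; t < m; t++) if (R_finite(Y(i, t))) nobs[t] += 1;
  std::vector<int> livet;
  if (fit_mean)
    for (int t = 0; t < m; t++) if (nobs[t] > 0.5) livet.push_back(t);
  const int nb = (int)livet.size();
  const int dim = nl * m + nb;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(40 * n); tj.reserve(40 * n); tx.reserve(40 * n);
  arma::vec rhs(dim, arma::fill::zeros);
  // push an m x m block at animal-block positions (1-based reduced ids)
  auto push_blk = [&](int a, int b, const arma::mat &B) {
    for (int r = 0; r < m; r++)
      for (int c = 0; c < m; c++)
        if (B.at(r, c) != 0) {
          ti.push_back((a - 1) * m + r + 1);
          tj.push_back((b - 1) * m + c + 1);
          tx.push_back(B.at(r, c));
        }
  };
  auto push_scalar = [&](int a, int b, double v) {
    for (int r = 0; r < m; r++) {
      ti.push_back((a - 1) * m + r + 1);
      tj.push_back((b - 1) * m + r + 1);
      tx.push_back(v);
    }
  };

  arma::mat Im(m, m, arma::fill::eye);
  // decorrelated record carries per animal
  auto rvec = [&](int i) {
    arma::vec yi(m, arma::fill::zeros);
    for (int t = 0; t < m; t++) if (R_finite(Y(i, t))) yi[t] = Y(i, t);
    return arma::vec(LW[pat[i]] * yi);
  };

  arma::vec bb_rhs(m, arma::fill::zeros);
  arma::mat bb(m, m, arma::fill::zeros);  // mean-mean block (trait basis)
  // b-coupling triplets are collected in trait space then mapped to livet
  std::vector<int> bi, bj; std::vector<double> bx;
  auto push_bu = [&](int a, const arma::mat &C) {
    // C is m (traits) x m (u* components): coupling mean x u*_a
    for (int r = 0; r < m; r++)
      for (int c = 0; c < m; c++)
        if (C.at(r, c) != 0) {
          bi.push_back(r);                   // trait index
          bj.push_back((a - 1) * m + c + 1); // u* index
          bx.push_back(C.at(r, c));
        }
  };

  for (int i = 0; i < n; i++) {
    int s = sire[i], d = dam[i];
    double g = msprec(s, d, F);
    int rs = (s > 0) ? map[s] : 0;
    int rd = (d > 0) ? map[d] : 0;
    if (nonleaf[i]) {
      int ri = map[i + 1];
      // Henderson contributions of i (scalar x I)
      push_scalar(ri, ri, g);
      if (rs) { push_scalar(ri, rs, -0.5 * g); push_scalar(rs, ri, -0.5 * g); }
      if (rd) { push_scalar(ri, rd, -0.5 * g); push_scalar(rd, ri, -0.5 * g); }
      if (rs) push_scalar(rs, rs, 0.25 * g);
      if (rd) push_scalar(rd, rd, 0.25 * g);
      if (rs && rd) { push_scalar(rs, rd, 0.25 * g); push_scalar(rd, rs, 0.25 * g); }
      if (pat[i] > 0) {
        push_blk(ri, ri, Ws[pat[i]]);
        arma::vec r_i = rvec(i);
        for (int t = 0; t < m; t++) rhs[(ri - 1) * m + t] += r_i[t];
        // mean couplings (trait basis W on the b side)
        push_bu(ri, LW[pat[i]].t());  // rows = traits? see below
        bb += Wraw[pat[i]];
        arma::vec yi(m, arma::fill::zeros);
        for (int t = 0; t < m; t++) if (R_finite(Y(i, t))) yi[t] = Y(i, t);
        bb_rhs += Wraw[pat[i]] * yi;
      }
    } else if (m == 1) {
      // leaf, univariate: scalar absorption
      double B = Ws[pat[i]].at(0, 0) + g;
      double Binv = 1.0 / B;
      double Mv = 0.25 * g * (1.0 - g * Binv);
      if (rs) push_scalar(rs, rs, Mv);
      if (rd) push_scalar(rd, rd, Mv);
      if (rs && rd) { push_scalar(rs, rd, Mv); push_scalar(rd, rs, Mv); }
      if (pat[i] > 0) {
        double yi = R_finite(Y(i, 0)) ? Y(i, 0) : 0.0;
        double r_i = LW[pat[i]].at(0, 0) * yi;
        double carry = 0.5 * g * Binv * r_i;
        if (rs) rhs[rs - 1] += carry;
        if (rd) rhs[rd - 1] += carry;
        double W0 = Wraw[pat[i]].at(0, 0);
        bb.at(0, 0) += W0;
        bb_rhs[0] += W0 * yi;
        double CbL = LW[pat[i]].at(0, 0);  // = W Lg (scalar)
        double CbB = CbL * Binv;
        bb.at(0, 0) -= CbB * CbL;
        bb_rhs[0] -= CbB * r_i;
        double couple = 0.5 * g * CbB;
        arma::mat cm(1, 1); cm.at(0, 0) = couple;
        if (rs) push_bu(rs, cm);
        if (rd) push_bu(rd, cm);
      }
    } else {
      // leaf: absorb
      arma::mat B = Ws[pat[i]] + g * Im;
      arma::mat Binv = arma::inv_sympd(B);
      arma::mat M = 0.25 * g * (Im - g * Binv);
      if (rs) push_blk(rs, rs, M);
      if (rd) push_blk(rd, rd, M);
      if (rs && rd) { push_blk(rs, rd, M); push_blk(rd, rs, M); }
      if (pat[i] > 0) {
        arma::vec r_i = rvec(i);
        arma::vec carry = 0.5 * g * (Binv * r_i);
        if (rs) for (int t = 0; t < m; t++) rhs[(rs - 1) * m + t] += carry[t];
        if (rd) for (int t = 0; t < m; t++) rhs[(rd - 1) * m + t] += carry[t];
        // absorbed mean couplings: Cb_i = W_i' Lg (trait x u*): after
        // absorbing u*_i: bb -= CbL Binv CbL', b-parent += 0.5 g CbL Binv,
        // b rhs -= CbL Binv r_i
        arma::mat CbL = LW[pat[i]].t();       // m(traits) x m(u*)
        arma::mat CbB = CbL * Binv;           // m x m
        bb += Wraw[pat[i]];
        arma::vec yi(m, arma::fill::zeros);
        for (int t = 0; t < m; t++) if (R_finite(Y(i, t))) yi[t] = Y(i, t);
        bb_rhs += Wraw[pat[i]] * yi;
        bb -= CbB * CbL.t();
        bb_rhs -= CbB * r_i;
        arma::mat couple = 0.5 * g * CbB;     // coupling mean x u*_parent
        if (rs) push_bu(rs, couple);
        if (rd) push_bu(rd, couple);
      }
    }
  }

  // map mean couplings into the bordered system (live traits only)
  if (nb > 0) {
    std::vector<int> tpos(m, -1);
    for (int k = 0; k < nb; k++) tpos[livet[k]] = nl * m + k + 1;
    for (size_t k = 0; k < bi.size(); k++) {
      int r = tpos[bi[k]];
      if (r < 0) continue;
      ti.push_back(r); tj.push_back(bj[k]); tx.push_back(bx[k]);
      ti.push_back(bj[k]); tj.push_back(r); tx.push_back(bx[k]);
    }
    for (int a = 0; a < nb; a++)
      for (int b2 = 0; b2 < nb; b2++)
        if (bb.at(livet[a], livet[b2]) != 0) {
          ti.push_back(nl * m + a + 1);
          tj.push_back(nl * m + b2 + 1);
          tx.push_back(bb.at(livet[a], livet[b2]));
        }
    for (int a = 0; a < nb; a++) rhs[nl * m + a] = bb_rhs[livet[a]];
  }

  // assemble the lower triangle as compressed sparse columns (summing
  // duplicate entries) for a direct dsCMatrix construction
  size_t nt = ti.size();
  std::vector<int> colcnt(dim + 1, 0);
  for (size_t k = 0; k < nt; k++)
    if (ti[k] >= tj[k]) colcnt[tj[k]]++;
  std::vector<int> p(dim + 1, 0);
  for (int c = 1; c <= dim; c++) p[c] = p[c - 1] + colcnt[c];
  std::vector<int> ri(p[dim]);
  std::vector<double> rx(p[dim]);
  std::vector<int> fill(p.begin(), p.end() - 1);
  for (size_t k = 0; k < nt; k++) {
    if (ti[k] < tj[k]) continue;
    int c = tj[k] - 1;
    ri[fill[c]] = ti[k] - 1;
    rx[fill[c]] = tx[k];
    fill[c]++;
  }
  // sort each column by row and merge duplicates
  std::vector<int> outp(dim + 1, 0);
  std::vector<std::pair<int, double> > buf;
  int w = 0;
  for (int c = 0; c < dim; c++) {
    buf.clear();
    for (int k = p[c]; k < p[c + 1]; k++)
      buf.push_back(std::make_pair(ri[k], rx[k]));
    std::sort(buf.begin(), buf.end());
    for (size_t k = 0; k < buf.size(); k++) {
      if (k > 0 && buf[k].first == ri[w - 1])
        rx[w - 1] += buf[k].second;
      else { ri[w] = buf[k].first; rx[w] = buf[k].second; w++; }
    }
    outp[c + 1] = w;
  }
  ri.resize(w); rx.resize(w);
  return List::create(_["ci"] = wrap(ri), _["cp"] = wrap(outp),
                      _["cx"] = wrap(rx), _["dim"] = dim,
                      _["rhs"] = wrap(rhs),
                      _["nl"] = nl, _["nb"] = nb,
                      _["livet"] = wrap(livet));
}

// back-substitution: recover leaf EBVs and return the full EBV matrix in
// the trait basis, plus the means.
// [[Rcpp::export]]
List cpp_absorb_backsolve(IntegerVector sire, IntegerVector dam,
                          NumericVector F, LogicalVector nonleaf,
                          NumericMatrix Y, NumericMatrix R0,
                          NumericMatrix G0R, NumericVector theta,
                          IntegerVector livet) {
  const int n = Y.nrow(), m = Y.ncol();
  arma::mat G0(G0R.begin(), m, m), R0a(R0.begin(), m, m);
  arma::mat Lg = arma::chol(G0, "lower");
  std::vector<int> pat;
  std::vector<arma::mat> Wraw, Ws, LW;
  mk_patterns(Y, R0a, Lg, pat, Wraw, Ws, LW);
  std::vector<int> map(n + 1, 0);
  int nl = 0;
  for (int i = 0; i < n; i++) if (nonleaf[i]) map[i + 1] = ++nl;
  arma::vec b(m, arma::fill::zeros);
  for (int k = 0; k < livet.size(); k++)
    b[livet[k]] = theta[nl * m + k];
  arma::mat Us(m, n, arma::fill::zeros);  // decorrelated effects
  for (int i = 0; i < n; i++)
    if (nonleaf[i]) {
      int ri = map[i + 1];
      for (int t = 0; t < m; t++) Us.at(t, i) = theta[(ri - 1) * m + t];
    }
  arma::mat Im(m, m, arma::fill::eye);
  for (int i = 0; i < n; i++) {
    if (nonleaf[i]) continue;
    int s = sire[i], d = dam[i];
    double g = msprec(s, d, F);
    if (m == 1) {
      double B = Ws[pat[i]].at(0, 0) + g;
      double acc = 0.0;
      if (s > 0) acc += 0.5 * g * Us.at(0, s - 1);
      if (d > 0) acc += 0.5 * g * Us.at(0, d - 1);
      if (pat[i] > 0) {
        double yi = R_finite(Y(i, 0)) ? Y(i, 0) : 0.0;
        acc += LW[pat[i]].at(0, 0) * (yi - b[0]);
      }
      Us.at(0, i) = acc / B;
      continue;
    }
    arma::mat B = Ws[pat[i]] + g * Im;
    arma::vec acc(m, arma::fill::zeros);
    if (s > 0) acc += 0.5 * g * Us.col(s - 1);
    if (d > 0) acc += 0.5 * g * Us.col(d - 1);
    if (pat[i] > 0) {
      arma::vec yi(m, arma::fill::zeros);
      for (int t = 0; t < m; t++) if (R_finite(Y(i, t))) yi[t] = Y(i, t);
      acc += LW[pat[i]] * yi;       // decorrelated record carry
      acc -= LW[pat[i]] * b;        // minus the fitted means
    }
    Us.col(i) = arma::solve(B, acc, arma::solve_opts::likely_sympd);
  }
  arma::mat U = arma::trans(Lg * Us);
  return List::create(_["u"] = wrap(U), _["b"] = wrap(b));
}
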