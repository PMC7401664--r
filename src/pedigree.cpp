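#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Inbreeding by the Meuwissen & Luo (1992) algorithm plus Henderson's rules
// for the inverse numerator relationship matrix. Pedigrees are append-only in
// the simulation, so both F and the A-inverse contributions are computed
// incrementally: `from` (1-based) marks the first animal whose F is unknown.
// Unknown parents are coded 0 and treated as unrelated non-inbred founders.

// [[Rcpp::export]]
List cpp_ainv_update(IntegerVector sire, IntegerVector dam, NumericVector Fin,
                     int from) {
  int n = sire.size();
  NumericVector F(clone(Fin));
  if (F.size() != n) stop("F must have length n");
  std::vector<double> L(n + 1, 0.0);
  // mendelian sampling variance d_i given parent inbreeding
  auto dvar = [&](int i) {
    int s = sire[i], d = dam[i];
    double v = 1.0;
    if (s > 0) v -= 0.25 * (1.0 + F[s - 1]);
    if (d > 0) v -= 0.25 * (1.0 + F[d - 1]);
    return v;
  };
  for (int i = from - 1; i < n; i++) {
    int s = sire[i], d = dam[i];
    if (s > (i + 1) || d > (i + 1) || s == i + 1 || d == i + 1)
      stop("pedigree is not topologically sorted (parents must precede offspring)");
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    // trace ancestors of i, largest id first
    std::set<int, std::greater<int> > anc;
    double FI = -1.0;
    L[i] = 1.0;
    anc.insert(i);
    while (!anc.empty()) {
      int j = *anc.begin();
      anc.erase(anc.begin());
      double Lj = L[j];
      int js = sire[j], jd = dam[j];
      if (js > 0) { L[js - 1] += 0.5 * Lj; anc.insert(js - 1); }
      if (jd > 0) { L[jd - 1] += 0.5 * Lj; anc.insert(jd - 1); }
      FI += Lj * Lj * dvar(j);
      L[j] = 0.0;
    }
    F[i] = FI;
  }
  // Henderson triplets for animals from..n (upper+lower stored explicitly;
  // duplicates are summed by the sparse constructor on the R side)
  std::vector<int> ti, tj;
  std::vector<double> tx;
  for (int i = from - 1; i < n; i++) {
    int s = sire[i], d = dam[i];
    double alpha = 1.0 / dvar(i);
    int ids[3] = {i + 1, s, d};
    double w[3] = {1.0, -0.5, -0.5};
    for (int a = 0; a < 3; a++) {
      if (ids[a] == 0) continue;
      for (int b = 0; b < 3; b++) {
        if (ids[b] == 0) continue;
        ti.push_back(ids[a]);
        tj.push_back(ids[b]);
        tx.push_back(alpha * w[a] * w[b]);
      }
    }
  }
  return List::create(_["F"] = F, _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}

// Henderson triplets for the sub-pedigree spanned by `keep` (1-based,
// ascending, closed under ancestry), using inbreeding coefficients from the
// full pedigree. Record-less animals outside the closure are leaves whose
// A-inverse contributions cancel exactly, so this equals the full-pedigree
// A-inverse marginalized to the closure.
// [[Rcpp::export]]
List cpp_ainv_sub(IntegerVector sire, IntegerVector dam, NumericVector F,
                  IntegerVector keep) {
  int n = sire.size(), k = keep.size();
  std::vector<int> map(n + 1, 0);
  for (int j = 0; j < k; j++) map[keep[j]] = j + 1;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(9 * k); tj.reserve(9 * k); tx.reserve(9 * k);
  for (int j = 0; j < k; j++) {
    int i = keep[j] - 1;
    int s = sire[i], d = dam[i];
    int ss = (s > 0) ? map[s] : 0;
    int dd = (d > 0) ? map[d] : 0;
    if ((s > 0 && ss == 0) || (d > 0 && dd == 0))
      stop("keep set is not closed under ancestry");
    double v = 1.0;
    if (s > 0) v -= 0.25 * (1.0 + F[s - 1]);
    if (d > 0) v -= 0.25 * (1.0 + F[d - 1]);
    double alpha = 1.0 / v;
    int ids[3] = {j + 1, ss, dd};
    double w[3] = {1.0, -0.5, -0.5};
    for (int a = 0; a < 3; a++) {
      if (ids[a] == 0) continue;
      for (int b = 0; b < 3; b++) {
        if (ids[b] == 0) continue;
        ti.push_back(ids[a]);
        tj.push_back(ids[b]);
        tx.push_back(alpha * w[a] * w[b]);
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}

// Fill unsolved rows of an EBV matrix with recursive parent averages
// (pedigree order guarantees parents are filled first). E is modified in
// place.
// [[Rcpp::export]]
void cpp_parent_average_fill(IntegerVector sire, IntegerVector dam,
                             NumericMatrix E, LogicalVector solved) {
  int n = E.nrow(), m = E.ncol();
  for (int i = 0; i < n; i++) {
    if (solved[i]) continue;
    int s = sire[i], d = dam[i];
    for (int t = 0; t < m; t++) {
      double v = 0.0;
      if (s > 0) v += 0.5 * E(s - 1, t);
      if (d > 0) v += 0.5 * E(d - 1, t);
      E(i, t) = v;
    }
  }
}

// Ancestor closure of a seed set: logical vector over 1..n marking the
// seed animals and all their ancestors.
// [[Rcpp::export]]
LogicalVector cpp_ancestor_closure(IntegerVector sire, IntegerVector dam,
                                   IntegerVector seed) {
  int n = sire.size();
  LogicalVector keep(n);
  std::vector<int> stack(seed.begin(), seed.end());
  for (size_t k = 0; k < stack.size(); k++) keep[stack[k] - 1] = true;
  while (!stack.empty()) {
    int i = stack.back() - 1;
    stack.pop_back();
    int s = sire[i], d = dam[i];
    if (s > 0 && !keep[s - 1]) { keep[s - 1] = true; stack.push_back(s); }
    if (d > 0 && !keep[d - 1]) { keep[d - 1] = true; stack.push_back(d); }
  }
  return keep;
}

// Tabular numerator relationship matrix (dense); quadratic, intended for
// moderate pedigrees (standalone kinship queries, tests, exports).
// [[Rcpp::export]]
NumericMatrix cpp_tabular_a(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; i++) {
    int s = sire[i], d = dam[i];
    for (int j = 0; j < i; j++) {
      double v = 0.0;
      if (s > 0) v += 0.5 * A(j, s - 1);
      if (d > 0) v += 0.5 * A(j, d - 1);
      A(i, j) = A(j, i) = v;
    }
    double self = 1.0;
    if (s > 0 && d > 0) self += 0.5 * A(s - 1, d - 1);
    A(i, i) = self;
  }
  return A;
}
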