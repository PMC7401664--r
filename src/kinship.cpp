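#include <Rcpp.h>
using namespace Rcpp;

// Incremental additive-relationship tracker used by the year loop. K holds
// A-scale relationships (a = 2 * kinship) for the currently tracked animals;
// rows are recycled when animals leave. New animals are filled from their
// parents' rows: a(o,x) = 0.5 (a(s,x) + a(d,x)), a(o,o) = 1 + 0.5 a(s,d),
// missing parents contribute zero (unrelated founders). K is modified in
// place; newrow/rs/rd are 1-based row indices (0 = untracked parent), act are
// the rows already holding live animals.
// [[Rcpp::export]]
void cpp_kin_add(NumericMatrix K, IntegerVector newrow, IntegerVector rs,
                 IntegerVector rd, IntegerVector act) {
  int k = newrow.size();
  const size_t nr = K.nrow();
  double *Kp = &K(0, 0);
  std::vector<int> cols(act.begin(), act.end());
  for (int t = 0; t < k; t++) {
    const int r = newrow[t] - 1;
    const int s = rs[t] - 1, d = rd[t] - 1;
    const double *Ks = (s >= 0) ? Kp + s : 0;
    const double *Kd = (d >= 0) ? Kp + d : 0;
    double *Kr = Kp + r;
    for (size_t c = 0; c < cols.size(); c++) {
      const size_t cc = (size_t)(cols[c] - 1);
      double v = 0.0;
      if (Ks) v += 0.5 * Ks[cc * nr];
      if (Kd) v += 0.5 * Kd[cc * nr];
      Kr[cc * nr] = v;
      Kp[cc + (size_t)r * nr] = v;
    }
    double self = 1.0;
    if (s >= 0 && d >= 0) self += 0.5 * Kp[s + (size_t)d * nr];
    Kp[r + (size_t)r * nr] = self;
    cols.push_back(r + 1);
  }
}

// Mean of the A-scale relationship block over a set of rows (including the
// diagonal); mean kinship of the cohort is half of this.
// [[Rcpp::export]]
double cpp_kin_block_mean(NumericMatrix K, IntegerVector rows) {
  int k = rows.size();
  double s = 0.0;
  for (int a = 0; a < k; a++)
    for (int b = 0; b < k; b++) s += K(rows[a] - 1, rows[b] - 1);
  return s / ((double)k * (double)k);
}
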