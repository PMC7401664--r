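#include <Rcpp.h>
using namespace Rcpp;

// Haplotype storage convention: one animal's phased genome is a raw vector of
// length 2L (first L entries = paternal haplotype, next L = maternal), alleles
// coded 0/1. Batch containers are raw matrices with one column per animal.

// [[Rcpp::export]]
RawMatrix cpp_founder_genomes(int n, NumericVector freq) {
  int L = freq.size();
  RawMatrix out(2 * L, n);
  for (int a = 0; a < n; a++) {
    Rbyte *col = &out(0, a);
    for (int h = 0; h < 2; h++)
      for (int j = 0; j < L; j++)
        col[h * L + j] = (unif_rand() < freq[j]) ? 1 : 0;
  }
  return out;
}

// One meiosis: Poisson(Morgan length) crossovers per chromosome, uniform
// positions, no interference (Haldane), random start strand, independent
// segregation across chromosomes. Writes gamete into `out`, returns total
// crossover count per chromosome through xo (if non-null).
static void gamete_into(const Rbyte *h1, const Rbyte *h2,
                        const IntegerVector &chr_start,
                        const IntegerVector &chr_nloci,
                        const NumericVector &chr_len,
                        const NumericVector &pos, Rbyte *out, int *xo) {
  int nchr = chr_start.size();
  std::vector<double> x;
  for (int c = 0; c < nchr; c++) {
    int s = chr_start[c], nl = chr_nloci[c];
    double len = chr_len[c];
    int nxo = (len > 0) ? (int)R::rpois(len / 100.0) : 0;
    if (xo) xo[c] = nxo;
    x.resize(nxo);
    for (int k = 0; k < nxo; k++) x[k] = unif_rand() * len;
    std::sort(x.begin(), x.end());
    int strand = (unif_rand() < 0.5) ? 0 : 1;
    const Rbyte *src[2] = {h1, h2};
    int k = 0;
    for (int j = 0; j < nl; j++) {
      while (k < nxo && x[k] <= pos[s + j]) { strand ^= 1; k++; }
      out[s + j] = src[strand][s + j];
    }
  }
}

// [[Rcpp::export]]
List cpp_meiosis(RawVector genome, IntegerVector chr_start,
                 IntegerVector chr_nloci, NumericVector chr_len,
                 NumericVector pos) {
  int L = pos.size();
  RawVector gam(L);
  IntegerVector xo(chr_start.size());
  gamete_into(&genome[0], &genome[L], chr_start, chr_nloci, chr_len, pos,
              &gam[0], &xo[0]);
  return List::create(_["gamete"] = gam, _["crossovers"] = xo);
}

// Offspring batch: genomes is an R list indexed by animal id holding raw
// vectors of length 2L; sire/dam are 1-based ids. Column a of the result is
// the offspring genome (sire gamete then dam gamete).
// [[Rcpp::export]]
List cpp_make_offspring_batch(List genomes, IntegerVector sire,
                              IntegerVector dam, IntegerVector chr_start,
                              IntegerVector chr_nloci,
                              NumericVector chr_len, NumericVector pos) {
  int L = pos.size(), n = sire.size();
  List out(n);
  for (int a = 0; a < n; a++) {
    RawVector gs = genomes[sire[a] - 1];
    RawVector gd = genomes[dam[a] - 1];
    if (gs.size() != 2 * L || gd.size() != 2 * L)
      stop("parent genome length does not match map");
    RawVector col(2 * L);
    gamete_into(&gs[0], &gs[L], chr_start, chr_nloci, chr_len, pos, &col[0],
                0);
    gamete_into(&gd[0], &gd[L], chr_start, chr_nloci, chr_len, pos,
                &col[L], 0);
    out[a] = col;
  }
  return out;
}

// Dosage matrix at the QTL for genomes stored in a list (1-based ids);
// animals x QTL, double for downstream matrix products.
// [[Rcpp::export]]
NumericMatrix cpp_qtl_dosage(List genomes, IntegerVector ids,
                             IntegerVector qtl) {
  int n = ids.size(), nq = qtl.size();
  NumericMatrix D(n, nq);
  for (int a = 0; a < n; a++) {
    RawVector g = genomes[ids[a] - 1];
    int L = g.size() / 2;
    const Rbyte *col = &g[0];
    for (int q = 0; q < nq; q++)
      D(a, q) = (double)(col[qtl[q]] + col[L + qtl[q]]);
  }
  return D;
}

// True genomic values: dosage at QTL loci times additive effect matrix.
// G is 2L x n raw, qtl 0-based locus indices, eff nqtl x ntraits.
// [[Rcpp::export]]
NumericMatrix cpp_tbv(RawMatrix G, IntegerVector qtl, NumericMatrix eff) {
  int n = G.ncol(), L = G.nrow() / 2, nq = qtl.size(), nt = eff.ncol();
  if (eff.nrow() != nq) stop("effect matrix rows must equal number of QTL");
  NumericMatrix tbv(n, nt);
  for (int a = 0; a < n; a++) {
    const Rbyte *col = &G(0, a);
    for (int q = 0; q < nq; q++) {
      int d = col[qtl[q]] + col[L + qtl[q]];
      if (d)
        for (int t = 0; t < nt; t++) tbv(a, t) += d * eff(q, t);
    }
  }
  return tbv;
}

// Centered dosage matrix (L x k) for the VanRaden G: dosage - 2p with founder
// allele frequencies p.
// [[Rcpp::export]]
NumericMatrix cpp_centered_dosage(List genomes, IntegerVector ids,
                                  NumericVector p) {
  int L = p.size(), k = ids.size();
  NumericMatrix Z(L, k);
  for (int a = 0; a < k; a++) {
    RawVector g = genomes[ids[a] - 1];
    if (g.size() != 2 * L) stop("genome length does not match frequency vector");
    for (int j = 0; j < L; j++)
      Z(j, a) = (double)(g[j] + g[L + j]) - 2.0 * p[j];
  }
  return Z;
}

// Allele frequency from a raw genome matrix (2L x n).
// [[Rcpp::export]]
NumericVector cpp_allele_freq_matrix(RawMatrix G) {
  int n = G.ncol(), L = G.nrow() / 2;
  NumericVector p(L);
  for (int a = 0; a < n; a++) {
    const Rbyte *col = &G(0, a);
    for (int j = 0; j < L; j++) p[j] += col[j] + col[L + j];
  }
  for (int j = 0; j < L; j++) p[j] /= 2.0 * n;
  return p;
}

// Allele frequency of a stored cohort (used for founder bookkeeping).
// [[Rcpp::export]]
NumericVector cpp_allele_freq(List genomes, IntegerVector ids, int L) {
  NumericVector p(L);
  int k = ids.size();
  for (int a = 0; a < k; a++) {
    RawVector g = genomes[ids[a] - 1];
    for (int j = 0; j < L; j++) p[j] += g[j] + g[L + j];
  }
  for (int j = 0; j < L; j++) p[j] /= 2.0 * k;
  return p;
}
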