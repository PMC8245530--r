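#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment scores with affine gaps for a batch of
// sequence pairs.  Sequences are 0-based integer encodings (0..19); the
// substitution matrix is 20x20.  An optional band limits |i - j| (band <= 0
// disables banding); because the band only ever shifts forward, cells that
// enter it are untouched since initialisation, which is the correct empty
// boundary for local alignment.  Only the optimal score is returned; the
// pipeline never needs the traceback.
// [[Rcpp::export(name = ".sw_pair_scores")]]
NumericVector sw_pair_scores(List seqs, IntegerVector idx_a, IntegerVector idx_b,
                             NumericMatrix submat, double gap_open,
                             double gap_extend, int band) {
  const int npair = idx_a.size();
  if (idx_b.size() != npair) stop("pair index vectors differ in length");
  NumericVector out(npair);

  const int nseq = seqs.size();
  std::vector<IntegerVector> sv;
  sv.reserve(nseq);
  for (int i = 0; i < nseq; ++i) sv.push_back(as<IntegerVector>(seqs[i]));

  const double NEG = -1e30;
  const double *S = submat.begin(); // column-major 20x20
  for (int p = 0; p < npair; ++p) {
    const IntegerVector &av = sv[idx_a[p] - 1];
    const IntegerVector &bv = sv[idx_b[p] - 1];
    const int n = av.size(), m = bv.size();
    const int *a = av.begin();
    std::vector<int> b20(m);
    for (int j = 0; j < m; ++j) b20[j] = 20 * bv[j];
    std::vector<double> Hv(m + 1, 0.0), Ev(m + 1, NEG);
    double *H = Hv.data(), *E = Ev.data();
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      int jlo = 1, jhi = m;
      if (band > 0) {
        jlo = std::max(1, i - band);
        jhi = std::min(m, i + band);
      }
      double diag = (jlo > 1) ? H[jlo - 1] : 0.0; // previous row, column jlo-1
      double Hprev = 0.0;                          // H[i][jlo-1]: outside band/empty
      double F = NEG;                              // vertical gap state
      const double *Srow = S + a[i - 1];           // S[ai + 20*bj]
      for (int j = jlo; j <= jhi; ++j) {
        E[j] = std::max(E[j] - gap_extend, H[j] - gap_open);
        F = std::max(F - gap_extend, Hprev - gap_open);
        double h = diag + Srow[b20[j - 1]];
        h = std::max(h, E[j]);
        h = std::max(h, F);
        h = std::max(h, 0.0);
        diag = H[j];
        H[j] = h;
        Hprev = h;
        if (h > best) best = h;
      }
    }
    out[p] = best;
  }
  return out;
}

// Best ungapped sliding-window log-odds score of a profile against each
// protein.  logodds is L x 20 (rows = match columns).  Proteins are 0-based
// integer encodings.  When a protein is shorter than the profile, the
// profile slides over the protein instead, so the shorter of the two is
// always fully covered.
// [[Rcpp::export(name = ".profile_best_scores")]]
NumericVector profile_best_scores(NumericMatrix logodds, List proteins) {
  const int L = logodds.nrow();
  const int np = proteins.size();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    IntegerVector x = proteins[p];
    const int n = x.size();
    double best = R_NegInf;
    if (n >= L) {
      for (int s = 0; s + L <= n; ++s) {
        double sc = 0.0;
        for (int k = 0; k < L; ++k) sc += logodds(k, x[s + k]);
        if (sc > best) best = sc;
      }
    } else {
      for (int t = 0; t + n <= L; ++t) {
        double sc = 0.0;
        for (int k = 0; k < n; ++k) sc += logodds(t + k, x[k]);
        if (sc > best) best = sc;
      }
    }
    out[p] = best;
  }
  return out;
}
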