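#include <Rcpp.h>
using namespace Rcpp;

// Between-community mean nearest taxon distance for every sample pair,
// under a set of taxon-label permutations of the patristic distance matrix.
//
// D      : S x S patristic distances between taxa
// W      : n x S per-sample taxon weights (relative abundance, or 1/S_k for
//          the unweighted variant; 0 marks absence)
// perms  : S x P, each column a 0-based permutation of taxon indices
//          (identity column gives the observed value)
//
// Returns a P x (n*(n-1)/2) matrix; pair columns follow the lower-triangle
// order of R's dist objects: (2,1),(3,1),...,(n,1),(3,2),...
// [[Rcpp::export]]
NumericMatrix bmntd_perms(const NumericMatrix& D, const NumericMatrix& W,
                          const IntegerMatrix& perms) {
  const int S = D.nrow(), n = W.nrow(), P = perms.ncol();
  const int npairs = n * (n - 1) / 2;
  NumericMatrix out(P, npairs);

  // presence lists per sample
  std::vector<std::vector<int>> present(n);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < S; ++j)
      if (W(k, j) > 0) present[k].push_back(j);

  // dmin[k][i]: distance from taxon i to its nearest taxon in sample k
  std::vector<std::vector<double>> dmin(n, std::vector<double>(S));

  for (int p = 0; p < P; ++p) {
    const int* perm = &perms(0, p);
    for (int k = 0; k < n; ++k) {
      std::vector<double>& dk = dmin[k];
      const std::vector<int>& pk = present[k];
      for (int i = 0; i < S; ++i) {
        const double* Drow = &D(0, perm[i]);  // column = row (symmetric)
        double best = R_PosInf;
        for (size_t t = 0; t < pk.size(); ++t) {
          double d = Drow[perm[pk[t]]];
          if (d < best) best = d;
        }
        dk[i] = best;
      }
    }
    int col = 0;
    for (int a = 0; a < n - 1; ++a) {
      for (int b = a + 1; b < n; ++b, ++col) {
        double s1 = 0.0, s2 = 0.0;
        const std::vector<int>& pa = present[a];
        const std::vector<int>& pb = present[b];
        for (size_t t = 0; t < pa.size(); ++t)
          s1 += W(a, pa[t]) * dmin[b][pa[t]];
        for (size_t t = 0; t < pb.size(); ++t)
          s2 += W(b, pb[t]) * dmin[a][pb[t]];
        out(p, col) = 0.5 * (s1 + s2);
      }
    }
  }
  return out;
}
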