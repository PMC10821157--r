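#include <Rcpp.h>
using namespace Rcpp;

// Weighted sampling without replacement (Efraimidis-Spirakis exponential
// keys): pick `r` indices with probability proportional to w.
static void sample_weighted(const std::vector<double>& w, int r,
                            std::vector<int>& idx_buf, std::vector<int>& out) {
  const int S = (int)w.size();
  static std::vector<double> keys;
  keys.resize(S);
  for (int i = 0; i < S; ++i)
    keys[i] = (w[i] > 0) ? exp_rand() / w[i] : R_PosInf;
  idx_buf.resize(S);
  for (int i = 0; i < S; ++i) idx_buf[i] = i;
  std::nth_element(idx_buf.begin(), idx_buf.begin() + r, idx_buf.end(),
                   [&](int a, int b) { return keys[a] < keys[b]; });
  out.assign(idx_buf.begin(), idx_buf.begin() + r);
}

// Abundance-based Raup-Crick null loop. For each sample pair, n_null null
// communities per sample are assembled by (1) drawing the observed richness
// with probability proportional to metacommunity occurrence frequency and
// (2) filling to the observed library size proportional to metacommunity
// relative abundance among the chosen taxa; RCbray compares null and
// observed Bray-Curtis (ties half-weighted) and is rescaled to [-1, 1].
// [[Rcpp::export]]
NumericMatrix rcbray_pairs(const IntegerMatrix& counts,
                           const NumericVector& occurrence,
                           const NumericVector& abundance, int n_null) {
  const int n = counts.nrow(), S = counts.ncol();
  std::vector<double> occ(occurrence.begin(), occurrence.end());
  std::vector<double> ab(abundance.begin(), abundance.end());
  std::vector<int> rich(n, 0);
  std::vector<long> tot(n, 0);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < S; ++j) {
      int c = counts(k, j);
      if (c > 0) rich[k]++;
      tot[k] += c;
    }

  NumericMatrix rc(n, n);
  rc.fill(NA_REAL);

  std::vector<int> idx_buf, ch1, ch2;
  std::vector<long> x(S, 0), y(S, 0);
  std::vector<double> prob;
  std::vector<int> fill;

  // assemble one null community into `v` (returns touched indices in ch)
  auto null_comm = [&](int richness, long size, std::vector<long>& v,
                       std::vector<int>& ch) {
    sample_weighted(occ, richness, idx_buf, ch);
    prob.resize(richness);
    double ps = 0.0;
    for (int t = 0; t < richness; ++t) { prob[t] = ab[ch[t]]; ps += prob[t]; }
    for (int t = 0; t < richness; ++t) prob[t] = (ps > 0) ? prob[t] / ps
                                                          : 1.0 / richness;
    fill.assign(richness, 0);
    int extra = (int)(size - richness);
    if (extra > 0) ::rmultinom(extra, prob.data(), richness, fill.data());
    for (int t = 0; t < richness; ++t) v[ch[t]] = 1 + fill[t];
  };

  for (int a = 0; a < n - 1; ++a) {
    for (int b = a + 1; b < n; ++b) {
      long num = 0, den = tot[a] + tot[b];
      for (int j = 0; j < S; ++j) num += std::labs((long)counts(a, j) - counts(b, j));
      double obs = (double)num / den;
      int below = 0, ties = 0;
      for (int r = 0; r < n_null; ++r) {
        null_comm(rich[a], tot[a], x, ch1);
        null_comm(rich[b], tot[b], y, ch2);
        long nnum = 0;
        for (int t = 0; t < (int)ch1.size(); ++t) {
          int j = ch1[t];
          nnum += std::labs(x[j] - y[j]);
          // count y[j] once; mark consumed
          y[j] = -y[j];
        }
        for (int t = 0; t < (int)ch2.size(); ++t) {
          int j = ch2[t];
          if (y[j] < 0) y[j] = -y[j];  // already paired with x
          else nnum += y[j];
        }
        double bc = (double)nnum / den;
        if (bc < obs) below++;
        else if (bc == obs) ties++;
        for (int t = 0; t < (int)ch1.size(); ++t) x[ch1[t]] = 0;
        for (int t = 0; t < (int)ch2.size(); ++t) y[ch2[t]] = 0;
      }
      rc(a, b) = rc(b, a) = 2.0 * ((below + 0.5 * ties) / n_null) - 1.0;
    }
  }
  return rc;
}
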