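#include <Rcpp.h>
using namespace Rcpp;

// Latent-Gaussian block haplotype sampler: per LD block each haplotype is an
// exchangeable-correlation multivariate normal thresholded at the
// allele-frequency quantile; the dosage is the sum of two haplotypes.
// Draw order (block -> haplotype -> individual -> variant) is fixed, so a
// given R RNG state yields identical matrices.
// [[Rcpp::export]]
NumericMatrix sample_block_dosages(int n, NumericVector tau, IntegerVector block,
                                   double rho) {
  int m = tau.size();
  NumericMatrix G(n, m);
  double sq = std::sqrt(rho), sq1 = std::sqrt(1.0 - rho);
  int j0 = 0;
  while (j0 < m) {
    int j1 = j0;
    while (j1 + 1 < m && block[j1 + 1] == block[j0]) ++j1;
    for (int hap = 0; hap < 2; ++hap) {
      for (int i = 0; i < n; ++i) {
        double u = norm_rand();
        for (int j = j0; j <= j1; ++j) {
          double z = sq * u + sq1 * norm_rand();
          if (z < tau[j]) G(i, j) += 1.0;
        }
      }
    }
    j0 = j1 + 1;
  }
  return G;
}
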