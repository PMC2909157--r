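#include <Rcpp.h>
using namespace Rcpp;

// Gene-dropping simulator: base animals receive two allele effects per
// locus drawn from their breed's allele-effect distribution; descendants
// inherit one allele per parent per locus by a fair coin flip. Returns the
// empirical covariance matrix of total genotypic values over replicates.
// Purely Monte-Carlo, sharing no code with the tabular/collapsed
// relationship-matrix paths it serves as an oracle for.

// [[Rcpp::export]]
List gene_drop_cpp(IntegerVector sire, IntegerVector dam,
                   IntegerVector base_breed, // 0 = A, 1 = B, -1 = non-base
                   NumericMatrix mu,         // n_loci x 2 allele-effect means
                   NumericMatrix vl,         // n_loci x 2 allele-effect vars
                   int n_rep) {
  const int q = sire.size();
  const int L = mu.nrow();
  std::vector<double> pat(q * L), mat(q * L);
  std::vector<double> g(q);
  std::vector<double> gsum(q, 0.0);
  std::vector<double> gcross(q * q, 0.0);
  std::vector<double> sdl(2 * L);
  for (int t = 0; t < L; t++) {
    sdl[t] = std::sqrt(vl(t, 0));
    sdl[L + t] = std::sqrt(vl(t, 1));
  }

  for (int rep = 0; rep < n_rep; rep++) {
    if (rep % 1024 == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < q; i++) {
      double gi = 0.0;
      if (base_breed[i] >= 0) {
        const int b = base_breed[i];
        for (int t = 0; t < L; t++) {
          const double a1 = mu(t, b) + sdl[b * L + t] * R::norm_rand();
          const double a2 = mu(t, b) + sdl[b * L + t] * R::norm_rand();
          pat[i * L + t] = a1;
          mat[i * L + t] = a2;
          gi += a1 + a2;
        }
      } else {
        const int s = sire[i] - 1;
        const int d = dam[i] - 1;
        for (int t = 0; t < L; t++) {
          const double as =
              unif_rand() < 0.5 ? pat[s * L + t] : mat[s * L + t];
          const double ad =
              unif_rand() < 0.5 ? pat[d * L + t] : mat[d * L + t];
          pat[i * L + t] = as;
          mat[i * L + t] = ad;
          gi += as + ad;
        }
      }
      g[i] = gi;
    }
    for (int i = 0; i < q; i++) {
      gsum[i] += g[i];
      for (int j = 0; j <= i; j++) gcross[i * q + j] += g[i] * g[j];
    }
  }

  NumericMatrix cov(q, q);
  NumericVector mean(q);
  for (int i = 0; i < q; i++) mean[i] = gsum[i] / n_rep;
  for (int i = 0; i < q; i++)
    for (int j = 0; j <= i; j++) {
      const double c =
          (gcross[i * q + j] - n_rep * mean[i] * mean[j]) / (n_rep - 1.0);
      cov(i, j) = c;
      cov(j, i) = c;
    }
  return List::create(_["cov"] = cov, _["mean"] = mean);
}
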