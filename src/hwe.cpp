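// Exact test of Hardy-Weinberg proportions: the two-sided p-value is the sum,
// over all heterozygote counts compatible with the observed allele counts, of
// those conditional probabilities not exceeding the probability of the
// observed configuration (Wigginton-style conditional enumeration).

#include <Rcpp.h>
#include <cmath>
#include <vector>

// [[Rcpp::export]]
double cpp_hwe_exact_p(int n_hom_ref, int n_het, int n_hom_alt) {
  if (n_hom_ref < 0 || n_het < 0 || n_hom_alt < 0)
    Rcpp::stop("genotype counts must be non-negative");
  const int n = n_hom_ref + n_het + n_hom_alt;
  if (n < 1) Rcpp::stop("total genotype count must be at least 1");
  const int nA = 2 * n_hom_ref + n_het;
  const int nB = 2 * n_hom_alt + n_het;
  const int rare = std::min(nA, nB);
  if (rare == 0) return 1.0;  // monomorphic: single attainable configuration

  // heterozygote counts share the parity of the rare allele count
  const int h0 = rare % 2;
  std::vector<int> hs;
  for (int h = h0; h <= rare; h += 2) hs.push_back(h);

  auto logprob = [&](int h) {
    const int a = (nA - h) / 2, b = (nB - h) / 2;  // homozygote counts
    return std::lgamma(n + 1.0) - std::lgamma(a + 1.0) - std::lgamma(h + 1.0) -
           std::lgamma(b + 1.0) + h * std::log(2.0) + std::lgamma(nA + 1.0) +
           std::lgamma(nB + 1.0) - std::lgamma(2.0 * n + 1.0);
  };

  std::vector<double> lp(hs.size());
  double mx = -INFINITY;
  for (size_t i = 0; i < hs.size(); ++i) {
    lp[i] = logprob(hs[i]);
    if (lp[i] > mx) mx = lp[i];
  }
  double z = 0.0;
  for (double v : lp) z += std::exp(v - mx);
  const double logz = mx + std::log(z);  // renormalize for numerical safety

  const double lobs = logprob(n_het) - logz;
  double p = 0.0;
  for (size_t i = 0; i < hs.size(); ++i) {
    const double li = lp[i] - logz;
    if (li <= lobs + 1e-12) p += std::exp(li);
  }
  return std::min(1.0, p);
}
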