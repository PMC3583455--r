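#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Gamete simulation for a multi-chromosome genome under the no-interference
// (Haldane) model: per chromosome the crossover count is Poisson with mean
// equal to the genetic length in Morgans, breakpoint positions are uniform on
// the chromosome, and the starting strand is chosen with probability 1/2.
//
// Haplotypes are stored locus-by-individual (one column per individual) so a
// parental haplotype is contiguous in memory. All randomness goes through R's
// RNG, so results are reproducible under set.seed().
//
// hap1, hap2 : L x N integer matrices of allele codes (0 = parent-1 allele,
//              1 = parent-2 allele), one column per individual
// parents    : 1-based column indices, one per requested gamete
// pos        : locus genetic positions in cM, within-chromosome coordinates
// chrom_first, chrom_last : 0-based first/last locus index per chromosome
// chrom_len  : chromosome genetic lengths in cM
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& hap1, const IntegerMatrix& hap2,
                          const IntegerVector& parents, const NumericVector& pos,
                          const IntegerVector& chrom_first, const IntegerVector& chrom_last,
                          const NumericVector& chrom_len) {
  const int L = hap1.nrow();
  const int G = parents.size();
  const int n_chrom = chrom_len.size();
  IntegerMatrix out(L, G);
  std::vector<double> bp;

  for (int g = 0; g < G; ++g) {
    const int p = parents[g] - 1;
    const int* h1 = &hap1(0, p);
    const int* h2 = &hap2(0, p);
    int* dst = &out(0, g);
    for (int c = 0; c < n_chrom; ++c) {
      const double len_cM = chrom_len[c];
      const int first = chrom_first[c], last = chrom_last[c];
      int strand = (unif_rand() < 0.5) ? 0 : 1;
      int nx = (len_cM > 0.0) ? (int) R::rpois(len_cM / 100.0) : 0;
      if (nx == 0) {
        const int* src = strand ? h2 : h1;
        for (int i = first; i <= last; ++i) dst[i] = src[i];
        continue;
      }
      bp.resize(nx);
      for (int k = 0; k < nx; ++k) bp[k] = unif_rand() * len_cM;
      std::sort(bp.begin(), bp.end());
      int k = 0;
      for (int i = first; i <= last; ++i) {
        while (k < nx && bp[k] < pos[i]) { strand ^= 1; ++k; }
        dst[i] = strand ? h2[i] : h1[i];
      }
    }
  }
  return out;
}
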