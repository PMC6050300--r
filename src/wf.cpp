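#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Form one generation of gametes by meiosis with crossover.
//
// haps:     2N x S matrix of 0/1 haplotypes; individual i (1-based) owns rows
//           2i-1 and 2i.
// pos:      S site positions, strictly increasing, on [0, seq_len].
// parents:  1-based individual index of the transmitting parent, one per gamete.
//           Gametes 2j-1 and 2j form offspring j.
// rec_per_unit * seq_len is the expected crossover count per meiosis (Haldane:
// Poisson crossovers, positions uniform, no interference).
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix wf_gametes(const IntegerMatrix& haps, const NumericVector& pos,
                         const IntegerVector& parents, double rec_per_unit,
                         double seq_len) {
  const int S = haps.ncol();
  const int G = parents.size();
  IntegerMatrix out(G, S);
  const double lambda = rec_per_unit * seq_len;
  std::vector<double> cuts;
  for (int g = 0; g < G; ++g) {
    const int p = parents[g] - 1;
    const int r1 = 2 * p, r2 = 2 * p + 1;
    if (S == 0) continue;
    const int nc = (int) R::rpois(lambda);
    if (nc == 0) {
      const int src = (unif_rand() < 0.5) ? r1 : r2;
      for (int j = 0; j < S; ++j) out(g, j) = haps(src, j);
    } else {
      cuts.resize(nc);
      for (int k = 0; k < nc; ++k) cuts[k] = unif_rand() * seq_len;
      std::sort(cuts.begin(), cuts.end());
      int cur = (unif_rand() < 0.5) ? r1 : r2;
      int k = 0;
      for (int j = 0; j < S; ++j) {
        while (k < nc && pos[j] > cuts[k]) {
          cur = (cur == r1) ? r2 : r1;
          ++k;
        }
        out(g, j) = haps(cur, j);
      }
      // remaining cuts beyond the last site do not change transmitted alleles
    }
  }
  return out;
}
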