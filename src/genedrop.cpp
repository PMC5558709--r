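#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Gene-dropping along one chromosome.
//
// Founder gametes are copied from a pre-generated pool of haplotypes (rows
// of `pool`), handed out sequentially so founders stay unrelated;
// descendant gametes are formed by meiosis with Poisson crossovers at the
// given rate (Morgans per bp), no interference. Uses R's RNG so set.seed()
// governs.
//
// sire/dam: 1-based indices (0 = unknown), parents before offspring.
// pos: 1-based bp positions, ascending.
// [[Rcpp::export(name = ".geneDropChr")]]
IntegerMatrix geneDropChr(IntegerVector sire, IntegerVector dam,
                          NumericVector pos, IntegerMatrix pool,
                          double morgansPerBp, double chromLen) {
  int n = sire.size(), m = pos.size();
  IntegerMatrix h1(n, m), h2(n, m);
  double meanXo = morgansPerBp * chromLen;
  int poolNext = 0, npool = pool.nrow();

  // gamete from parent p into row 'to' of target matrix
  auto meiosis = [&](int p, IntegerMatrix &target, int to) {
    int k = (int) R::rpois(meanXo);
    std::vector<double> bk(k);
    for (int c = 0; c < k; ++c) bk[c] = R::runif(0.0, chromLen);
    std::sort(bk.begin(), bk.end());
    int cur = (R::unif_rand() < 0.5) ? 0 : 1; // starting haplotype
    int bi = 0;
    for (int j = 0; j < m; ++j) {
      while (bi < k && bk[bi] < pos[j]) { cur = 1 - cur; ++bi; }
      target(to, j) = cur == 0 ? h1(p, j) : h2(p, j);
    }
  };

  // unknown parent -> next unused haplotype from the founder pool
  auto poolGamete = [&](IntegerMatrix &target, int to) {
    int r = poolNext < npool ? poolNext++ : (int)(R::unif_rand() * npool);
    for (int j = 0; j < m; ++j) target(to, j) = pool(r, j);
  };

  for (int i = 0; i < n; ++i) {
    if (sire[i] == 0) poolGamete(h1, i); else meiosis(sire[i] - 1, h1, i);
    if (dam[i] == 0)  poolGamete(h2, i); else meiosis(dam[i] - 1, h2, i);
  }
  IntegerMatrix dose(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      dose(i, j) = h1(i, j) + h2(i, j);
  return dose;
}
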