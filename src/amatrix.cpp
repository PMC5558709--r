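#include <Rcpp.h>
using namespace Rcpp;

// Tabular method for the numerator relationship matrix.
// sire/dam are 1-based indices into the (parents-first) animal order, 0 = unknown.
// [[Rcpp::export(name = ".tabularA")]]
NumericMatrix tabularA(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    // diagonal: 1 + F_i, F_i = 0.5 * A(s,d)
    double f = (s > 0 && d > 0) ? 0.5 * A(s - 1, d - 1) : 0.0;
    A(i, i) = 1.0 + f;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s > 0) a += 0.5 * A(j, s - 1);
      if (d > 0) a += 0.5 * A(j, d - 1);
      A(i, j) = a;
      A(j, i) = a;
    }
  }
  return A;
}

// Sparse inverse of A by Henderson's rules with inbreeding (Meuwissen & Luo
// style, using the diagonal of A for the Mendelian sampling variance).
// Returns triplets (i, j, x) of the lower triangle incl. diagonal.
// [[Rcpp::export(name = ".ainverseTriplets")]]
List ainverseTriplets(IntegerVector sire, IntegerVector dam, NumericVector Fcoef) {
  int n = sire.size();
  std::vector<int> ri, ci;
  std::vector<double> xv;
  std::vector<double> diag(n, 0.0);
  // off-diagonal contributions collected in a map keyed by (i,j), i > j
  std::map<std::pair<int,int>, double> off;
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    double fs = s >= 0 ? Fcoef[s] : 0.0;
    double fd = d >= 0 ? Fcoef[d] : 0.0;
    double msv; // Mendelian sampling variance
    if (s >= 0 && d >= 0)      msv = 0.5 - 0.25 * (fs + fd);
    else if (s >= 0 || d >= 0) msv = 0.75 - 0.25 * (s >= 0 ? fs : fd);
    else                       msv = 1.0;
    double ai = 1.0 / msv;
    diag[i] += ai;
    if (s >= 0) {
      diag[s] += 0.25 * ai;
      off[std::make_pair(i, s)] += -0.5 * ai;
    }
    if (d >= 0) {
      diag[d] += 0.25 * ai;
      off[std::make_pair(i, d)] += -0.5 * ai;
    }
    if (s >= 0 && d >= 0) {
      int a = std::max(s, d), b = std::min(s, d);
      if (a == b) diag[a] += 0.5 * ai; // selfing never happens here, but be safe
      else off[std::make_pair(a, b)] += 0.25 * ai;
    }
  }
  for (int i = 0; i < n; ++i) { ri.push_back(i + 1); ci.push_back(i + 1); xv.push_back(diag[i]); }
  for (auto &kv : off) {
    ri.push_back(kv.first.first + 1);
    ci.push_back(kv.first.second + 1);
    xv.push_back(kv.second);
  }
  return List::create(_["i"] = wrap(ri), _["j"] = wrap(ci), _["x"] = wrap(xv));
}
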