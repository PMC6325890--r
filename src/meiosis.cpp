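#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Batch meiosis for one chromosome.
//
// For each requested gamete, the crossover count is Poisson(len) (no
// interference), crossover positions are uniform on (0, len), and the
// starting parental haplotype is chosen with probability 1/2; the copied
// strand switches at every crossover passed along the genetic map. Uses R's
// RNG so runs are reproducible from set.seed().
//
// The copy loop runs locus-major so that reads and writes stay within one
// matrix column at a time (R matrices are column-major).
//
// M, P: parental haplotype matrices (rows = parents, cols = loci)
// pos:  locus positions in Morgans, strictly increasing
// len:  chromosome length in Morgans
// rows: 1-based parent row per gamete (repeats = independent meioses)
// [[Rcpp::export(.meiosis_cpp)]]
IntegerMatrix meiosis_cpp(const IntegerMatrix& M, const IntegerMatrix& P,
                          const NumericVector& pos, double len,
                          const IntegerVector& rows) {
  const int n = rows.size();
  const int L = pos.size();
  IntegerMatrix out(n, L);

  // per-gamete crossover positions (flat, sorted) and starting haplotype
  std::vector<int> start(n), koff(n + 1, 0), jj(n, 0);
  std::vector<double> cx;
  cx.reserve(2 * n);
  for (int g = 0; g < n; ++g) {
    start[g] = (unif_rand() < 0.5) ? 0 : 1;
    const int k = (len > 0.0) ? (int)R::rpois(len) : 0;
    for (int j = 0; j < k; ++j) cx.push_back(R::runif(0.0, len));
    koff[g + 1] = (int)cx.size();
    std::sort(cx.begin() + koff[g], cx.end());
  }

  const int* pm = INTEGER(M);
  const int* pp = INTEGER(P);
  int* po = INTEGER(out);
  const int nm = M.nrow();

  for (int l = 0; l < L; ++l) {
    const double x = pos[l];
    const int* mcol = pm + (R_xlen_t)l * nm;
    const int* pcol = pp + (R_xlen_t)l * nm;
    int* ocol = po + (R_xlen_t)l * n;
    for (int g = 0; g < n; ++g) {
      const int kend = koff[g + 1] - koff[g];
      int j = jj[g];
      while (j < kend && cx[koff[g] + j] < x) ++j;
      jj[g] = j;
      const int parent = rows[g] - 1;
      const int parity = (start[g] + j) & 1;
      const int m = mcol[parent];
      ocol[g] = m + parity * (pcol[parent] - m);
    }
  }
  return out;
}
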