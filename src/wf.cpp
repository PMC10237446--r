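#include <Rcpp.h>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Forward Wright-Fisher evolution of one chromosome.
//
// H: L x 2N integer matrix of 0/1 alleles; each column is a haplotype,
// columns 2k, 2k+1 (0-based) belong to diploid individual k.  Each
// generation every offspring draws a random parent individual per gamete
// and receives a recombinant of that parent's two haplotypes: crossover
// count ~ Poisson(map length), breakpoint positions uniform on the genetic
// map (pos_m, Morgans, nondecreasing).  Uses R's RNG, so results are
// reproducible from set.seed().
//
// mu: per-locus per-gamete recurrent (flip) mutation rate; 0 disables it.
//
// [[Rcpp::export]]
IntegerMatrix wf_evolve(IntegerMatrix H, NumericVector pos_m, int generations,
                        double mu = 0.0) {
  const int L = H.nrow();
  const int nh = H.ncol();
  if (nh % 2 != 0) stop("haplotype count must be even");
  const int N = nh / 2;
  if ((int)pos_m.size() != L) stop("pos_m length must match marker count");
  const double tot = (L > 0) ? (pos_m[L - 1] - pos_m[0]) : 0.0;

  IntegerMatrix A(clone(H));
  IntegerMatrix B(L, nh);
  int *cur = INTEGER(A), *nxt = INTEGER(B);

  std::vector<double> cuts;
  for (int g = 0; g < generations; ++g) {
    for (int off = 0; off < nh; ++off) {
      int parent = (int)(unif_rand() * N);
      if (parent >= N) parent = N - 1;
      const int *h0 = cur + (size_t)(2 * parent) * L;
      const int *h1 = h0 + L;
      int *dst = nxt + (size_t)off * L;
      int k = (unif_rand() < 0.5) ? 0 : 1;
      int ncross = (tot > 0) ? (int)R::rpois(tot) : 0;
      if (ncross == 0) {
        std::memcpy(dst, k ? h1 : h0, sizeof(int) * L);
        continue;
      }
      cuts.resize(ncross);
      for (int c = 0; c < ncross; ++c) cuts[c] = pos_m[0] + unif_rand() * tot;
      std::sort(cuts.begin(), cuts.end());
      int start = 0;
      for (int c = 0; c < ncross; ++c) {
        // first marker index strictly beyond the crossover point
        int brk = std::upper_bound(pos_m.begin(), pos_m.end(), cuts[c]) -
                  pos_m.begin();
        if (brk > start)
          std::memcpy(dst + start, (k ? h1 : h0) + start,
                      sizeof(int) * (brk - start));
        start = brk;
        k = 1 - k;
      }
      if (start < L)
        std::memcpy(dst + start, (k ? h1 : h0) + start,
                    sizeof(int) * (L - start));
    }
    if (mu > 0.0 && L > 0) {
      int nmut = (int)R::rpois(mu * (double)L * (double)nh);
      for (int m = 0; m < nmut; ++m) {
        size_t cell = (size_t)(unif_rand() * (double)L * (double)nh);
        if (cell >= (size_t)L * nh) cell = (size_t)L * nh - 1;
        nxt[cell] ^= 1;
      }
    }
    std::swap(cur, nxt);
  }
  return (cur == INTEGER(A)) ? A : B;
}
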