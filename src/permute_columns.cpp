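#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Independently permute the rows within each column of a numeric matrix
// (Fisher-Yates per column) -- the randomization step of the
// parallel-analysis eigenvalue null and the package's only compiled hot
// loop. The generator is an xorshift128+ stream seeded from R's RNG, so
// results are reproducible under set.seed while avoiding the per-element
// overhead of unif_rand().
// [[Rcpp::export]]
NumericMatrix permute_columns(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  RNGScope scope;
  uint64_t s0 = 0, s1 = 0;
  for (int b = 0; b < 4; ++b) {
    s0 = (s0 << 16) ^ (uint64_t)(unif_rand() * 65536.0);
    s1 = (s1 << 16) ^ (uint64_t)(unif_rand() * 65536.0);
  }
  if (s0 == 0 && s1 == 0) s0 = 0x9E3779B97F4A7C15ULL;
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) out(i, j) = x(i, j);
    for (int i = n - 1; i > 0; --i) {
      uint64_t t = s0;
      const uint64_t s = s1;
      s0 = s;
      t ^= t << 23;
      t ^= t >> 17;
      t ^= s ^ (s >> 26);
      s1 = t;
      int k = (int)((t + s) % (uint64_t)(i + 1));
      double tmp = out(i, j);
      out(i, j) = out(k, j);
      out(k, j) = tmp;
    }
  }
  return out;
}
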