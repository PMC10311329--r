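#include <Rcpp.h>
using namespace Rcpp;

// Sample a DNA sequence from a 3rd-order Markov chain.
//
// trans: 64 x 4 matrix of transition probabilities; row index encodes the
// 3-mer context (A=0, C=1, G=2, T=3; index = 16*c1 + 4*c2 + c3), columns give
// P(next base | context). Rows must sum to 1. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
std::string simulate_markov_sequence(int length, NumericMatrix trans) {
  if (length <= 0) return std::string();
  if (trans.nrow() != 64 || trans.ncol() != 4)
    stop("transition matrix must be 64 x 4");
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string seq(length, 'A');
  int ctx = 0;
  // first three bases uniform
  int head = length < 3 ? length : 3;
  for (int i = 0; i < head; ++i) {
    int b = (int)(unif_rand() * 4.0);
    if (b > 3) b = 3;
    seq[i] = bases[b];
    ctx = (ctx * 4 + b) % 64;
  }
  for (int i = 3; i < length; ++i) {
    double u = unif_rand();
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(ctx, j);
      if (u < acc) { b = j; break; }
    }
    seq[i] = bases[b];
    ctx = (ctx % 16) * 4 + b;
  }
  return seq;
}
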