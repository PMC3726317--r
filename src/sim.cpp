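// Sequencing-error injection: i.i.d. base substitutions at a fixed per-base
// rate, using R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static inline char other_base(char c, int shift) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  int b;
  switch (c) {
  case 'A': b = 0; break; case 'C': b = 1; break;
  case 'G': b = 2; break; case 'T': b = 3; break;
  default: return c;
  }
  return B[(b + shift) % 4];
}

// [[Rcpp::export]]
List cpp_inject_errors(CharacterVector seqs, double rate) {
  RNGScope scope;
  CharacterVector out(seqs.size());
  IntegerVector nerr(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int n = 0;
    if (rate > 0) {
      for (size_t j = 0; j < s.size(); ++j) {
        if (unif_rand() < rate) {
          int shift = 1 + (int)std::floor(unif_rand() * 3.0);
          if (shift > 3) shift = 3;
          s[j] = other_base(s[j], shift);
          ++n;
        }
      }
    }
    out[i] = s;
    nerr[i] = n;
  }
  return List::create(_["sequence"] = out, _["n_errors"] = nerr);
}
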