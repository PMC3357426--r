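#include <Rcpp.h>
using namespace Rcpp;

// Sample a nucleotide sequence from a transition model conditioned on the
// preceding trinucleotide (64 contexts x 4 bases, row-stochastic).  Uses
// R's RNG so results are reproducible under set.seed().
// init: probabilities for the first three bases (length 4).
// [[Rcpp::export(name = ".sampleMarkovSeq")]]
CharacterVector sampleMarkovSeq(int n, NumericMatrix trans, NumericVector init) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  if (n < 1) return CharacterVector::create("");
  std::string out(n, 'A');
  // cumulative rows for fast inversion sampling
  std::vector<double> cum(64 * 4);
  for (int r = 0; r < 64; ++r) {
    double c = 0;
    for (int b = 0; b < 4; ++b) { c += trans(r, b); cum[r * 4 + b] = c; }
  }
  double ic[4]; double c = 0;
  for (int b = 0; b < 4; ++b) { c += init[b]; ic[b] = c; }
  int ctx = 0;
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    int b = 0;
    if (i < 3) {
      while (b < 3 && u > ic[b]) ++b;
    } else {
      const double *row = &cum[ctx * 4];
      while (b < 3 && u > row[b]) ++b;
    }
    out[i] = bases[b];
    ctx = ((ctx << 2) | b) & 63;
  }
  PutRNGstate();
  return CharacterVector::create(out);
}
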