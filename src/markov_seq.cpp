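#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov nucleotide sequence with a modified transition row
// out of C, used to set the CpG observed/expected ratio independently of
// base composition. States 1=A, 2=C, 3=G, 4=T (1-based for R). `freqs`
// is the transition distribution from non-C states (and the initial
// distribution); `from_c` is the transition distribution out of C.
// Draws from R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector markov_sequence(int n, NumericVector freqs,
                              NumericVector from_c) {
  if (freqs.size() != 4 || from_c.size() != 4)
    stop("freqs and from_c must have length 4");
  NumericVector cum0 = cumsum(freqs).get();
  NumericVector cumC = cumsum(from_c).get();
  cum0 = cum0 / cum0[3];
  cumC = cumC / cumC[3];
  IntegerVector out(n);
  int prev = 0;
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    const NumericVector &cum = (prev == 2) ? cumC : cum0;
    int s = 1;
    while (s < 4 && u > cum[s - 1]) ++s;
    out[i] = s;
    prev = s;
  }
  return out;
}
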