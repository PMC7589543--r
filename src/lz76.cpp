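#include <Rcpp.h>
using namespace Rcpp;

// LZ76 exhaustive-history phrase count (Kaspar-Schuster scan).
// A new phrase ends at the first position where the current extension is no
// longer a substring (self-overlap allowed) of the sequence seen so far.
// [[Rcpp::export]]
int lz76_phrase_count(IntegerVector s) {
  int n = s.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 1;
  int c = 1;   // first symbol is always a phrase
  int l = 1;   // start of current phrase (0-based)
  while (l < n) {
    int kmax = 0;
    // longest match of s[l..] against any start i < l (copy may run past l)
    for (int i = 0; i < l; ++i) {
      int k = 0;
      while (l + k < n && s[i + k] == s[l + k]) ++k;
      if (k > kmax) kmax = k;
      if (l + kmax >= n) break;
    }
    ++c;
    if (l + kmax >= n) break;   // tail reproducible: it is the last phrase
    l += kmax + 1;              // phrase = longest reproducible prefix + 1 symbol
  }
  return c;
}
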