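#include <Rcpp.h>
using namespace Rcpp;

// Kaspar-Schuster production parsing of the LZ76 exhaustive history.
// `bits` is a 0/1 integer vector; returns the number of words c(n).
// Convention: copying may overlap the current word; the final, possibly
// uncompleted word counts toward c.
//
// Bookkeeping (1-based view): l = symbols consumed so far, the current word
// starts at l+1; i+1 = candidate copy start within the history; k = current
// match length; kmax = longest match over candidate starts tried so far.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(const IntegerVector& bits) {
  const int n = bits.size();
  if (n == 0) stop("empty sequence");
  if (n == 1) return 1;
  std::vector<signed char> s(n);
  for (int t = 0; t < n; ++t) s[t] = static_cast<signed char>(bits[t]);
  const signed char* p = s.data();
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  for (;;) {
    if (p[i + k - 1] != p[l + k - 1]) {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {            // no copy source anywhere: word completes
        ++c;
        l += kmax;
        if (l + 1 > n) break;  // everything consumed
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    } else {
      ++k;
      if (l + k > n) {         // word still copyable at end of string
        ++c;
        break;
      }
    }
  }
  return c;
}
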