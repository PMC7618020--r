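#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter: y = filter(b, a, x), a[0] == 1
// (coefficients come from signal::butter; this is only the sample loop,
// kept in C++ because R-level per-sample recursion dominates pipeline time).
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(const NumericVector& b, const NumericVector& a,
                         const NumericVector& x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na);
  std::vector<double> w(nw, 0.0);
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + w[0];
    for (int k = 0; k < nw - 1; ++k) {
      double wk = w[k + 1];
      if (k + 1 < nb) wk += b[k + 1] * xt;
      if (k + 1 < na) wk -= a[k + 1] * yt;
      w[k] = wk;
    }
    w[nw - 1] = 0.0;
    y[t] = yt;
  }
  return y;
}
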