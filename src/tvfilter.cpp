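#include <Rcpp.h>
using namespace Rcpp;

// Cascade of a time-varying two-pole resonator: per-sample coefficients
// a1[t], a2[t] (denominator), unit numerator with gain g[t].
// y[t] = g[t] * x[t] - a1[t] * y[t-1] - a2[t] * y[t-2]
//
// [[Rcpp::export(name = ".tv_resonator")]]
NumericVector tv_resonator(NumericVector x, NumericVector a1,
                           NumericVector a2, NumericVector g) {
  const int n = x.size();
  NumericVector y(n);
  double y1 = 0.0, y2 = 0.0;
  for (int t = 0; t < n; ++t) {
    const double v = g[t] * x[t] - a1[t] * y1 - a2[t] * y2;
    y[t] = v;
    y2 = y1;
    y1 = v;
  }
  return y;
}
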