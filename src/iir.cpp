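#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// a must be normalized (a[0] == 1) and the same length as b.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size();
  if (a.size() != nb) stop("b and a must have equal length");
  if (zi.size() != nb - 1) stop("zi must have length(b) - 1");
  int n = x.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int k = 0; k < nb - 2; ++k) {
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    }
    z[nb - 2] = b[nb - 1] * xi - a[nb - 1] * yi;
    y[i] = yi;
  }
  return y;
}
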