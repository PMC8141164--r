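#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Approximate entropy, Pincus construction: self-matches included, phase m
// uses N-m+1 windows, phase m+1 uses N-m windows. Pairwise symmetry halves
// the distance work; the Chebyshev comparison bails out at the tolerance.
// [[Rcpp::export]]
double apen_cpp(NumericVector xs, int m, double r) {
  int n = xs.size();
  if (n <= m + 1) stop("signal too short for ApEn");
  const double* x = xs.begin();
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int M = n - mm + 1;
    std::vector<int> cnt(M, 1); // self-match
    for (int i = 0; i < M; ++i) {
      for (int j = i + 1; j < M; ++j) {
        bool within = true;
        for (int k = 0; k < mm; ++k) {
          if (std::fabs(x[i + k] - x[j + k]) > r) { within = false; break; }
        }
        if (within) { ++cnt[i]; ++cnt[j]; }
      }
    }
    double acc = 0.0;
    for (int i = 0; i < M; ++i) acc += std::log((double)cnt[i] / M);
    phi[s] = acc / M;
  }
  return phi[0] - phi[1];
}

// Fuzzy entropy: both phases use N-m windows; each window has its own mean
// removed before the Chebyshev distance; membership exp(-(d/r)^p); self-
// matches excluded (mean over j != i with denominator N-m-1).
// [[Rcpp::export]]
double fuzzyen_cpp(NumericVector xs, int m, double r, double p) {
  int n = xs.size();
  int M = n - m;            // window count shared by both phases
  if (M < 2) stop("signal too short for FuzzyEn");
  const double* x = xs.begin();
  bool squared = (p == 2.0);
  double inv_r = 1.0 / r;
  double lnphi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    // baseline-removed windows, contiguous row-major
    std::vector<double> w((size_t)M * mm);
    for (int i = 0; i < M; ++i) {
      double mu = 0.0;
      for (int k = 0; k < mm; ++k) mu += x[i + k];
      mu /= mm;
      for (int k = 0; k < mm; ++k) w[(size_t)i * mm + k] = x[i + k] - mu;
    }
    std::vector<double> sim(M, 0.0);
    for (int i = 0; i < M; ++i) {
      const double* wi = &w[(size_t)i * mm];
      for (int j = i + 1; j < M; ++j) {
        const double* wj = &w[(size_t)j * mm];
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double v = std::fabs(wi[k] - wj[k]);
          if (v > d) d = v;
        }
        double u = d * inv_r;
        double mshp = squared ? std::exp(-u * u) : std::exp(-std::pow(u, p));
        sim[i] += mshp;
        sim[j] += mshp;
      }
    }
    double acc = 0.0;
    for (int i = 0; i < M; ++i) acc += sim[i] / (M - 1);
    lnphi[s] = std::log(acc / M);
  }
  return lnphi[0] - lnphi[1];
}
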