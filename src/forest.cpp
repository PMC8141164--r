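#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Deterministic, platform-independent RNG (xorshift64*), so forests are
// bit-identical for a given seed on any compiler.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Node {
  int feat = -1;        // -1: leaf
  double thr = 0.0;
  int left = -1, right = -1;
  int pred = 0;         // leaf majority class
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y; // 0/1
  int mtry;
  XRng& rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              XRng& rng_) : X(X_), y(y_), mtry(mtry_), rng(rng_) {}

  int majority(const std::vector<int>& idx) {
    int c1 = 0;
    for (int i : idx) c1 += y[i];
    int c0 = (int)idx.size() - c1;
    if (c1 == c0) return rng.below(2); // exact tie: random, seeded
    return c1 > c0 ? 1 : 0;
  }

  int grow(const std::vector<int>& idx) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    int c1 = 0;
    for (int i : idx) c1 += y[i];
    if (c1 == 0 || c1 == (int)idx.size() || idx.size() < 2) {
      nodes[id].pred = majority(idx);
      return id;
    }
    int p = X.ncol();
    // sample mtry distinct features
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      std::swap(feats[j], feats[j + rng.below(p - j)]);
    }
    double bestGini = 1e300, bestThr = 0.0;
    int bestFeat = -1;
    int n = (int)idx.size();
    std::vector<std::pair<double, int>> vals(n);
    for (int f = 0; f < mtry && f < p; ++f) {
      int j = feats[f];
      for (int t = 0; t < n; ++t) vals[t] = { X(idx[t], j), y[idx[t]] };
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int t = 0; t < n - 1; ++t) {
        l1 += vals[t].second;
        if (vals[t + 1].first <= vals[t].first) continue; // tied value
        int nl = t + 1, nr = n - nl;
        int r1 = c1 - l1;
        double gl = 1.0 - (double)l1 * l1 / ((double)nl * nl)
                        - (double)(nl - l1) * (nl - l1) / ((double)nl * nl);
        double gr = 1.0 - (double)r1 * r1 / ((double)nr * nr)
                        - (double)(nr - r1) * (nr - r1) / ((double)nr * nr);
        double g = (nl * gl + nr * gr) / n;
        if (g < bestGini - 1e-12) {
          bestGini = g; bestFeat = j;
          bestThr = 0.5 * (vals[t].first + vals[t + 1].first);
        }
      }
    }
    if (bestFeat < 0) { // all sampled features constant on this node
      nodes[id].pred = majority(idx);
      return id;
    }
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, bestFeat) <= bestThr) li.push_back(i); else ri.push_back(i);
    }
    nodes[id].feat = bestFeat;
    nodes[id].thr = bestThr;
    int l = grow(li);
    int r = grow(ri);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  int predict(const NumericMatrix& Xt, int row) const {
    int id = 0;
    while (nodes[id].feat >= 0) {
      id = (Xt(row, nodes[id].feat) <= nodes[id].thr) ? nodes[id].left
                                                      : nodes[id].right;
    }
    return nodes[id].pred;
  }
};

// Grow a random forest on (Xtr, y) and return, for each row of Xte, the
// fraction of trees voting class 1. Bootstrap per tree, mtry features per
// node, trees grown to purity.
// [[Rcpp::export]]
NumericVector rf_votes_cpp(NumericMatrix Xtr, IntegerVector y,
                           NumericMatrix Xte, int ntree, int mtry,
                           double seed) {
  int n = Xtr.nrow(), nt = Xte.nrow();
  if (y.size() != n) stop("label length must match training rows");
  XRng rng((uint64_t)seed);
  std::vector<double> votes(nt, 0.0);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = rng.below(n);
    TreeBuilder tb(Xtr, y, mtry, rng);
    tb.grow(boot);
    for (int i = 0; i < nt; ++i) votes[i] += tb.predict(Xte, i);
  }
  NumericVector out(nt);
  for (int i = 0; i < nt; ++i) out[i] = votes[i] / ntree;
  return out;
}
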