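#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling over the channel x time grid. A point is
// connected to its spatial neighbours at the same time sample and to itself
// at adjacent time samples. Node index (0-based): ch + t * nch.
static void flood(int start, int cur, const std::vector<signed char> &keep,
                  std::vector<int> &labels,
                  const std::vector<std::vector<int>> &nb,
                  int nch, int ntime, std::vector<int> &stack) {
  stack.clear();
  stack.push_back(start);
  labels[start] = cur;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    int ch = v % nch, t = v / nch;
    if (t > 0) {
      int u = v - nch;
      if (keep[u] && !labels[u]) { labels[u] = cur; stack.push_back(u); }
    }
    if (t < ntime - 1) {
      int u = v + nch;
      if (keep[u] && !labels[u]) { labels[u] = cur; stack.push_back(u); }
    }
    int base = t * nch;
    for (int k : nb[ch]) {
      int u = base + k;
      if (keep[u] && !labels[u]) { labels[u] = cur; stack.push_back(u); }
    }
  }
}

static std::vector<std::vector<int>> build_nb(List adj, int nch) {
  std::vector<std::vector<int>> nb(nch);
  for (int c = 0; c < nch; c++) {
    IntegerVector a = adj[c];
    for (int j = 0; j < a.size(); j++) nb[c].push_back(a[j] - 1);
  }
  return nb;
}

// [[Rcpp::export]]
IntegerVector cpp_label_clusters(LogicalVector keep_in, List adj, int nch,
                                 int ntime) {
  int P = keep_in.size();
  std::vector<signed char> keep(P);
  for (int i = 0; i < P; i++) keep[i] = keep_in[i] ? 1 : 0;
  std::vector<int> labels(P, 0), stack;
  auto nb = build_nb(adj, nch);
  int cur = 0;
  for (int i = 0; i < P; i++) {
    if (keep[i] && !labels[i]) flood(i, ++cur, keep, labels, nb, nch, ntime, stack);
  }
  return IntegerVector(labels.begin(), labels.end());
}

// For each permutation (row of tmat): the largest positive cluster mass and
// the smallest (most negative) negative cluster mass, clustering the
// suprathreshold points |t| > tcrit separately by sign.
// [[Rcpp::export]]
NumericMatrix cpp_perm_extremes(NumericMatrix tmat, double tcrit, List adj,
                                int nch, int ntime) {
  int B = tmat.nrow(), P = tmat.ncol();
  auto nb = build_nb(adj, nch);
  NumericMatrix out(B, 2);
  std::vector<signed char> keep(P);
  std::vector<int> labels(P), stack;
  for (int b = 0; b < B; b++) {
    for (int sgn = 0; sgn < 2; sgn++) {
      double best = 0.0;
      for (int i = 0; i < P; i++) {
        double tv = tmat(b, i);
        keep[i] = (sgn == 0 ? tv > tcrit : tv < -tcrit) ? 1 : 0;
        labels[i] = 0;
      }
      int cur = 0;
      for (int i = 0; i < P; i++) {
        if (keep[i] && !labels[i]) {
          flood(i, ++cur, keep, labels, nb, nch, ntime, stack);
        }
      }
      if (cur > 0) {
        std::vector<double> mass(cur + 1, 0.0);
        for (int i = 0; i < P; i++)
          if (labels[i]) mass[labels[i]] += tmat(b, i);
        for (int c = 1; c <= cur; c++) {
          if (sgn == 0) { if (mass[c] > best) best = mass[c]; }
          else          { if (mass[c] < best) best = mass[c]; }
        }
      }
      out(b, sgn) = best;
    }
  }
  return out;
}
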