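#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Cluster score of one sequence from its positive log-odds hits:
// greedy non-overlap resolution by descending score (ties by position),
// then the best sliding-window sum of retained hits.
static double cluster_score(std::vector<int> &pos, std::vector<double> &sc,
                            int w, int window_bp, int L) {
  int n = pos.size();
  if (n == 0) return 0.0;
  if (n == 1) return sc[0];
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (sc[a] != sc[b]) return sc[a] > sc[b];
    return pos[a] < pos[b];
  });
  std::vector<char> occ(L + w, 0);
  std::vector<int> kpos;
  std::vector<double> ksc;
  for (int ii = 0; ii < n; ++ii) {
    int p0 = pos[idx[ii]];
    bool free = true;
    for (int q = p0; q < p0 + w; ++q)
      if (occ[q]) { free = false; break; }
    if (free) {
      for (int q = p0; q < p0 + w; ++q) occ[q] = 1;
      kpos.push_back(p0);
      ksc.push_back(sc[idx[ii]]);
    }
  }
  int m = kpos.size();
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return kpos[a] < kpos[b];
  });
  std::vector<int> sp(m);
  std::vector<double> ss(m);
  for (int i = 0; i < m; ++i) { sp[i] = kpos[ord[i]]; ss[i] = ksc[ord[i]]; }
  if (window_bp >= L) {
    double tot = 0;
    for (int i = 0; i < m; ++i) tot += ss[i];
    return tot;
  }
  // windows of window_bp containing whole hits: pos in [W, W + window_bp - w]
  int span = window_bp - w;
  double best = 0, cur = 0;
  int lo_i = 0;
  for (int i = 0; i < m; ++i) {
    cur += ss[i];
    while (sp[lo_i] < sp[i] - span) cur -= ss[lo_i++];
    if (cur > best) best = cur;
  }
  return best;
}

// Scan a concatenated, integer-encoded promoter set (1..4 = ACGT, 5 kills
// any window) against one motif on both strands and return the
// per-sequence windowed cluster score.
// [[Rcpp::export]]
NumericVector scan_concat_cpp(IntegerVector vec, NumericMatrix lo,
                              NumericMatrix lo_rc, int window_bp,
                              IntegerVector starts, IntegerVector len) {
  int w = lo.ncol();
  int n = starts.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    int L = len[s];
    int off = starts[s] - 1;  // R index -> 0-based
    int np = L - w + 1;
    if (np <= 0) continue;
    std::vector<int> pos;
    std::vector<double> sc;
    for (int p = 0; p < np; ++p) {
      double f = 0, r = 0;
      for (int j = 0; j < w; ++j) {
        int c = vec[off + p + j] - 1;
        f += lo(c, j);
        r += lo_rc(c, j);
      }
      if (f > 0) { pos.push_back(p + 1); sc.push_back(f); }
      if (r > 0) { pos.push_back(p + 1); sc.push_back(r); }
    }
    out[s] = cluster_score(pos, sc, w, window_bp, L);
  }
  return out;
}
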