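#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Average-linkage agglomerative clustering via Lance-Williams updates.
//
// Clusters are identified by the smallest original row index (1-based) of
// their members; a merge keeps the smaller of the two ids.  Ties in the
// minimal linkage distance break towards the lexicographically smallest
// (i, j) id pair.  Equivalent to the naive all-cross-pairs recompute (the
// average-linkage distance between merged clusters is the size-weighted
// mean of the old distances), but O(N^2) in the typical case through
// nearest-neighbour caching.
//
// d: full N x N symmetric distance matrix; k: number of clusters to keep;
// linkage: 0 = average, 1 = single, 2 = complete.  Returns integer labels
// 1..k (in order of cluster id) and the merge history (id1 < id2, linkage
// distance) for the N - k merges.
// [[Rcpp::export(name = ".ah_linkage_cpp")]]
List ah_linkage_cpp(NumericMatrix d, int k, int linkage = 0) {
  const int n = d.nrow();
  if (d.ncol() != n) stop("distance matrix must be square");
  if (k < 1 || k > n) stop("k must be in [1, N]");

  // working copy of the distance matrix
  std::vector<double> dd(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      dd[static_cast<size_t>(i) * n + j] = d(i, j);

  std::vector<bool> active(n, true);
  std::vector<int> size(n, 1);
  std::vector<int> nn(n, -1);          // nearest active neighbour (any index != i)
  std::vector<double> nnd(n, 0.0);

  const double inf = std::numeric_limits<double>::infinity();

  auto recompute_nn = [&](int i) {
    double best = inf;
    int bestj = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i || !active[j]) continue;
      double v = dd[static_cast<size_t>(i) * n + j];
      if (v < best) { best = v; bestj = j; }   // strict <: smallest j wins ties
    }
    nn[i] = bestj;
    nnd[i] = best;
  };

  for (int i = 0; i < n; ++i) recompute_nn(i);

  const int nmerge = n - k;
  IntegerVector m_id1(nmerge), m_id2(nmerge);
  NumericVector m_dist(nmerge);

  for (int step = 0; step < nmerge; ++step) {
    // global minimum: ascending scan with strict < gives the smallest i,
    // and nn[i] already holds the smallest j for that i.
    double best = inf;
    int a = -1;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      if (nnd[i] < best) { best = nnd[i]; a = i; }
    }
    int b = nn[a];
    if (b < a) { int t = a; a = b; b = t; }   // a keeps the smaller id

    m_id1[step] = a + 1;
    m_id2[step] = b + 1;
    m_dist[step] = best;

    // Lance-Williams update: d(a+b, x)
    const double na = size[a], nb = size[b];
    for (int x = 0; x < n; ++x) {
      if (!active[x] || x == a || x == b) continue;
      const double dax = dd[static_cast<size_t>(a) * n + x];
      const double dbx = dd[static_cast<size_t>(b) * n + x];
      double v;
      if (linkage == 1)      v = dax < dbx ? dax : dbx;          // single
      else if (linkage == 2) v = dax > dbx ? dax : dbx;          // complete
      else                   v = (na * dax + nb * dbx) / (na + nb);
      dd[static_cast<size_t>(a) * n + x] = v;
      dd[static_cast<size_t>(x) * n + a] = v;
    }
    size[a] += size[b];
    active[b] = false;

    recompute_nn(a);
    for (int x = 0; x < n; ++x) {
      if (!active[x] || x == a) continue;
      if (nn[x] == a || nn[x] == b) {
        recompute_nn(x);
      } else {
        double v = dd[static_cast<size_t>(x) * n + a];
        // prefer the smaller index on exact ties, matching a full rescan
        if (v < nnd[x] || (v == nnd[x] && a < nn[x])) { nn[x] = a; nnd[x] = v; }
      }
    }
  }

  // labels 1..k in ascending cluster-id order
  std::vector<int> ids;
  for (int i = 0; i < n; ++i) if (active[i]) ids.push_back(i);
  std::vector<int> owner(n, -1);
  // trace each point to its surviving cluster id by replaying merges
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int s = 0; s < nmerge; ++s) {
    int a = m_id1[s] - 1, b = m_id2[s] - 1;
    for (int i = 0; i < n; ++i) if (parent[i] == b) parent[i] = a;
  }
  IntegerVector labels(n);
  for (size_t c = 0; c < ids.size(); ++c)
    for (int i = 0; i < n; ++i)
      if (parent[i] == ids[c]) labels[i] = static_cast<int>(c) + 1;
  (void)owner;

  return List::create(
    _["labels"] = labels,
    _["merge_id1"] = m_id1,
    _["merge_id2"] = m_id2,
    _["merge_dist"] = m_dist);
}
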