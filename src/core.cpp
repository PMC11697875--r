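#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Path ENumeration (PEN) and its uniform-sampling variant (URPEN).
//
// Grows simple paths by appending vertices adjacent to the current tail
// that are not already on the path. Each undirected path is generated once
// from each endpoint; only the canonical orientation (last vertex index >
// first) is emitted. With per-depth probabilities p_d < 1, each candidate
// extension at depth d is traversed with probability p_d, so every leaf
// (path) is reached with probability prod(p_d) -- uniform over paths.
//
// radialMode: 0 = none; 1 = symmetric two-endpoint criterion (distance
// from the first node strictly increases forward AND distance from the
// last node strictly increases backward); 2 = forward-only variant;
// 3 = pairwise-monotone criterion (for every pair, path distance and
// physical distance are concordant: d(v_i, v_j) strictly increases with
// |i - j| along both index directions). Modes 1-2: only the forward
// chain is prefix-stable, so it is pruned during extension and the
// backward chain is checked at emission. Mode 3 is fully incremental:
// appending w requires d(v_i, w) > d(v_i, v_last) and
// d(v_i, w) > d(v_{i+1}, w) for every earlier i, both prefix-stable.

static inline double dist2(const NumericMatrix& co, int a, int b) {
  double s = 0.0;
  for (int j = 0; j < co.ncol(); ++j) {
    double d = co(a - 1, j) - co(b - 1, j);
    s += d * d;
  }
  return s;
}

struct PenState {
  const std::vector< std::vector<int> >* adj;
  const NumericMatrix* co;
  const NumericVector* probs;
  int k;
  int radialMode;
  bool stochastic;
  std::vector<int> path;
  std::vector<char> inPath;
  std::vector<int> out;
};

static void penExtend(PenState& st, int depth) {
  if (depth == st.k) {
    const std::vector<int>& p = st.path;
    if (p[st.k - 1] <= p[0]) return;
    if (st.radialMode == 1) {
      // backward chain from the final endpoint
      int last = p[st.k - 1];
      for (int i = st.k - 2; i > 0; --i) {
        if (!(dist2(*st.co, last, p[i]) < dist2(*st.co, last, p[i - 1])))
          return;
      }
    }
    st.out.insert(st.out.end(), p.begin(), p.end());
    return;
  }
  int tail = st.path[depth - 1];
  int root = st.path[0];
  const std::vector<int>& nb = (*st.adj)[tail - 1];
  double pd = (*st.probs)[depth];  // probability of descending to depth+1
  for (size_t i = 0; i < nb.size(); ++i) {
    int w = nb[i];
    if (st.inPath[w]) continue;
    if (st.radialMode == 1 || st.radialMode == 2) {
      // forward chain: strictly increasing distance from the root
      // (at depth 1, tail == root and the requirement is d > 0)
      double dTail = (depth == 1) ? 0.0 : dist2(*st.co, root, tail);
      if (!(dist2(*st.co, root, w) > dTail)) continue;
    } else if (st.radialMode == 3) {
      bool ok = true;
      double dPrev = -1.0;  // d(v_{i+1}, w) of the previous i, scanned down
      for (int i = depth - 1; i >= 0; --i) {
        double diw = dist2(*st.co, st.path[i], w);
        if (diw <= dPrev) { ok = false; break; }
        if (i < depth - 1 &&
            !(diw > dist2(*st.co, st.path[i], tail))) { ok = false; break; }
        dPrev = diw;
      }
      if (!ok) continue;
    }
    if (st.stochastic && pd < 1.0) {
      if (pd <= 0.0 || unif_rand() >= pd) continue;
    }
    st.path[depth] = w;
    st.inPath[w] = 1;
    penExtend(st, depth + 1);
    st.inPath[w] = 0;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_pen(List adjList, int k, NumericVector probs,
                      NumericMatrix coords, int radialMode) {
  int n = adjList.size();
  std::vector< std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adjList[i];
    adj[i].assign(v.begin(), v.end());
  }
  bool stochastic = false;
  for (int d = 0; d < k; ++d) if (probs[d] < 1.0) stochastic = true;

  PenState st;
  st.adj = &adj;
  st.co = &coords;
  st.probs = &probs;
  st.k = k;
  st.radialMode = radialMode;
  st.stochastic = stochastic;
  st.path.assign(k, 0);
  st.inPath.assign(n + 1, 0);

  double p0 = probs[0];
  for (int v = 1; v <= n; ++v) {
    if (stochastic && p0 < 1.0) {
      if (p0 <= 0.0 || unif_rand() >= p0) continue;
    }
    st.path[0] = v;
    st.inPath[v] = 1;
    penExtend(st, 1);
    st.inPath[v] = 0;
  }

  int m = st.out.size() / k;
  IntegerMatrix res(m, k);
  for (int r = 0; r < m; ++r)
    for (int j = 0; j < k; ++j)
      res(r, j) = st.out[(size_t)r * k + j];
  return res;
}

// Greedy maximal node-disjoint occurrence selection, per word.
//
// `order` (1-based occurrence row indices) must be grouped by word; within
// each word the order is the deterministic occurrence order. `code` gives
// the word group (1..nWords) of each occurrence. An occurrence is accepted
// iff none of its nodes was already used by an accepted occurrence of the
// same word. Returns per-word counts and the accepted flags.
// [[Rcpp::export]]
List cpp_znic_count(IntegerVector order, IntegerVector code,
                    IntegerMatrix nodes, int nWords, int nNodes) {
  int W = nodes.ncol();
  IntegerVector counts(nWords);
  LogicalVector selected(nodes.nrow());
  std::vector<int> stamp(nNodes + 1, 0);
  for (int i = 0; i < order.size(); ++i) {
    int r = order[i] - 1;
    int w = code[r];
    bool ok = true;
    for (int j = 0; j < W; ++j) {
      if (stamp[nodes(r, j)] == w) { ok = false; break; }
    }
    if (!ok) continue;
    counts[w - 1] += 1;
    selected[r] = true;
    for (int j = 0; j < W; ++j) stamp[nodes(r, j)] = w;
  }
  return List::create(_["counts"] = counts, _["selected"] = selected);
}

// Single greedy walk with one shared node mask: occurrences are processed
// in the given order (ranked words first) and accepted iff all their nodes
// are still free; accepted occurrences claim their nodes. Used for the
// incremental ZNIC counts of enrichment and for hold-out scoring.
// [[Rcpp::export]]
LogicalVector cpp_masked_walk(IntegerVector order, IntegerMatrix nodes,
                              int nNodes) {
  int W = nodes.ncol();
  LogicalVector accepted(order.size());
  std::vector<char> used(nNodes + 1, 0);
  for (int i = 0; i < order.size(); ++i) {
    int r = order[i] - 1;
    bool ok = true;
    for (int j = 0; j < W; ++j) {
      if (used[nodes(r, j)]) { ok = false; break; }
    }
    if (!ok) continue;
    accepted[i] = true;
    for (int j = 0; j < W; ++j) used[nodes(r, j)] = 1;
  }
  return accepted;
}

// Full word table in one pass: encode each occurrence's label word in
// base L+1 (skipping occurrences touching erased nodes), collect the
// unique words in sorted order, group the occurrence rows by word
// (counting sort; stable, so rows stay in their deterministic stored
// order within each word), and run the greedy per-word ZNIC selection.
// [[Rcpp::export]]
List cpp_word_table(IntegerVector labels, IntegerMatrix nodes, int L,
                    int nNodes) {
  int m = nodes.nrow(), W = nodes.ncol();
  std::vector<long long> id(m, -1);
  long long base = L + 1;
  std::unordered_map<long long, int> seen;
  seen.reserve(1 << 14);
  for (int r = 0; r < m; ++r) {
    long long v = 0;
    bool ok = true;
    for (int j = 0; j < W; ++j) {
      int lab = labels[nodes(r, j) - 1];
      if (lab <= 0) { ok = false; break; }
      v = v * base + lab;
    }
    if (!ok) continue;
    id[r] = v;
    seen.emplace(v, 0);
  }
  int nW = seen.size();
  std::vector<long long> uw;
  uw.reserve(nW);
  for (auto& kv : seen) uw.push_back(kv.first);
  std::sort(uw.begin(), uw.end());
  for (int i = 0; i < nW; ++i) seen[uw[i]] = i;

  IntegerVector occCounts(nW);
  std::vector<int> code(m, -1);
  for (int r = 0; r < m; ++r) {
    if (id[r] < 0) continue;
    code[r] = seen[id[r]];
    occCounts[code[r]] += 1;
  }
  std::vector<int> pos(nW + 1, 0);
  for (int i = 0; i < nW; ++i) pos[i + 1] = pos[i] + occCounts[i];
  IntegerVector order(pos[nW]);
  std::vector<int> fill(pos.begin(), pos.end() - 1);
  for (int r = 0; r < m; ++r) {
    if (code[r] < 0) continue;
    order[fill[code[r]]++] = r + 1;
  }

  IntegerVector counts(nW);
  LogicalVector selected(m);
  std::vector<int> stamp(nNodes + 1, -1);
  int total = 0;
  for (int i = 0; i < order.size(); ++i) {
    int r = order[i] - 1;
    int w = code[r];
    bool free_ = true;
    for (int j = 0; j < W; ++j) {
      if (stamp[nodes(r, j)] == w) { free_ = false; break; }
    }
    if (!free_) continue;
    counts[w] += 1;
    selected[r] = true;
    ++total;
    for (int j = 0; j < W; ++j) stamp[nodes(r, j)] = w;
  }

  NumericVector uwOut(nW);
  for (int i = 0; i < nW; ++i) uwOut[i] = (double)uw[i];
  return List::create(_["uw"] = uwOut, _["counts"] = counts,
                      _["occCounts"] = occCounts, _["order"] = order,
                      _["selected"] = selected, _["total"] = total);
}

// Breadth-first search ball: all vertices within graph distance <= K of
// `start` (excluding start itself). Used by the kernel-shuffle null model.
// [[Rcpp::export]]
IntegerVector cpp_bfs_ball(List adjList, int start, int K) {
  int n = adjList.size();
  std::vector<int> depth(n + 1, -1);
  std::vector<int> queue;
  queue.push_back(start);
  depth[start] = 0;
  size_t head = 0;
  std::vector<int> out;
  while (head < queue.size()) {
    int v = queue[head++];
    if (depth[v] >= K) continue;
    IntegerVector nb = adjList[v - 1];
    for (int i = 0; i < nb.size(); ++i) {
      int w = nb[i];
      if (depth[w] < 0) {
        depth[w] = depth[v] + 1;
        out.push_back(w);
        queue.push_back(w);
      }
    }
  }
  return wrap(out);
}
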