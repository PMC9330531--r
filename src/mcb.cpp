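#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Minimum cycle basis of a simple undirected graph by Horton's method:
// candidate cycles C(r, e) = SP(r, u) + SP(r, v) + (u, v) over all roots r
// and edges e = (u, v), restricted to candidates whose two tree paths are
// edge-disjoint (these always contain a minimum basis when shortest paths
// are taken consistently from one tree per root); candidates are sorted by
// (weight, support) and selected greedily by GF(2) Gaussian elimination
// over the edge space until the cyclomatic number is reached.

struct Cand {
  double w;
  std::vector<uint64_t> bits;
  int nbits;
};

static inline bool get_bit(const std::vector<uint64_t>& b, int i) {
  return (b[i >> 6] >> (i & 63)) & 1ULL;
}
static inline void flip_bit(std::vector<uint64_t>& b, int i) {
  b[i >> 6] ^= (1ULL << (i & 63));
}

static bool bits_less(const std::vector<uint64_t>& a, const std::vector<uint64_t>& b) {
  for (size_t i = 0; i < a.size(); i++) if (a[i] != b[i]) return a[i] < b[i];
  return false;
}

// [[Rcpp::export(name = ".mcb_cpp")]]
List mcb_cpp(int nv, IntegerMatrix edges, NumericVector weights) {
  const int m = edges.nrow();
  const int W = (m + 63) / 64;

  std::vector<std::vector<std::pair<int,int>>> adj(nv); // (nbr, edge id)
  for (int e = 0; e < m; e++) {
    int u = edges(e, 0), v = edges(e, 1);
    adj[u].push_back({v, e});
    adj[v].push_back({u, e});
  }

  // components for cyclomatic number
  std::vector<int> comp(nv, -1);
  int ncomp = 0;
  for (int s = 0; s < nv; s++) {
    if (comp[s] >= 0) continue;
    ncomp++;
    std::vector<int> stack = {s};
    comp[s] = ncomp;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (auto& pr : adj[u]) if (comp[pr.first] < 0) { comp[pr.first] = ncomp; stack.push_back(pr.first); }
    }
  }
  int cyc = m - nv + ncomp;
  if (cyc <= 0) return List::create(_["cycles"] = List(), _["weights"] = NumericVector());

  std::vector<Cand> cands;
  std::vector<double> dist(nv);
  std::vector<int> pedge(nv);

  for (int r = 0; r < nv; r++) {
    // Dijkstra from r (unit weights reduce to BFS cost but stay general)
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(pedge.begin(), pedge.end(), -1);
    typedef std::pair<double,int> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    dist[r] = 0; pq.push({0, r});
    while (!pq.empty()) {
      QE t = pq.top(); pq.pop();
      int u = t.second;
      if (t.first > dist[u]) continue;
      for (auto& pr : adj[u]) {
        double nd = dist[u] + weights[pr.second];
        int v = pr.first;
        if (nd < dist[v] - 1e-12) {
          dist[v] = nd; pedge[v] = pr.second; pq.push({nd, v});
        }
      }
    }
    for (int e = 0; e < m; e++) {
      int u = edges(e, 0), v = edges(e, 1);
      if (u == v) continue;
      if (!R_FINITE(dist[u]) || !R_FINITE(dist[v])) continue;
      if (pedge[u] == e || pedge[v] == e) continue; // tree edge: no cycle
      // XOR of the two tree paths plus e
      Cand c;
      c.bits.assign(W, 0);
      flip_bit(c.bits, e);
      int steps = 0;
      for (int x : {u, v}) {
        int cur = x;
        while (pedge[cur] >= 0) {
          int pe = pedge[cur];
          flip_bit(c.bits, pe);
          cur = (edges(pe, 0) == cur) ? edges(pe, 1) : edges(pe, 0);
          if (++steps > 2 * nv) break;
        }
      }
      // count bits, weight; require edge-disjoint paths (popcount matches)
      int nb = 0; double w = 0;
      for (int b = 0; b < m; b++) if (get_bit(c.bits, b)) { nb++; w += weights[b]; }
      // path edge counts
      int lu = 0, lv = 0;
      int cur = u; while (pedge[cur] >= 0) { lu++; cur = (edges(pedge[cur],0)==cur)?edges(pedge[cur],1):edges(pedge[cur],0); }
      cur = v; while (pedge[cur] >= 0) { lv++; cur = (edges(pedge[cur],0)==cur)?edges(pedge[cur],1):edges(pedge[cur],0); }
      if (nb != lu + lv + 1) continue; // overlapping paths: not a Horton candidate
      c.nbits = nb;
      c.w = w;
      cands.push_back(std::move(c));
    }
  }

  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.w != b.w) return a.w < b.w;
    return bits_less(a.bits, b.bits);
  });
  // deduplicate
  cands.erase(std::unique(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    return a.bits == b.bits;
  }), cands.end());

  // greedy GF(2) independence
  std::vector<std::vector<uint64_t>> pivots;   // reduced rows
  std::vector<int> pivot_bit;
  List out_cycles(cyc);
  NumericVector out_w(cyc);
  int found = 0;
  for (size_t ci = 0; ci < cands.size() && found < cyc; ci++) {
    std::vector<uint64_t> row = cands[ci].bits;
    for (size_t pi = 0; pi < pivots.size(); pi++) {
      if (get_bit(row, pivot_bit[pi]))
        for (int wq = 0; wq < W; wq++) row[wq] ^= pivots[pi][wq];
    }
    int pb = -1;
    for (int b = 0; b < m; b++) if (get_bit(row, b)) { pb = b; break; }
    if (pb < 0) continue; // dependent
    pivots.push_back(row);
    pivot_bit.push_back(pb);
    IntegerVector eidx;
    for (int b = 0; b < m; b++) if (get_bit(cands[ci].bits, b)) eidx.push_back(b + 1);
    out_cycles[found] = eidx;
    out_w[found] = cands[ci].w;
    found++;
  }
  if (found < cyc) stop("minimum cycle basis: candidate set incomplete (found %d of %d)", found, cyc);
  return List::create(_["cycles"] = out_cycles, _["weights"] = out_w);
}
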