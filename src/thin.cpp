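#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3D topology-preserving curve thinning by sequential deletion of simple
// points. A voxel is simple (its deletion preserves the topology of both
// foreground and background) iff, in its 3x3x3 neighbourhood,
//   (a) the foreground 26-neighbours form exactly one 26-connected
//       component, and
//   (b) the background voxels of the 18-neighbourhood form exactly one
//       6-connected component that is 6-adjacent to the centre
// (Bertrand & Malandain characterization). Curve endpoints (exactly one
// foreground 26-neighbour) are protected so centerlines of tubes survive.
// Deletion proceeds in six directional subiterations with re-checking at
// deletion time, so the result is deterministic and every removal is of a
// voxel that is simple in the current image.

// neighbourhood positions: p = di+1 + 3*(dj+1) + 9*(dk+1), centre p=13.

static int nb_offsets_built = 0;
static int adj26[27][27]; // adjacency between neighbourhood positions (26-conn)
static int adj6[27][27];  // 6-adjacency between positions
static int in18[27];      // membership of 18-neighbourhood (incl. face nbrs), centre excluded
static int face6[27];     // is a face (6-) neighbour of the centre

static void build_tables() {
  if (nb_offsets_built) return;
  for (int p = 0; p < 27; p++) {
    int di = p % 3 - 1, dj = (p / 3) % 3 - 1, dk = p / 9 - 1;
    int nz = (di != 0) + (dj != 0) + (dk != 0);
    in18[p] = (p != 13) && (nz <= 2);
    face6[p] = (nz == 1);
    for (int q = 0; q < 27; q++) {
      int ei = q % 3 - 1, ej = (q / 3) % 3 - 1, ek = q / 9 - 1;
      int ai = std::abs(di - ei), aj = std::abs(dj - ej), ak = std::abs(dk - ek);
      int s = ai + aj + ak;
      adj26[p][q] = (p != q) && ai <= 1 && aj <= 1 && ak <= 1;
      adj6[p][q] = (s == 1);
    }
  }
  nb_offsets_built = 1;
}

// nb[27]: 0/1 foreground flags, centre at 13 (assumed foreground).
static bool is_simple(const int* nb) {
  // (a) one 26-component of foreground neighbours
  int seen[27]; std::memset(seen, 0, sizeof(seen));
  int stack[27], top;
  int ncomp = 0, nfg = 0;
  for (int p = 0; p < 27; p++) if (p != 13 && nb[p]) nfg++;
  if (nfg == 0) return false; // isolated: deletion removes a component
  for (int p = 0; p < 27; p++) {
    if (p == 13 || !nb[p] || seen[p]) continue;
    ncomp++;
    if (ncomp > 1) return false;
    top = 0; stack[top++] = p; seen[p] = 1;
    while (top) {
      int c = stack[--top];
      for (int q = 0; q < 27; q++) {
        if (q == 13 || seen[q] || !nb[q]) continue;
        if (adj26[c][q]) { seen[q] = 1; stack[top++] = q; }
      }
    }
  }
  if (ncomp != 1) return false;
  // (b) one 6-component of background within the 18-neighbourhood,
  // 6-adjacent to the centre
  std::memset(seen, 0, sizeof(seen));
  int nbgcomp = 0;
  for (int p = 0; p < 27; p++) {
    if (!in18[p] || nb[p] || seen[p] || !face6[p]) continue;
    // start flood fills only from face neighbours (components must touch one)
    nbgcomp++;
    if (nbgcomp > 1) return false;
    top = 0; stack[top++] = p; seen[p] = 1;
    while (top) {
      int c = stack[--top];
      for (int q = 0; q < 27; q++) {
        if (!in18[q] || nb[q] || seen[q]) continue;
        if (adj6[c][q]) { seen[q] = 1; stack[top++] = q; }
      }
    }
    // absorb face neighbours already seen
    for (int q = 0; q < 27; q++) {
      if (face6[q] && !nb[q] && !seen[q]) {
        // another face-adjacent background voxel not reached: will start a
        // new component on a later p
        ;
      }
    }
  }
  return nbgcomp == 1;
}

struct Vol {
  int n1, n2, n3;
  std::vector<int> d;
  inline int at(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) return 0;
    return d[(size_t)i + (size_t)n1 * (j + (size_t)n2 * k)];
  }
};

static void fill_nb(const Vol& V, int i, int j, int k, int* nb) {
  int p = 0;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++, p++)
        nb[p] = V.at(i + di, j + dj, k + dk);
}

static int count_fg_nb(const int* nb) {
  int c = 0;
  for (int p = 0; p < 27; p++) if (p != 13 && nb[p]) c++;
  return c;
}

// [[Rcpp::export(name = ".thin_cpp")]]
LogicalVector thin_cpp(LogicalVector mask, IntegerVector dim) {
  build_tables();
  Vol V;
  V.n1 = dim[0]; V.n2 = dim[1]; V.n3 = dim[2];
  size_t ntot = (size_t)V.n1 * V.n2 * V.n3;
  V.d.resize(ntot);
  for (size_t i = 0; i < ntot; i++) V.d[i] = mask[i] ? 1 : 0;

  // directional offsets: U, D, N, S, E, W (fixed order)
  const int dirs[6][3] = {
    {0, 0, -1}, {0, 0, 1}, {0, -1, 0}, {0, 1, 0}, {-1, 0, 0}, {1, 0, 0}
  };

  int nb[27];
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      const int di = dirs[d][0], dj = dirs[d][1], dk = dirs[d][2];
      for (int k = 0; k < V.n3; k++)
        for (int j = 0; j < V.n2; j++)
          for (int i = 0; i < V.n1; i++) {
            size_t idx = (size_t)i + (size_t)V.n1 * (j + (size_t)V.n2 * k);
            if (!V.d[idx]) continue;
            if (V.at(i + di, j + dj, k + dk)) continue; // not a border voxel
            fill_nb(V, i, j, k, nb);
            if (count_fg_nb(nb) == 1) continue; // endpoint: keep
            if (is_simple(nb)) cand.push_back(idx);
          }
      // sequential deletion with re-check (linear-index order)
      for (size_t c = 0; c < cand.size(); c++) {
        size_t idx = cand[c];
        int i = (int)(idx % V.n1);
        int j = (int)((idx / V.n1) % V.n2);
        int k = (int)(idx / ((size_t)V.n1 * V.n2));
        fill_nb(V, i, j, k, nb);
        if (count_fg_nb(nb) == 1) continue;
        if (is_simple(nb)) {
          V.d[idx] = 0;
          changed = true;
        }
      }
    }
  }

  LogicalVector out(ntot);
  for (size_t i = 0; i < ntot; i++) out[i] = V.d[i] != 0;
  return out;
}
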