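#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <map>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// 0-dimensional persistence of the sublevel-set filtration of a 1-D series.
// Elder rule with ties broken by index (earlier index = older component).
// Returns finite pairs (birth, death) with death > birth strictly, plus the
// birth of the single essential class (the global minimum).
// ---------------------------------------------------------------------------

namespace {

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n, -1) {}
  int find(int i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    while (parent[i] != r) { int nxt = parent[i]; parent[i] = r; i = nxt; }
    return r;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_sublevel_pairs(NumericVector x) {
  const int n = x.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return a < b;
  });
  // processing rank of each index: smaller rank = older
  std::vector<int> rank_of(n);
  for (int r = 0; r < n; ++r) rank_of[ord[r]] = r;

  UnionFind uf(n);
  // birth index of the component root
  std::vector<int> birth_idx(n, -1);
  std::vector<double> births, deaths;

  for (int r = 0; r < n; ++r) {
    int i = ord[r];
    uf.parent[i] = i;
    birth_idx[i] = i;
    for (int step = -1; step <= 1; step += 2) {
      int j = i + step;
      if (j < 0 || j >= n) continue;
      if (uf.parent[j] == -1) continue; // neighbour not yet in the filtration
      int ri = uf.find(i), rj = uf.find(j);
      if (ri == rj) continue;
      // older component = the one whose birth was processed earlier
      int bi = birth_idx[ri], bj = birth_idx[rj];
      int old_root, young_root;
      if (rank_of[bi] < rank_of[bj]) { old_root = ri; young_root = rj; }
      else                           { old_root = rj; young_root = ri; }
      double b = x[birth_idx[young_root]];
      double d = x[i];
      if (d > b) { births.push_back(b); deaths.push_back(d); }
      uf.parent[young_root] = old_root;
      birth_idx[old_root] = (rank_of[bi] < rank_of[bj]) ? bi : bj;
    }
  }
  double essential = n > 0 ? x[ord[0]] : NA_REAL;
  return List::create(_["birth"] = births, _["death"] = deaths,
                      _["essential_birth"] = essential);
}

// ---------------------------------------------------------------------------
// Vietoris-Rips persistence up to dimension 1 for a Euclidean point cloud.
// Edges enter at their length, triangles at their longest edge. Dimension 0
// via union-find over sorted edges (all points born at 0); dimension 1 via
// standard boundary-matrix reduction over GF(2) with triangle columns
// indexed by edges in filtration order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_rips_pairs(NumericMatrix pts) {
  const int n = pts.nrow(), d = pts.ncol();
  if (n < 2) stop("Rips filtration needs at least 2 points");

  // pairwise distances
  std::vector<double> dist((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = pts(i, k) - pts(j, k);
        s += diff * diff;
      }
      double dd = std::sqrt(s);
      dist[(size_t)i * n + j] = dd;
      dist[(size_t)j * n + i] = dd;
    }

  struct Edge { double len; int i, j; };
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      edges.push_back({dist[(size_t)i * n + j], i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.len != b.len) return a.len < b.len;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int ne = (int)edges.size();
  // filtration index of edge (i,j)
  std::vector<int> edge_rank((size_t)n * n, -1);
  for (int e = 0; e < ne; ++e) {
    edge_rank[(size_t)edges[e].i * n + edges[e].j] = e;
    edge_rank[(size_t)edges[e].j * n + edges[e].i] = e;
  }

  // dimension 0: union-find over sorted edges
  UnionFind uf(n);
  for (int i = 0; i < n; ++i) uf.parent[i] = i;
  std::vector<double> d0_birth, d0_death;
  for (int e = 0; e < ne; ++e) {
    int ri = uf.find(edges[e].i), rj = uf.find(edges[e].j);
    if (ri != rj) {
      uf.parent[rj] = ri;
      if (edges[e].len > 0.0) { d0_birth.push_back(0.0); d0_death.push_back(edges[e].len); }
    }
  }

  // dimension 1: boundary-matrix reduction over GF(2), triangle columns as
  // bitsets indexed by edge filtration order
  struct Tri { double diam; int e1, e2, e3; }; // edge filtration indices
  std::vector<Tri> tris;
  tris.reserve((size_t)n * (n - 1) * (n - 2) / 6);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      for (int k = j + 1; k < n; ++k) {
        int e1 = edge_rank[(size_t)i * n + j];
        int e2 = edge_rank[(size_t)i * n + k];
        int e3 = edge_rank[(size_t)j * n + k];
        int m = std::max(e1, std::max(e2, e3));
        tris.push_back({edges[m].len, e1, e2, e3});
      }
  std::sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
    if (a.diam != b.diam) return a.diam < b.diam;
    int ma = std::max(a.e1, std::max(a.e2, a.e3));
    int mb = std::max(b.e1, std::max(b.e2, b.e3));
    if (ma != mb) return ma < mb;
    return std::make_pair(a.e1, a.e2) < std::make_pair(b.e1, b.e2);
  });

  std::vector<double> d1_birth, d1_death;
  const int nw = (ne + 63) / 64;
  std::vector<std::vector<uint64_t>> pivot_col(ne);
  std::vector<signed char> has_pivot(ne, 0);
  std::vector<uint64_t> col(nw);

  auto set_bit = [&](int e) { col[e >> 6] ^= (uint64_t)1 << (e & 63); };
  auto low_bit = [&]() -> int {
    for (int w = nw - 1; w >= 0; --w)
      if (col[w]) return (w << 6) + 63 - __builtin_clzll(col[w]);
    return -1;
  };

  for (size_t t = 0; t < tris.size(); ++t) {
    std::fill(col.begin(), col.end(), 0);
    set_bit(tris[t].e1);
    set_bit(tris[t].e2);
    set_bit(tris[t].e3);
    int low = low_bit();
    while (low >= 0 && has_pivot[low]) {
      const std::vector<uint64_t>& other = pivot_col[low];
      for (int w = 0; w < nw; ++w) col[w] ^= other[w];
      low = low_bit();
    }
    if (low >= 0) {
      has_pivot[low] = 1;
      pivot_col[low] = col;
      double b = edges[low].len, dd = tris[t].diam;
      if (dd > b) { d1_birth.push_back(b); d1_death.push_back(dd); }
    }
  }

  return List::create(
    _["d0_birth"] = d0_birth, _["d0_death"] = d0_death,
    _["d1_birth"] = d1_birth, _["d1_death"] = d1_death);
}

// ---------------------------------------------------------------------------
// Chirp-median phase summarisation: for each (frame, bin), wrap-align the
// per-chirp phase angles to the first chirp's phase (shift by multiples of
// 2*pi so all lie within +/- pi of it) and take the ordinary median.
// samples is a complex array with dim = c(frames, chirps, bins).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_chirp_median_phase(ComplexVector samples, IntegerVector dims) {
  const int nf = dims[0], nc = dims[1], nb = dims[2];
  NumericMatrix out(nf, nb);
  const double TWO_PI = 2.0 * M_PI;
  std::vector<double> ph(nc);
  for (int b = 0; b < nb; ++b) {
    for (int f = 0; f < nf; ++f) {
      for (int c = 0; c < nc; ++c) {
        Rcomplex z = samples[f + (size_t)nf * c + (size_t)nf * nc * b];
        ph[c] = std::atan2(z.i, z.r);
      }
      double ref = ph[0];
      for (int c = 1; c < nc; ++c) {
        double delta = ph[c] - ref;
        delta -= TWO_PI * std::round(delta / TWO_PI);
        ph[c] = ref + delta;
      }
      std::sort(ph.begin(), ph.end());
      double med = (nc % 2 == 1) ? ph[nc / 2]
                                 : 0.5 * (ph[nc / 2 - 1] + ph[nc / 2]);
      out(f, b) = med;
    }
  }
  return out;
}
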