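#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Vietoris-Rips persistence in dimensions 0 and 1 from a distance matrix.
//
// Filtration value of a simplex = its longest pairwise distance (diameter).
// Ties are broken by lexicographic vertex order, so the filtration is a
// total order and results are deterministic under point permutation up to
// diagram equality.
//
// H0: Kruskal union-find over distance-sorted pairs. Every merge edge with
// weight w <= maxEps yields a bar (0, w); each component still alive at
// maxEps yields a capped bar (0, maxEps), so an n-point cloud always has
// exactly n bars.
//
// H1: standard persistence reduction of the triangle boundary matrix over
// GF(2), columns processed in filtration order, pivots indexed by edge
// filtration position. Only edges that close a cycle (union-find says both
// endpoints already connected) can give birth to a loop; reduction on
// triangle columns alone is the clearing-optimised form of the full
// reduction. Zero-persistence bars are discarded; loops still open at
// maxEps are capped there.

namespace {

struct Edge {
  double w;
  int i, j;     // i < j
  bool operator<(const Edge& o) const {
    if (w != o.w) return w < o.w;
    if (i != o.i) return i < o.i;
    return j < o.j;
  }
};

struct Tri {
  double w;
  int i, j, k;  // i < j < k
  bool operator<(const Tri& o) const {
    if (w != o.w) return w < o.w;
    if (i != o.i) return i < o.i;
    if (j != o.j) return j < o.j;
    return k < o.k;
  }
};

class UnionFind {
  std::vector<int> parent, rank_;
public:
  explicit UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int v = 0; v < n; ++v) parent[v] = v;
  }
  int find(int v) {
    while (parent[v] != v) { parent[v] = parent[parent[v]]; v = parent[v]; }
    return v;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};

// dense GF(2) working column over edge ranks, with fast low-bit queries
class BitColumn {
  std::vector<uint64_t> w;
public:
  explicit BitColumn(int nbits) : w((nbits + 63) / 64, 0) {}
  void reset() { std::fill(w.begin(), w.end(), 0); }
  void flip(int i) { w[i >> 6] ^= (uint64_t{1} << (i & 63)); }
  // xor a sparse sorted column in
  void xorSparse(const std::vector<int>& col) {
    for (int i : col) flip(i);
  }
  // highest set bit at or below `from`; -1 if none
  int lowBelow(int from) const {
    int wi = from >> 6;
    uint64_t mask = (from & 63) == 63 ? ~uint64_t{0}
                    : ((uint64_t{1} << ((from & 63) + 1)) - 1);
    for (; wi >= 0; --wi) {
      uint64_t v = w[wi] & mask;
      if (v) return (wi << 6) + 63 - __builtin_clzll(v);
      mask = ~uint64_t{0};
    }
    return -1;
  }
  std::vector<int> toSparse(int low) const {
    std::vector<int> out;
    for (int wi = 0; wi <= (low >> 6); ++wi) {
      uint64_t v = w[wi];
      while (v) {
        int b = __builtin_ctzll(v);
        out.push_back((wi << 6) + b);
        v &= v - 1;
      }
    }
    return out;
  }
};

} // namespace

// [[Rcpp::export(name = ".ripsPersistenceCpp")]]
List ripsPersistenceCpp(NumericMatrix dmat, double maxEps, int maxDim) {
  const int n = dmat.nrow();
  if (n < 1) stop("empty point cloud");

  // --- edges within the cap, sorted by (diameter, lex) ---
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = dmat(i, j);
      if (w <= maxEps) edges.push_back(Edge{w, i, j});
    }
  std::sort(edges.begin(), edges.end());
  const int nE = (int)edges.size();

  // --- H0 by union-find; also mark positive (cycle-closing) edges ---
  UnionFind uf(n);
  std::vector<double> h0death;
  h0death.reserve(n);
  std::vector<char> positive(nE, 0);
  for (int e = 0; e < nE; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) h0death.push_back(edges[e].w);
    else positive[e] = 1;
  }
  int alive = n - (int)h0death.size();  // components uncapped at maxEps
  NumericMatrix h0((int)h0death.size() + alive, 2);
  for (size_t b = 0; b < h0death.size(); ++b) { h0(b, 0) = 0.0; h0(b, 1) = h0death[b]; }
  for (int b = 0; b < alive; ++b) {
    h0((int)h0death.size() + b, 0) = 0.0;
    h0((int)h0death.size() + b, 1) = maxEps;
  }

  if (maxDim < 1 || n < 3) {
    return List::create(_["h0"] = h0, _["h1"] = NumericMatrix(0, 2));
  }

  // --- edge rank lookup: position of (i,j) in filtration order ---
  // dense lookup table keyed by i*n+j (i<j); n is at most a few hundred here
  std::vector<int> erank((size_t)n * n, -1);
  for (int e = 0; e < nE; ++e)
    erank[(size_t)edges[e].i * n + edges[e].j] = e;

  // --- triangles within the cap, sorted by (diameter, lex) ---
  std::vector<Tri> tris;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = dmat(i, j);
      if (dij > maxEps) continue;
      for (int k = j + 1; k < n; ++k) {
        double dik = dmat(i, k), djk = dmat(j, k);
        if (dik > maxEps || djk > maxEps) continue;
        double w = std::max(dij, std::max(dik, djk));
        tris.push_back(Tri{w, i, j, k});
      }
    }
  std::sort(tris.begin(), tris.end());

  // --- reduce triangle columns; pivot = largest edge rank in the column ---
  std::vector<std::vector<int> > reduced(nE);      // stored column per pivot edge
  std::vector<double> pivotDeath(nE, -1.0);        // death value for pivot edge
  std::vector<char> hasPivot(nE, 0);

  BitColumn work(nE);
  std::vector<double> h1b, h1d;
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri& tr = tris[t];
    int e0 = erank[(size_t)tr.i * n + tr.j];
    int e1 = erank[(size_t)tr.i * n + tr.k];
    int e2 = erank[(size_t)tr.j * n + tr.k];
    int top = std::max(e0, std::max(e1, e2));
    // apparent-pair fast path: unclaimed pivot straight from the raw column
    if (!hasPivot[top]) {
      hasPivot[top] = 1;
      pivotDeath[top] = tr.w;
      std::vector<int> col{e0, e1, e2};
      std::sort(col.begin(), col.end());
      reduced[top].swap(col);
      continue;
    }
    work.reset();
    work.flip(e0); work.flip(e1); work.flip(e2);
    int low = top;
    while (low >= 0 && hasPivot[low]) {
      work.xorSparse(reduced[low]);
      low = work.lowBelow(low);
    }
    if (low >= 0) {
      hasPivot[low] = 1;
      pivotDeath[low] = tr.w;
      reduced[low] = work.toSparse(low);
    }
    // low < 0: column reduced to zero; nothing to store
  }

  for (int e = 0; e < nE; ++e) {
    if (!positive[e]) continue;
    double birth = edges[e].w;
    double death = hasPivot[e] ? pivotDeath[e] : maxEps;  // cap open loops
    if (death > birth) { h1b.push_back(birth); h1d.push_back(death); }
  }

  NumericMatrix h1((int)h1b.size(), 2);
  for (size_t b = 0; b < h1b.size(); ++b) { h1(b, 0) = h1b[b]; h1(b, 1) = h1d[b]; }
  return List::create(_["h0"] = h0, _["h1"] = h1);
}

// Fused pipeline step: Euclidean distance matrix from the cloud, optional
// maxmin landmark restriction (seeded start index supplied by the caller),
// enclosing-radius filtration cap, then Rips persistence.
// [[Rcpp::export(name = ".ripsCloudCpp")]]
List ripsCloudCpp(NumericMatrix cloud, int nLandmark, int start,
                  int maxDim) {
  const int n = cloud.nrow(), m = cloud.ncol();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < m; ++c) {
        double v = cloud(i, c) - cloud(j, c);
        s += v * v;
      }
      s = std::sqrt(s);
      d(i, j) = s; d(j, i) = s;
    }
  NumericMatrix dd = d;
  if (nLandmark > 0 && nLandmark < n) {
    std::vector<double> mind(n);
    std::vector<int> sel(nLandmark);
    int cur = start - 1;
    sel[0] = cur;
    for (int i = 0; i < n; ++i) mind[i] = d(i, cur);
    for (int s = 1; s < nLandmark; ++s) {
      int best = 0;
      for (int i = 1; i < n; ++i) if (mind[i] > mind[best]) best = i;
      cur = best;
      sel[s] = cur;
      for (int i = 0; i < n; ++i) mind[i] = std::min(mind[i], d(i, cur));
    }
    std::sort(sel.begin(), sel.end());
    NumericMatrix sub(nLandmark, nLandmark);
    for (int a = 0; a < nLandmark; ++a)
      for (int b = 0; b < nLandmark; ++b) sub(a, b) = d(sel[a], sel[b]);
    dd = sub;
  }
  // enclosing radius: past it the complex cones off and H1 is settled
  double maxEps = R_PosInf;
  for (int i = 0; i < dd.nrow(); ++i) {
    double mx = 0;
    for (int j = 0; j < dd.nrow(); ++j) mx = std::max(mx, dd(i, j));
    maxEps = std::min(maxEps, mx);
  }
  if (maxEps <= 0) maxEps = 1e-12;
  List res = ripsPersistenceCpp(dd, maxEps, maxDim);
  res["maxEps"] = maxEps;
  return res;
}

// landscape layers: k-th largest tent values over a grid
// [[Rcpp::export(name = ".landscapeCpp")]]
NumericMatrix landscapeCpp(NumericMatrix pairs, NumericVector grid, int k) {
  const int np = pairs.nrow(), ng = grid.size();
  NumericMatrix out(k, ng);
  std::vector<double> vals;
  vals.reserve(np);
  for (int g = 0; g < ng; ++g) {
    vals.clear();
    double t = grid[g];
    for (int i = 0; i < np; ++i) {
      double v = std::min(t - pairs(i, 0), pairs(i, 1) - t);
      if (v > 0) vals.push_back(v);
    }
    int kk = std::min<int>(k, vals.size());
    std::partial_sort(vals.begin(), vals.begin() + kk, vals.end(),
                      std::greater<double>());
    for (int j = 0; j < kk; ++j) out(j, g) = vals[j];
  }
  return out;
}

// sample-entropy pair counts: number of template pairs (i < j) whose
// Chebyshev distance is < r at embedding length m (B) and m+1 (A)
// [[Rcpp::export(name = ".sampenCountsCpp")]]
NumericVector sampenCountsCpp(NumericVector z, int m, double r) {
  const int n = z.size();
  const int nt = n - m;  // templates comparable at both lengths
  double A = 0, B = 0;
  for (int i = 0; i < nt; ++i)
    for (int j = i + 1; j < nt; ++j) {
      double mx = 0;
      for (int k = 0; k < m; ++k)
        mx = std::max(mx, std::fabs(z[i + k] - z[j + k]));
      if (mx < r) {
        B += 1;
        if (std::max(mx, std::fabs(z[i + m] - z[j + m])) < r) A += 1;
      }
    }
  return NumericVector::create(A, B);
}

// maxmin (farthest-point) landmark selection on a distance matrix,
// starting from a given index; returns 1-based indices of the landmarks.
// [[Rcpp::export(name = ".maxminLandmarksCpp")]]
IntegerVector maxminLandmarksCpp(NumericMatrix dmat, int nMax, int start) {
  const int n = dmat.nrow();
  if (nMax >= n) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  std::vector<double> mind(n);
  IntegerVector sel(nMax);
  int cur = start - 1;
  sel[0] = cur + 1;
  for (int i = 0; i < n; ++i) mind[i] = dmat(i, cur);
  for (int s = 1; s < nMax; ++s) {
    int best = 0;
    for (int i = 1; i < n; ++i) if (mind[i] > mind[best]) best = i;
    cur = best;
    sel[s] = cur + 1;
    for (int i = 0; i < n; ++i) mind[i] = std::min(mind[i], dmat(i, cur));
  }
  return sel;
}
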