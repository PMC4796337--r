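// Fast kernels for binary haplotype network construction: latent-node
// discovery (Buneman/median vectors), Hamming distances and geodesic-link
// detection. State vectors are bit-packed, 64 characters per word.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

typedef std::vector<uint64_t> BitVec;

static std::string vec_key(const BitVec &v) {
  return std::string(reinterpret_cast<const char *>(v.data()),
                     v.size() * sizeof(uint64_t));
}

static std::vector<BitVec> pack_matrix(const IntegerMatrix &X, int &nsites) {
  int n = X.nrow(), m = X.ncol();
  nsites = m;
  int W = m == 0 ? 1 : (m + 63) / 64;
  std::vector<BitVec> out(n, BitVec(W, 0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (X(i, j)) out[i][j / 64] |= (uint64_t(1) << (j % 64));
  return out;
}

static IntegerMatrix unpack(const std::vector<BitVec> &v, int m) {
  int n = v.size();
  IntegerMatrix X(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      X(i, j) = (v[i][j / 64] >> (j % 64)) & 1 ? 1 : 0;
  return X;
}

static inline int hamming(const BitVec &a, const BitVec &b) {
  int d = 0;
  for (size_t w = 0; w < a.size(); ++w) {
#if defined(__GNUC__) || defined(__clang__)
    d += __builtin_popcountll(a[w] ^ b[w]);
#else
    uint64_t x = a[w] ^ b[w];
    while (x) { d += x & 1; x >>= 1; }
#endif
  }
  return d;
}

// Latent haplotype states consistent with the observed character data: the
// vectors x such that for every character pair (i, j) the combination
// (x_i, x_j) occurs in some observed haplotype (Buneman vectors; a
// superset of the median-network vectors, so every most-parsimonious
// Steiner point is included). Discovered by breadth-first single-character
// flips from the observed states. Returns the node matrix (observed
// states first), the 1-based row of each input vector in it, and the
// single-flip (Hamming distance 1) edge list.
// [[Rcpp::export]]
List buneman_graph_cpp(IntegerMatrix X, int max_nodes = 20000) {
  int m;
  std::vector<BitVec> input = pack_matrix(X, m);
  int W = input.empty() ? 1 : input[0].size();

  // valid[j] mask of real character columns
  BitVec valid(W, 0);
  for (int j = 0; j < m; ++j) valid[j / 64] |= (uint64_t(1) << (j % 64));

  // occ[i][a] = OR over observed rows with x_i == a of (row bits), and
  // occ0[i][a] likewise of complemented bits; a pair (a, b) at (i, j) is
  // observed iff bit j of (b ? occ1 : occ0)[i][a] is set
  std::vector<BitVec> occ1(2 * m, BitVec(W, 0)), occ0(2 * m, BitVec(W, 0));
  for (size_t r = 0; r < input.size(); ++r) {
    for (int i = 0; i < m; ++i) {
      int a = (input[r][i / 64] >> (i % 64)) & 1;
      for (int w = 0; w < W; ++w) {
        occ1[2 * i + a][w] |= input[r][w];
        occ0[2 * i + a][w] |= ~input[r][w] & valid[w];
      }
    }
  }
  // bad1[i][a]: j where (a, x_j = 1) never observed
  std::vector<BitVec> bad1(2 * m, BitVec(W, 0)), bad0(2 * m, BitVec(W, 0));
  for (int k = 0; k < 2 * m; ++k) {
    for (int w = 0; w < W; ++w) {
      bad1[k][w] = ~occ1[k][w] & valid[w];
      bad0[k][w] = ~occ0[k][w] & valid[w];
    }
  }

  std::vector<BitVec> nodes;
  std::unordered_map<std::string, int> index;
  IntegerVector input_index(input.size());
  for (size_t r = 0; r < input.size(); ++r) {
    std::string k = vec_key(input[r]);
    auto it = index.find(k);
    if (it == index.end()) {
      index[k] = nodes.size();
      nodes.push_back(input[r]);
      input_index[r] = nodes.size();
    } else {
      input_index[r] = it->second + 1;
    }
  }

  std::vector<int> efrom, eto;
  BitVec y(W);
  for (size_t cur = 0; cur < nodes.size(); ++cur) {
    BitVec x = nodes[cur];  // copy: nodes may reallocate
    for (int i = 0; i < m; ++i) {
      y = x;
      y[i / 64] ^= (uint64_t(1) << (i % 64));
      int a = (y[i / 64] >> (i % 64)) & 1;
      // consistent iff no character j conflicts with the flipped value
      uint64_t viol = 0;
      for (int w = 0; w < W && !viol; ++w) {
        viol = (bad1[2 * i + a][w] & y[w]) |
               (bad0[2 * i + a][w] & ~y[w] & valid[w]);
      }
      if (viol) continue;
      std::string k = vec_key(y);
      auto it = index.find(k);
      int tgt;
      if (it == index.end()) {
        tgt = nodes.size();
        index[k] = tgt;
        nodes.push_back(y);
        if ((int)nodes.size() > max_nodes)
          stop("latent-node search exceeded %d nodes; the character data "
               "are too conflicted for a haplotype network", max_nodes);
      } else {
        tgt = it->second;
      }
      if ((int)cur < tgt) { efrom.push_back(cur + 1); eto.push_back(tgt + 1); }
    }
  }
  IntegerMatrix E(efrom.size(), 2);
  for (size_t i = 0; i < efrom.size(); ++i) {
    E(i, 0) = efrom[i];
    E(i, 1) = eto[i];
  }
  return List::create(Named("nodes") = unpack(nodes, m),
                      Named("input_index") = input_index,
                      Named("flip_edges") = E);
}

// Pairwise Hamming distance matrix of binary row vectors.
// [[Rcpp::export]]
IntegerMatrix hamming_cpp(IntegerMatrix X) {
  int m;
  std::vector<BitVec> v = pack_matrix(X, m);
  int n = v.size();
  IntegerMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      D(i, j) = D(j, i) = hamming(v[i], v[j]);
  return D;
}

// Geodesic links of a finite metric: pairs (u,v) with no third point w
// strictly between them (d(u,w)+d(w,v) == d(u,v)). 1-based, u < v.
// [[Rcpp::export]]
IntegerMatrix geodesic_edges_cpp(IntegerMatrix D) {
  int n = D.nrow();
  std::vector<int> from, to;
  for (int u = 0; u < n; ++u) {
    for (int v = u + 1; v < n; ++v) {
      int duv = D(u, v);
      bool direct = true;
      for (int w = 0; w < n && direct; ++w) {
        if (w == u || w == v) continue;
        if (D(u, w) > 0 && D(w, v) > 0 && D(u, w) + D(w, v) == duv)
          direct = false;
      }
      if (direct) { from.push_back(u + 1); to.push_back(v + 1); }
    }
  }
  IntegerMatrix E(from.size(), 2);
  for (size_t i = 0; i < from.size(); ++i) {
    E(i, 0) = from[i];
    E(i, 1) = to[i];
  }
  return E;
}
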