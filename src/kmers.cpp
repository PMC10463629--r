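#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit DNA encoding; k is capped at 31 so a k-mer fits in 62 bits.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N or anything else breaks k-mer extraction
  }
}

static const char DECODE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t x, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3 - (x & 3));
    x >>= 2;
  }
  return rc;
}

// Append all valid k-mer codes of seq (one strand) to out.
static void collect_kmers(const char *seq, size_t n, int k,
                          std::vector<uint64_t> &out) {
  if ((int)n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0; // valid bases accumulated
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) out.push_back(cur);
  }
}

static inline bool in_set(const std::vector<uint64_t> &s, uint64_t x) {
  return std::binary_search(s.begin(), s.end(), x);
}

// Build the condensed, conjugate-closed de Bruijn graph from reads and
// return the unitig sequences (both orientations, lexicographically
// sorted).  Vertices and conjugate pairing are derived on the R side
// from the terminal (k-1)-mers of each unitig.
// [[Rcpp::export]]
CharacterVector cpp_build_unitigs(CharacterVector reads, int k) {
  if (k < 3 || k > 31) stop("k must be between 3 and 31");
  std::vector<uint64_t> kmers;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    size_t n = std::strlen(s);
    collect_kmers(s, n, k, kmers);
  }
  // conjugate closure: add reverse complements
  size_t n0 = kmers.size();
  kmers.reserve(2 * n0);
  for (size_t i = 0; i < n0; ++i) kmers.push_back(revcomp_code(kmers[i], k));
  std::sort(kmers.begin(), kmers.end());
  kmers.erase(std::unique(kmers.begin(), kmers.end()), kmers.end());
  if (kmers.empty()) return CharacterVector(0);

  const int km1 = k - 1;
  const uint64_t node_mask = (1ULL << (2 * km1)) - 1;

  // node degrees probed against the k-mer set
  auto out_deg = [&](uint64_t node) {
    int d = 0;
    for (uint64_t x = 0; x < 4; ++x)
      if (in_set(kmers, ((node << 2) | x) & ((node_mask << 2) | 3))) ++d;
    return d;
  };
  auto in_deg = [&](uint64_t node) {
    int d = 0;
    for (uint64_t x = 0; x < 4; ++x)
      if (in_set(kmers, node | (x << (2 * km1)))) ++d;
    return d;
  };
  auto prefix_of = [&](uint64_t e) { return e >> 2; };
  auto suffix_of = [&](uint64_t e) { return e & node_mask; };
  auto sole_successor = [&](uint64_t node, uint64_t &succ) {
    int d = 0;
    for (uint64_t x = 0; x < 4; ++x) {
      uint64_t cand = (node << 2) | x;
      if (in_set(kmers, cand)) { ++d; succ = cand; }
    }
    return d == 1;
  };

  std::vector<bool> used(kmers.size(), false);
  std::vector<std::string> unitigs;

  auto decode_kmer = [&](uint64_t e) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) { s[i] = DECODE[e & 3]; e >>= 2; }
    return s;
  };

  auto walk_from = [&](size_t start_idx) {
    uint64_t e = kmers[start_idx];
    std::string u = decode_kmer(e);
    used[start_idx] = true;
    uint64_t cur = e;
    for (;;) {
      uint64_t v = suffix_of(cur);
      if (out_deg(v) != 1 || in_deg(v) != 1) break; // junction: stop
      uint64_t nxt;
      if (!sole_successor(v, nxt)) break;
      size_t idx = std::lower_bound(kmers.begin(), kmers.end(), nxt) -
                   kmers.begin();
      if (used[idx]) break; // closes a cycle (or rejoins): stop
      used[idx] = true;
      u.push_back(DECODE[nxt & 3]);
      cur = nxt;
    }
    unitigs.push_back(u);
  };

  // pass 1: unitigs starting at branch nodes (deterministic sorted order)
  for (size_t i = 0; i < kmers.size(); ++i) {
    if (used[i]) continue;
    uint64_t u = prefix_of(kmers[i]);
    if (out_deg(u) != 1 || in_deg(u) != 1) walk_from(i);
  }
  // pass 2: leftover pure cycles; smallest unvisited k-mer anchors each
  for (size_t i = 0; i < kmers.size(); ++i)
    if (!used[i]) walk_from(i);

  std::sort(unitigs.begin(), unitigs.end());
  CharacterVector out(unitigs.size());
  for (size_t i = 0; i < unitigs.size(); ++i) out[i] = unitigs[i];
  return out;
}

// Anchor every k-mer of every read in the unitig index.  Returns the
// per-read edge walks (first-occurrence order of distinct unitigs, 5'
// to 3') in a flattened form: $lengths[i] edges for read i, edge ids
// (1-based indices into `unitigs`) concatenated in $edges.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector unitigs, CharacterVector reads, int k) {
  if (k < 3 || k > 31) stop("k must be between 3 and 31");
  // index: sorted (kmer code, edge) pairs; ambiguous k-mers (repeats)
  // resolve to the lexicographically smallest unitig.
  std::vector<std::pair<uint64_t, int> > index;
  for (R_xlen_t e = 0; e < unitigs.size(); ++e) {
    const char *s = CHAR(STRING_ELT(unitigs, e));
    std::vector<uint64_t> ks;
    collect_kmers(s, std::strlen(s), k, ks);
    for (size_t i = 0; i < ks.size(); ++i)
      index.push_back(std::make_pair(ks[i], (int)e + 1));
  }
  std::sort(index.begin(), index.end());

  auto lookup = [&](uint64_t km) {
    std::pair<uint64_t, int> key(km, 0);
    auto it = std::lower_bound(index.begin(), index.end(), key);
    if (it != index.end() && it->first == km) return it->second;
    return 0;
  };

  R_xlen_t n = reads.size();
  IntegerVector lengths(n);
  std::vector<int> flat;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    size_t len = std::strlen(s);
    std::vector<uint64_t> ks;
    collect_kmers(s, len, k, ks);
    std::vector<int> path;
    for (size_t j = 0; j < ks.size(); ++j) {
      int e = lookup(ks[j]);
      if (e == 0) continue;
      if (std::find(path.begin(), path.end(), e) == path.end())
        path.push_back(e);
    }
    lengths[i] = (int)path.size();
    flat.insert(flat.end(), path.begin(), path.end());
  }
  IntegerVector edges(flat.begin(), flat.end());
  return List::create(_["lengths"] = lengths, _["edges"] = edges);
}

// Reverse complement (used for conjugate lookups on long unitigs).
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) {
      switch (r[j]) {
      case 'A': r[j] = 'T'; break; case 'a': r[j] = 't'; break;
      case 'C': r[j] = 'G'; break; case 'c': r[j] = 'g'; break;
      case 'G': r[j] = 'C'; break; case 'g': r[j] = 'c'; break;
      case 'T': r[j] = 'A'; break; case 't': r[j] = 'a'; break;
      default: break;
      }
    }
    out[i] = r;
  }
  return out;
}

#include <queue>

// Distance-bounded Dijkstra over a CSR adjacency (ptr is 0-based
// cumulative degree per vertex; head/w give the neighbor and novel
// length of each outgoing arc).  Returns every vertex with shortest
// distance <= d from the 1-based source.
// [[Rcpp::export]]
List cpp_bounded_dijkstra(IntegerVector ptr, IntegerVector head,
                          NumericVector w, int source, double d) {
  int n = ptr.size() - 1;
  if (source < 1 || source > n) stop("unknown source vertex");
  std::vector<double> dist(n + 1, R_PosInf);
  typedef std::pair<double, int> Item; // (distance, vertex); vertex id
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  dist[source] = 0.0;
  pq.push(Item(0.0, source));
  while (!pq.empty()) {
    Item it = pq.top(); pq.pop();
    double du = it.first; int u = it.second;
    if (du > dist[u]) continue; // stale entry
    for (int j = ptr[u - 1]; j < ptr[u]; ++j) {
      int v = head[j];
      double nd = du + w[j];
      if (nd <= d && nd < dist[v]) {
        dist[v] = nd;
        pq.push(Item(nd, v));
      }
    }
  }
  std::vector<int> vs;
  std::vector<double> ds;
  for (int v = 1; v <= n; ++v) {
    if (dist[v] <= d) { vs.push_back(v); ds.push_back(dist[v]); }
  }
  return List::create(_["vertex"] = IntegerVector(vs.begin(), vs.end()),
                      _["distance"] = NumericVector(ds.begin(), ds.end()));
}
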