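#ifndef RADBUBBLES_H
#define RADBUBBLES_H

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>

// 2-bit packed k-mer, first base in the most significant position so that
// numeric order on equal-length k-mers equals lexicographic order.
typedef unsigned __int128 kmer_t;

static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline kmer_t kmask(int k) {
  return (((kmer_t)1 << (2 * k)) - 1);
}

static inline kmer_t ext_fwd(kmer_t f, int c, kmer_t mask) {
  return ((f << 2) | (kmer_t)c) & mask;
}

static inline kmer_t ext_rc(kmer_t r, int c, int k) {
  return (r >> 2) | ((kmer_t)(3 - c) << (2 * (k - 1)));
}

struct KmerHash {
  size_t operator()(kmer_t x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo ^ (hi * 0x9E3779B97F4A7C15ULL);
    h ^= h >> 30; h *= 0xBF58476D1CE4E5B9ULL;
    h ^= h >> 27; h *= 0x94D049BB133111EBULL;
    h ^= h >> 31;
    return (size_t)h;
  }
};

struct KCount {
  uint32_t total = 0;  // occurrences across all samples
  uint32_t best = 0;   // highest within-sample count seen so far
  uint32_t cur = 0;    // count within the sample currently being read
  int32_t last = -1;   // id of that sample
};

struct KmerGraph {
  int k = 0;
  int min_abundance = 1;
  bool finalized = false;
  long long total_occ = 0;  // valid k-mer occurrences, pre-threshold
  kmer_t mask = 0;
  std::unordered_map<kmer_t, KCount, KmerHash> counts;
};

// an oriented graph node: forward encoding and its reverse complement
struct Node {
  kmer_t f, r;
};

static inline Node node_step(const Node& n, int c, const KmerGraph& g) {
  return Node{ext_fwd(n.f, c, g.mask), ext_rc(n.r, c, g.k)};
}

static inline Node node_rc(const Node& n) { return Node{n.r, n.f}; }

std::string rb_decode(kmer_t f, int k);
kmer_t rb_revcomp(kmer_t f, int k);
bool rb_encode(const char* s, int k, kmer_t& f);
std::string rb_revcomp_str(const std::string& s);
int rb_succ_chars(const KmerGraph& g, const Node& n, int out[4]);

#endif
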