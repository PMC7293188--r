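// de Bruijn graph core: canonical k-mer counting with per-sample solidity,
// oriented successor queries. k is odd and <= 63, so a k-mer fits in 128 bits
// and is never its own reverse complement.

#include "radbubbles.h"

// ---- encoding helpers (definitions for the inline-extern bits live in the header) ----

std::string rb_decode(kmer_t f, int k) {
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = CODE2BASE[(int)(f & 3)];
    f >>= 2;
  }
  return s;
}

kmer_t rb_revcomp(kmer_t f, int k) {
  kmer_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (kmer_t)(3 - (int)(f & 3));
    f >>= 2;
  }
  return r;
}

bool rb_encode(const char* s, int k, kmer_t& f) {
  f = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    f = (f << 2) | (kmer_t)c;
  }
  return true;
}

std::string rb_revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& ch : r) {
    switch (ch) {
      case 'A': ch = 'T'; break;
      case 'C': ch = 'G'; break;
      case 'G': ch = 'C'; break;
      case 'T': ch = 'A'; break;
      default: break;
    }
  }
  return r;
}

int rb_succ_chars(const KmerGraph& g, const Node& n, int out[4]) {
  int m = 0;
  for (int c = 0; c < 4; ++c) {
    kmer_t f2 = ext_fwd(n.f, c, g.mask);
    kmer_t r2 = ext_rc(n.r, c, g.k);
    if (g.counts.count(f2 < r2 ? f2 : r2)) out[m++] = c;
  }
  return m;
}

// ---- R interface ----

// [[Rcpp::export]]
SEXP cpp_graph_new(int k) {
  KmerGraph* g = new KmerGraph();
  g->k = k;
  g->mask = kmask(k);
  Rcpp::XPtr<KmerGraph> p(g, true);
  return p;
}

// [[Rcpp::export]]
void cpp_graph_add_reads(SEXP ptr, Rcpp::CharacterVector reads, int sample) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  if (g->finalized) Rcpp::stop("graph is already finalized");
  const int k = g->k;
  const kmer_t mask = g->mask;
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    const char* s = CHAR(STRING_ELT(reads, ri));
    kmer_t f = 0, r = 0;
    int len = 0;
    for (const char* p = s; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { len = 0; f = 0; r = 0; continue; }  // non-ACGT breaks the window
      f = ((f << 2) | (kmer_t)c) & mask;
      r = (r >> 2) | ((kmer_t)(3 - c) << (2 * (k - 1)));
      if (++len >= k) {
        KCount& kc = g->counts[f < r ? f : r];
        if (kc.last != sample) {
          if (kc.cur > kc.best) kc.best = kc.cur;
          kc.cur = 0;
          kc.last = sample;
        }
        kc.cur++;
        kc.total++;
        g->total_occ++;
      }
    }
  }
}

// Solidity: a k-mer is kept iff its count reaches min_abundance within at
// least one sample (for a single sample this equals thresholding the total).
// [[Rcpp::export]]
void cpp_graph_finalize(SEXP ptr, int min_abundance) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  if (g->finalized) Rcpp::stop("graph is already finalized");
  std::unordered_map<kmer_t, KCount, KmerHash> solid;
  for (auto& kv : g->counts) {
    KCount kc = kv.second;
    if (kc.cur > kc.best) kc.best = kc.cur;
    kc.cur = 0;
    if ((int)kc.best >= min_abundance) solid.emplace(kv.first, kc);
  }
  g->counts.swap(solid);
  g->min_abundance = min_abundance;
  g->finalized = true;
}

// [[Rcpp::export]]
double cpp_graph_size(SEXP ptr) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  return (double)g->counts.size();
}

// [[Rcpp::export]]
double cpp_graph_total_occurrences(SEXP ptr) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  return (double)g->total_occ;
}

static kmer_t canon_from_string(const KmerGraph& g, const char* s) {
  kmer_t f;
  if (!rb_encode(s, g.k, f)) return ~(kmer_t)0;  // sentinel: never canonical (top bits set)
  kmer_t r = rb_revcomp(f, g.k);
  return f < r ? f : r;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_graph_count(SEXP ptr, Rcpp::CharacterVector kmers) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  Rcpp::IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)strlen(s) != g->k) Rcpp::stop("k-mer query must have length k = %d", g->k);
    kmer_t c = canon_from_string(*g, s);
    auto it = g->counts.find(c);
    out[i] = (it == g->counts.end()) ? 0 : (int)it->second.total;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_graph_kmers(SEXP ptr) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  std::vector<kmer_t> ks;
  ks.reserve(g->counts.size());
  for (auto& kv : g->counts) ks.push_back(kv.first);
  std::sort(ks.begin(), ks.end());
  Rcpp::CharacterVector out(ks.size());
  for (size_t i = 0; i < ks.size(); ++i) out[i] = rb_decode(ks[i], g->k);
  return out;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_graph_kmer_totals(SEXP ptr) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  std::vector<kmer_t> ks;
  ks.reserve(g->counts.size());
  for (auto& kv : g->counts) ks.push_back(kv.first);
  std::sort(ks.begin(), ks.end());
  Rcpp::IntegerVector out(ks.size());
  for (size_t i = 0; i < ks.size(); ++i) out[i] = (int)g->counts.at(ks[i]).total;
  return out;
}

// Oriented successors of a k-mer: the extension bases alpha such that
// kmer[2:k] + alpha is in the graph (membership on canonical form).
// [[Rcpp::export]]
Rcpp::CharacterVector cpp_successors(SEXP ptr, std::string kmer) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  if ((int)kmer.size() != g->k) Rcpp::stop("k-mer query must have length k = %d", g->k);
  kmer_t f;
  if (!rb_encode(kmer.c_str(), g->k, f)) return Rcpp::CharacterVector(0);
  Node n{f, rb_revcomp(f, g->k)};
  int s[4];
  int m = rb_succ_chars(*g, n, s);
  Rcpp::CharacterVector out(m);
  for (int i = 0; i < m; ++i) out[i] = std::string(1, CODE2BASE[s[i]]);
  return out;
}

// [[Rcpp::export]]
bool cpp_is_branching(SEXP ptr, std::string kmer) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  if ((int)kmer.size() != g->k) Rcpp::stop("k-mer query must have length k = %d", g->k);
  kmer_t f;
  if (!rb_encode(kmer.c_str(), g->k, f)) return false;
  Node n{f, rb_revcomp(f, g->k)};
  int s[4];
  int ns = rb_succ_chars(*g, n, s);
  if (ns >= 2) return true;
  Node rc{n.r, n.f};
  int np = rb_succ_chars(*g, rc, s);
  return np >= 2;
}

// Canonical m-mers of arbitrary sequences (used for the shared (k-1)-mer
// locus clustering); one deduplicated character vector per input sequence.
// [[Rcpp::export]]
Rcpp::List cpp_canonical_kmers(Rcpp::CharacterVector seqs, int m) {
  kmer_t mask = kmask(m);
  Rcpp::List out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    std::unordered_set<kmer_t, KmerHash> seen;
    kmer_t f = 0, r = 0;
    int len = 0;
    for (const char* p = s; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { len = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (kmer_t)c) & mask;
      r = (r >> 2) | ((kmer_t)(3 - c) << (2 * (m - 1)));
      if (++len >= m) seen.insert(f < r ? f : r);
    }
    std::vector<kmer_t> v(seen.begin(), seen.end());
    std::sort(v.begin(), v.end());
    Rcpp::CharacterVector kv(v.size());
    for (size_t j = 0; j < v.size(); ++j) kv[j] = rb_decode(v[j], m);
    out[i] = kv;
  }
  return out;
}

// Substitution errors injected with R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
Rcpp::CharacterVector cpp_mutate_reads(Rcpp::CharacterVector reads, double error_rate) {
  Rcpp::RNGScope scope;
  Rcpp::CharacterVector out(reads.size());
  std::string buf;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    buf = CHAR(STRING_ELT(reads, i));
    for (auto& ch : buf) {
      if (unif_rand() < error_rate) {
        int c = base_code(ch);
        if (c < 0) continue;
        int alt = (int)(unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        ch = CODE2BASE[(c + 1 + alt) & 3];
      }
    }
    out[i] = buf;
  }
  return out;
}
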