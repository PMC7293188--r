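// Bubble detection: lockstep two-path traversal from each branching node,
// emitting complete bubbles (paths re-merge), symmetrically truncated bubbles
// (both paths dead-end at equal length with identical last 3-mer), close-SNP
// bubbles (several mismatches < k apart) and small indels (one path holds
// while the other consumes up to max_indel extra bases). Every crossroad
// offering more than one extension combination counts as one SBC traversal,
// capped at max_sbc per bubble (0 in high-precision mode).

#include "radbubbles.h"

enum Kind { SNP = 0, CLOSE_SNPS = 1, INDEL = 2 };
enum Closure { COMPLETE = 0, LEFT_TRUNCATED = 1, RIGHT_TRUNCATED = 2 };

struct BubbleOut {
  std::vector<std::string> pa, pb;
  std::vector<int> kind, closure, sbc;
  std::vector<std::vector<int>> offs;  // SNP kinds: 0-based mismatch offsets;
                                       // INDEL: {offset, length} on the longer path
  std::unordered_set<std::string> seen;
};

// leftmost equivalent placement of an inserted/deleted segment of length len
// currently at offset o within sequence s
static int left_align(const std::string& s, int o, int len) {
  while (o > 0 && s[(size_t)(o - 1)] == s[(size_t)(o + len - 1)]) --o;
  return o;
}

static void emit_bubble(BubbleOut& out, std::string p1, std::string p2,
                        std::vector<int> offs, int kind, int closure, int sbc) {
  // two orientations; each orders its paths lexicographically; keep the
  // orientation whose (path_a, path_b) tuple is smaller => strand-stable key
  std::string q1 = rb_revcomp_str(p1), q2 = rb_revcomp_str(p2);
  std::string a1 = std::min(p1, p2), b1 = std::max(p1, p2);
  std::string a2 = std::min(q1, q2), b2 = std::max(q1, q2);
  bool use_fwd = (a1 < a2) || (a1 == a2 && b1 <= b2);

  std::vector<int> o = offs;
  int clo = closure;
  if (!use_fwd) {
    if (kind == INDEL) {
      const std::string& lng = (q1.size() >= q2.size()) ? q1 : q2;
      int raw = (int)lng.size() - offs[0] - offs[1];
      o[0] = left_align(lng, raw, offs[1]);
      o[1] = offs[1];
    } else {
      int L = (int)p1.size();
      for (auto& x : o) x = L - 1 - x;
      std::sort(o.begin(), o.end());
    }
    if (closure == LEFT_TRUNCATED) clo = RIGHT_TRUNCATED;
    else if (closure == RIGHT_TRUNCATED) clo = LEFT_TRUNCATED;
  }
  const std::string& pa = use_fwd ? a1 : a2;
  const std::string& pb = use_fwd ? b1 : b2;
  std::string key = pa;
  key.push_back('\x01');
  key += pb;
  key.push_back((char)('0' + kind));
  if (!out.seen.insert(key).second) return;  // first discovery wins
  out.pa.push_back(pa);
  out.pb.push_back(pb);
  out.kind.push_back(kind);
  out.closure.push_back(clo);
  out.sbc.push_back(sbc);
  out.offs.push_back(std::move(o));
}

struct TravCfg {
  const KmerGraph* g;
  int max_snps, max_sbc, max_indel;
  bool high_precision;
  long work;
  long work_cap;
  BubbleOut* out;
};

static void snp_step(TravCfg& C, Node n1, Node n2, std::string& p1, std::string& p2,
                     std::vector<int>& mism, int sbc) {
  if (++C.work > C.work_cap) return;
  if (n1.f == n2.f) {  // paths re-merged: closing k-mer is the last k appended bases
    emit_bubble(*C.out, p1, p2, mism, mism.size() == 1 ? SNP : CLOSE_SNPS, COMPLETE, sbc);
    return;
  }
  int s1[4], s2[4];
  int m1 = rb_succ_chars(*C.g, n1, s1);
  int m2 = rb_succ_chars(*C.g, n2, s2);
  if (m1 == 0 && m2 == 0) {
    // symmetric truncation: equal length by construction; last 3-mer must match
    size_t L = p1.size();
    if (p1.compare(L - 3, 3, p2, L - 3, 3) == 0)
      emit_bubble(*C.out, p1, p2, mism, mism.size() == 1 ? SNP : CLOSE_SNPS,
                  RIGHT_TRUNCATED, sbc);
    return;
  }
  if (m1 == 0 || m2 == 0) return;  // asymmetric dead end: abandoned
  if (m1 * m2 >= 2) {              // a crossroad: all combinations explored
    ++sbc;
    if (sbc > (C.high_precision ? 0 : C.max_sbc)) return;
  }
  for (int i = 0; i < m1; ++i) {
    for (int j = 0; j < m2; ++j) {
      int a = s1[i], b = s2[j];
      bool mm = (a != b);
      if (mm && (int)mism.size() >= C.max_snps) continue;
      p1.push_back(CODE2BASE[a]);
      p2.push_back(CODE2BASE[b]);
      if (mm) mism.push_back((int)p1.size() - 1);
      snp_step(C, node_step(n1, a, *C.g), node_step(n2, b, *C.g), p1, p2, mism, sbc);
      if (mm) mism.pop_back();
      p1.pop_back();
      p2.pop_back();
    }
  }
}

// indel: long path has consumed `ins` extra bases (p_long); short path still
// sits at the opening node. Lockstep both with identical bases (b first on the
// short side); k-mer equality within k steps certifies the indel motif.
static void indel_lockstep(TravCfg& C, const Node& n_long, const std::string& p_long,
                           const Node& open, const std::string& p_open, int b, int ins) {
  const KmerGraph& g = *C.g;
  Node n1 = n_long, n2 = open;
  std::string q1 = p_long, q2 = p_open;
  for (int j = 1; j <= g.k; ++j) {
    int s1[4], s2[4];
    int m1 = rb_succ_chars(g, n1, s1);
    int m2 = rb_succ_chars(g, n2, s2);
    int c = -1;
    if (j == 1) {
      bool ok1 = false, ok2 = false;
      for (int i = 0; i < m1; ++i) ok1 |= (s1[i] == b);
      for (int i = 0; i < m2; ++i) ok2 |= (s2[i] == b);
      if (!ok1 || !ok2) return;
      c = b;
    } else {
      int common = -1, ncommon = 0;
      for (int i = 0; i < m1; ++i)
        for (int l = 0; l < m2; ++l)
          if (s1[i] == s2[l]) { common = s1[i]; ++ncommon; }
      if (ncommon != 1) return;  // ambiguous or impossible: abandoned
      c = common;
    }
    n1 = node_step(n1, c, g);
    n2 = node_step(n2, c, g);
    q1.push_back(CODE2BASE[c]);
    q2.push_back(CODE2BASE[c]);
    if (n1.f == n2.f) {
      int o = left_align(q1, g.k, ins);
      emit_bubble(*C.out, q1, q2, std::vector<int>{o, ins}, INDEL, COMPLETE, 0);
      return;
    }
  }
}

static void indel_explore(TravCfg& C, const Node& open, const std::string& open_str,
                          int a, int b) {
  const KmerGraph& g = *C.g;
  Node nl = node_step(open, a, g);
  std::string pl = open_str;
  pl.push_back(CODE2BASE[a]);
  for (int ins = 1; ins <= C.max_indel; ++ins) {
    indel_lockstep(C, nl, pl, open, open_str, b, ins);
    int s[4];
    int m = rb_succ_chars(g, nl, s);
    if (m != 1) break;  // only unambiguous held-branch extensions are followed
    pl.push_back(CODE2BASE[s[0]]);
    nl = node_step(nl, s[0], g);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_detect_bubbles(SEXP ptr, int max_snps, int max_sbc, int max_indel,
                              bool high_precision) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  BubbleOut out;
  TravCfg C{g.get(), max_snps, max_sbc, max_indel, high_precision, 0, 0, &out};

  std::vector<kmer_t> ks;
  ks.reserve(g->counts.size());
  for (auto& kv : g->counts) ks.push_back(kv.first);
  std::sort(ks.begin(), ks.end());  // deterministic discovery order

  for (kmer_t c : ks) {
    kmer_t rc = rb_revcomp(c, g->k);
    for (int orient = 0; orient < 2; ++orient) {
      Node X = orient == 0 ? Node{c, rc} : Node{rc, c};
      int s[4];
      int m = rb_succ_chars(*g, X, s);
      if (m < 2) continue;
      std::string Xs = rb_decode(X.f, g->k);
      for (int i = 0; i < m; ++i) {
        for (int j = i + 1; j < m; ++j) {
          std::string p1 = Xs, p2 = Xs;
          p1.push_back(CODE2BASE[s[i]]);
          p2.push_back(CODE2BASE[s[j]]);
          std::vector<int> mism{g->k};
          C.work = 0;
          C.work_cap = 200000;
          snp_step(C, node_step(X, s[i], *g), node_step(X, s[j], *g), p1, p2, mism, 0);
          if (max_indel > 0) {
            indel_explore(C, X, Xs, s[i], s[j]);
            indel_explore(C, X, Xs, s[j], s[i]);
          }
        }
      }
    }
  }

  R_xlen_t n = (R_xlen_t)out.pa.size();
  Rcpp::List offs(n);
  for (R_xlen_t i = 0; i < n; ++i) offs[i] = Rcpp::IntegerVector(out.offs[i].begin(), out.offs[i].end());
  return Rcpp::List::create(
      Rcpp::Named("path_a") = Rcpp::wrap(out.pa), Rcpp::Named("path_b") = Rcpp::wrap(out.pb),
      Rcpp::Named("kind") = Rcpp::wrap(out.kind), Rcpp::Named("closure") = Rcpp::wrap(out.closure),
      Rcpp::Named("sbc_crossed") = Rcpp::wrap(out.sbc), Rcpp::Named("offsets") = offs);
}

// unitig walk used for context extension: extend while the current node has
// exactly one successor, stopping after crossing into a node with more than
// one predecessor (the first ambiguity stays included, further nodes do not)
static std::string walk_right(const KmerGraph& g, Node n, int cap) {
  std::string ctx;
  while ((int)ctx.size() < cap) {
    int s[4];
    int m = rb_succ_chars(g, n, s);
    if (m != 1) break;
    Node nxt = node_step(n, s[0], g);
    ctx.push_back(CODE2BASE[s[0]]);
    n = nxt;
    int p[4];
    Node rcn = node_rc(n);
    if (rb_succ_chars(g, rcn, p) != 1) break;
  }
  return ctx;
}

// [[Rcpp::export]]
Rcpp::List cpp_extend_contexts(SEXP ptr, Rcpp::CharacterVector path_a,
                               Rcpp::CharacterVector path_b, Rcpp::IntegerVector closure) {
  Rcpp::XPtr<KmerGraph> g(ptr);
  const int k = g->k, cap = 100000;
  R_xlen_t n = path_a.size();
  Rcpp::CharacterVector left(n), right(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string pa = CHAR(STRING_ELT(path_a, i));
    std::string lc, rc_ctx;
    if (closure[i] != LEFT_TRUNCATED) {
      kmer_t f;
      if (rb_encode(pa.c_str(), k, f)) {
        Node open{f, rb_revcomp(f, k)};
        lc = rb_revcomp_str(walk_right(*g, node_rc(open), cap));
      }
    }
    if (closure[i] != RIGHT_TRUNCATED) {
      kmer_t f;
      if (rb_encode(pa.c_str() + (pa.size() - k), k, f)) {
        Node close{f, rb_revcomp(f, k)};
        rc_ctx = walk_right(*g, close, cap);
      }
    }
    left[i] = lc;
    right[i] = rc_ctx;
  }
  return Rcpp::List::create(Rcpp::Named("left_context") = left,
                            Rcpp::Named("right_context") = right);
}
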