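// Read-to-bubble mapping (allele coverage) and prediction localization:
// exact k-mer seeding followed by ungapped verification.

#include "radbubbles.h"

struct SeqIndex {
  int k;
  std::vector<std::string> seqs;       // target sequences
  std::vector<std::vector<int>> req;   // per target: positions that must match exactly
  std::vector<int> span_all;           // per target: read must cover every req position
  std::unordered_map<kmer_t, std::vector<std::pair<int32_t, int32_t>>, KmerHash> seeds;
};

static void index_seq(SeqIndex& ix, int idx) {
  const std::string& s = ix.seqs[(size_t)idx];
  const int k = ix.k;
  kmer_t mask = kmask(k), f = 0, r = 0;
  int len = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    int c = base_code(s[(size_t)i]);
    if (c < 0) { len = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (kmer_t)c) & mask;
    r = (r >> 2) | ((kmer_t)(3 - c) << (2 * (k - 1)));
    if (++len >= k) ix.seeds[f < r ? f : r].push_back({idx, i - k + 1});
  }
}

// candidate placements (target index, shift) of `rd` against the index;
// shift = position of rd[0] within the target (may be negative). Seed hits
// along one alignment diagonal arrive in runs, so a last-key short-circuit
// plus a hash set keeps deduplication cheap.
static void collect_candidates(const SeqIndex& ix, const std::string& rd,
                               std::vector<std::pair<int32_t, int32_t>>& cand,
                               std::unordered_set<uint64_t>& seen) {
  const int k = ix.k;
  kmer_t mask = kmask(k), f = 0, r = 0;
  int len = 0;
  uint64_t last_key = ~0ULL;
  seen.clear();
  for (int i = 0; i < (int)rd.size(); ++i) {
    int c = base_code(rd[(size_t)i]);
    if (c < 0) { len = 0; f = 0; r = 0; continue; }
    f = ((f << 2) | (kmer_t)c) & mask;
    r = (r >> 2) | ((kmer_t)(3 - c) << (2 * (k - 1)));
    if (++len >= k) {
      auto it = ix.seeds.find(f < r ? f : r);
      if (it == ix.seeds.end()) continue;
      int rpos = i - k + 1;
      for (auto& hit : it->second) {
        int32_t shift = hit.second - rpos;
        uint64_t key = ((uint64_t)(uint32_t)hit.first << 32) ^
                       (uint32_t)(shift + (1 << 30));
        if (key == last_key) continue;
        last_key = key;
        if (seen.insert(key).second) cand.push_back({hit.first, shift});
      }
    }
  }
}

// ungapped verification; returns mismatch count or -1 on failure.
// require_contained: the whole query must lie inside the target (localization);
// otherwise the read may overhang if the overlap is >= k (coverage mapping).
static int verify(const SeqIndex& ix, const std::string& rd, int idx, int shift,
                  int max_subst, bool require_contained, int* n_req_covered) {
  const std::string& s = ix.seqs[(size_t)idx];
  const int Ls = (int)s.size(), Lr = (int)rd.size();
  int start = std::max(0, shift), end = std::min(Ls, shift + Lr);
  int ov = end - start;
  if (ov <= 0) return -1;
  bool contained = (shift >= 0 && shift + Lr <= Ls);
  if (require_contained && !contained) return -1;
  if (!contained && ov < ix.k) return -1;
  int mism = 0;
  for (int j = start; j < end; ++j) {
    if (s[(size_t)j] != rd[(size_t)(j - shift)] && ++mism > max_subst) return -1;
  }
  const std::vector<int>& req = ix.req[(size_t)idx];
  int ncov = 0;
  for (int rp : req) {
    if (rp < start || rp >= end) continue;
    ++ncov;
    if (s[(size_t)rp] != rd[(size_t)(rp - shift)]) return -1;  // exact at variant positions
  }
  if (n_req_covered) *n_req_covered = ncov;
  if (ix.span_all[(size_t)idx] && ncov > 0 && ncov < (int)req.size()) return -1;
  return mism;
}

// [[Rcpp::export]]
SEXP cpp_bubble_index(Rcpp::CharacterVector ext_a, Rcpp::CharacterVector ext_b,
                      Rcpp::List req_a, Rcpp::List req_b, Rcpp::LogicalVector span_all,
                      int k) {
  SeqIndex* ix = new SeqIndex();
  ix->k = k;
  R_xlen_t n = ext_a.size();
  ix->seqs.reserve((size_t)(2 * n));
  for (R_xlen_t i = 0; i < n; ++i) {
    ix->seqs.push_back(CHAR(STRING_ELT(ext_a, i)));
    ix->seqs.push_back(CHAR(STRING_ELT(ext_b, i)));
    Rcpp::IntegerVector ra = req_a[i], rb = req_b[i];
    ix->req.push_back(std::vector<int>(ra.begin(), ra.end()));
    ix->req.push_back(std::vector<int>(rb.begin(), rb.end()));
    ix->span_all.push_back(span_all[i] ? 1 : 0);
    ix->span_all.push_back(span_all[i] ? 1 : 0);
  }
  for (int i = 0; i < (int)ix->seqs.size(); ++i) index_seq(*ix, i);
  return Rcpp::XPtr<SeqIndex>(ix, true);
}

// Allele coverage of one sample: each read (either strand) is placed on every
// seeded bubble allele; a read supports an allele when the placement passes
// verification and covers at least one variant position; a read matching both
// alleles of a bubble, or no variant position, contributes nothing.
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_map_sample(SEXP ptr, Rcpp::CharacterVector reads, int max_subst) {
  Rcpp::XPtr<SeqIndex> ix(ptr);
  int nb = (int)ix->seqs.size() / 2;
  Rcpp::IntegerMatrix counts(nb, 2);
  std::vector<std::pair<int32_t, int32_t>> cand;
  std::unordered_set<uint64_t> seen;
  std::unordered_map<int, int> support;  // bubble -> bitmask of supported alleles
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string rd = CHAR(STRING_ELT(reads, ri));
    support.clear();
    for (int strand = 0; strand < 2; ++strand) {
      if (strand == 1) rd = rb_revcomp_str(rd);
      cand.clear();
      collect_candidates(*ix, rd, cand, seen);
      for (auto& cs : cand) {
        int ncov = 0;
        int mm = verify(*ix, rd, cs.first, cs.second, max_subst, false, &ncov);
        if (mm < 0 || ncov == 0) continue;
        support[cs.first / 2] |= (cs.first % 2 == 0) ? 1 : 2;
      }
    }
    for (auto& kv : support) {
      if (kv.second == 1) counts(kv.first, 0)++;
      else if (kv.second == 2) counts(kv.first, 1)++;
      // both alleles matched: ambiguous, counted for neither
    }
  }
  return counts;
}

// Localization of predictions against simulated locus references: each allele
// sequence is placed (full containment, either strand, <= max_subst
// substitutions); the unique best placement wins. Status: 0 = localized,
// 1 = no placement, 2 = ambiguous.
// [[Rcpp::export]]
Rcpp::List cpp_localize(Rcpp::CharacterVector ext_a, Rcpp::CharacterVector ext_b,
                        Rcpp::CharacterVector loci, int k, int max_subst) {
  SeqIndex ix;
  ix.k = k;
  for (R_xlen_t i = 0; i < loci.size(); ++i) {
    ix.seqs.push_back(CHAR(STRING_ELT(loci, i)));
    ix.req.push_back({});
    ix.span_all.push_back(0);
  }
  for (int i = 0; i < (int)ix.seqs.size(); ++i) index_seq(ix, i);

  R_xlen_t n = ext_a.size();
  Rcpp::IntegerVector allele(n), locus(n), start(n), strand(n), mism(n), status(n);
  std::vector<std::pair<int32_t, int32_t>> cand;
  std::unordered_set<uint64_t> seen;

  for (R_xlen_t i = 0; i < n; ++i) {
    // best placement per allele: locus, strand, start, mismatches, tie count
    int best_loc[2] = {-1, -1}, best_str[2] = {0, 0}, best_sta[2] = {0, 0};
    int best_mm[2] = {max_subst + 1, max_subst + 1}, ties[2] = {0, 0};
    for (int al = 0; al < 2; ++al) {
      std::string s = CHAR(STRING_ELT(al == 0 ? ext_a : ext_b, i));
      for (int st = 0; st < 2; ++st) {
        std::string q = (st == 0) ? s : rb_revcomp_str(s);
        cand.clear();
        collect_candidates(ix, q, cand, seen);
        for (auto& cs : cand) {
          int mm = verify(ix, q, cs.first, cs.second, max_subst, true, nullptr);
          if (mm < 0) continue;
          if (mm < best_mm[al]) {
            best_mm[al] = mm;
            best_loc[al] = cs.first;
            best_str[al] = (st == 0) ? 1 : -1;
            best_sta[al] = cs.second;
            ties[al] = 1;
          } else if (mm == best_mm[al]) {
            if (cs.first != best_loc[al] || cs.second != best_sta[al] ||
                ((st == 0 ? 1 : -1) != best_str[al]))
              ties[al]++;
          }
        }
      }
    }
    bool ok_a = (best_loc[0] >= 0 && ties[0] == 1);
    bool ok_b = (best_loc[1] >= 0 && ties[1] == 1);
    int use = -1;
    if (ok_a && ok_b) {
      if (best_loc[0] == best_loc[1]) use = (best_mm[1] < best_mm[0]) ? 1 : 0;
      else { status[i] = 2; }
    } else if (ok_a) use = 0;
    else if (ok_b) use = 1;
    else status[i] = (best_loc[0] >= 0 || best_loc[1] >= 0) ? 2 : 1;
    if (use >= 0) {
      allele[i] = use + 1;
      locus[i] = best_loc[use] + 1;
      start[i] = best_sta[use];
      strand[i] = best_str[use];
      mism[i] = best_mm[use];
      status[i] = 0;
    } else {
      allele[i] = NA_INTEGER;
      locus[i] = NA_INTEGER;
      start[i] = NA_INTEGER;
      strand[i] = NA_INTEGER;
      mism[i] = NA_INTEGER;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("allele") = allele, Rcpp::Named("locus") = locus,
      Rcpp::Named("start") = start, Rcpp::Named("strand") = strand,
      Rcpp::Named("mismatches") = mism, Rcpp::Named("status") = status);
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_revcomp(Rcpp::CharacterVector seqs) {
  Rcpp::CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = rb_revcomp_str(CHAR(STRING_ELT(seqs, i)));
  return out;
}
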