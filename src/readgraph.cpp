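// Read-overlap graph construction for de novo repeat clustering: candidate
// pairs via shared k-mers (both orientations), scored by the best ungapped
// overlap; an edge is kept when identity and overlap-fraction thresholds are
// met. Candidate partners per read are capped so dense satellite clusters
// stay tractable.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement(c);
  return r;
}

static inline bool encode_kmer(const std::string& s, size_t i, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int j = 0; j < k; ++j) {
    int b = base2bit(s[i + j]);
    if (b < 0) return false;
    v = (v << 2) | static_cast<uint64_t>(b);
  }
  key = v;
  return true;
}

// Ungapped overlap of s1 and s2 at a fixed diagonal (offset of s2 relative to
// s1). Returns overlap length and identities via out-params.
static void score_diag(const std::string& s1, const std::string& s2, int diag,
                       int& olen, int& matches) {
  const int L1 = (int)s1.size(), L2 = (int)s2.size();
  int start1 = std::max(0, diag);
  int end1 = std::min(L1, L2 + diag);
  olen = end1 - start1;
  matches = 0;
  if (olen <= 0) { olen = 0; return; }
  for (int i = start1; i < end1; ++i) {
    int a = base2bit(s1[i]), b = base2bit(s2[i - diag]);
    if (a >= 0 && a == b) ++matches;
  }
}

// [[Rcpp::export]]
DataFrame cpp_read_graph(CharacterVector reads, int k, double min_identity,
                         double min_overlap_fraction, int max_candidates,
                         int max_kmer_occ) {
  const R_xlen_t n = reads.size();
  std::vector<std::string> seq(n);
  for (R_xlen_t i = 0; i < n; ++i) seq[i] = as<std::string>(reads[i]);

  // k-mer table over forward strands
  std::unordered_map<uint64_t, std::vector<std::pair<uint32_t, uint16_t> > > table;
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string& s = seq[i];
    if ((int)s.size() < k) stop("read shorter than k");
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t key;
      if (!encode_kmer(s, p, k, key)) continue;
      auto& v = table[key];
      if ((int)v.size() < max_kmer_occ)
        v.push_back(std::make_pair((uint32_t)i, (uint16_t)p));
    }
  }

  std::vector<int> e_from, e_to;
  std::vector<double> e_weight, e_identity, e_overlap;
  std::unordered_set<uint64_t> seen_pairs; // canonical (min << 32 | max)

  // candidate key: partner << 1 | orientation
  std::unordered_map<uint64_t, std::pair<int, int> > cands; // -> (diag, votes)
  for (R_xlen_t i = 0; i < n; ++i) {
    cands.clear();
    bool full = false;
    for (int orient = 0; orient < 2 && !full; ++orient) {
      std::string s1 = orient ? revcomp(seq[i]) : seq[i];
      for (size_t p = 0; p + k <= s1.size() && !full; ++p) {
        uint64_t key;
        if (!encode_kmer(s1, p, k, key)) continue;
        auto it = table.find(key);
        if (it == table.end()) continue;
        for (auto& hit : it->second) {
          if ((R_xlen_t)hit.first == i) continue;
          uint64_t ck = ((uint64_t)hit.first << 1) | (uint64_t)orient;
          int diag = (int)p - (int)hit.second;
          auto ct = cands.find(ck);
          if (ct == cands.end()) {
            if ((int)cands.size() >= max_candidates) { full = true; break; }
            cands[ck] = std::make_pair(diag, 1);
          } else {
            ct->second.second += 1;
            // keep the most-voted diagonal; simple majority update
            if (ct->second.first != diag && ct->second.second == 2)
              ct->second.first = diag;
          }
        }
      }
    }
    for (auto& kv : cands) {
      uint32_t j = (uint32_t)(kv.first >> 1);
      uint64_t pair_key = ((uint64_t)std::min((uint32_t)i, j) << 32) |
                          (uint64_t)std::max((uint32_t)i, j);
      if (seen_pairs.count(pair_key)) continue;
      int orient = (int)(kv.first & 1ULL);
      int diag = kv.second.first;
      const std::string s1 = orient ? revcomp(seq[i]) : seq[i];
      const std::string& s2 = seq[j];
      // diag stored as p(s1) - p(s2): offset of s2 start relative to s1 is diag
      int olen, matches;
      score_diag(s1, s2, diag, olen, matches);
      int minlen = (int)std::min(s1.size(), s2.size());
      if (olen < min_overlap_fraction * minlen) continue;
      double ident = olen > 0 ? (double)matches / olen : 0.0;
      if (ident < min_identity) continue;
      double ofrac = (double)olen / minlen;
      seen_pairs.insert(pair_key);
      e_from.push_back((int)i + 1);
      e_to.push_back((int)j + 1);
      e_identity.push_back(ident);
      e_overlap.push_back(ofrac);
      e_weight.push_back(ident * ofrac);
    }
  }
  return DataFrame::create(_["from"] = wrap(e_from), _["to"] = wrap(e_to),
                           _["weight"] = wrap(e_weight),
                           _["identity"] = wrap(e_identity),
                           _["overlap_fraction"] = wrap(e_overlap),
                           _["stringsAsFactors"] = false);
}
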