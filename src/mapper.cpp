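// Seed-and-extend read mapper: exact k-mer seeding on both strands of the
// reference, full-length ungapped extension, best-placement selection with
// seeded random tie-breaking. Also pileup accumulation and a brute-force
// aligner used as an independent oracle in the test suite.
#include <Rcpp.h>
#include <unordered_map>
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
  case 'A': return 'T'; case 'a': return 't';
  case 'C': return 'G'; case 'c': return 'g';
  case 'G': return 'C'; case 'g': return 'c';
  case 'T': return 'A'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement(c);
  return r;
}

// hit packing: contig (bits 33..62), pos (bits 1..32), strand (bit 0)
static inline uint64_t pack_hit(uint32_t contig, uint32_t pos, int rc) {
  return (static_cast<uint64_t>(contig) << 33) |
         (static_cast<uint64_t>(pos) << 1) | static_cast<uint64_t>(rc);
}

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t> > table;
};

// encode k-mer starting at s[i]; returns false if it contains a non-ACGT base
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

static inline uint64_t rc_key(uint64_t key, int k) {
  uint64_t r = 0;
  for (int j = 0; j < k; ++j) {
    r = (r << 2) | (3ULL - (key & 3ULL));
    key >>= 2;
  }
  return r;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  for (R_xlen_t c = 0; c < seqs.size(); ++c) {
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(as<std::string>(seqs[c]));
  }
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string& s = idx->seqs[c];
    if (static_cast<int>(s.size()) < k) continue;
    for (size_t i = 0; i + k <= s.size(); ++i) {
      uint64_t key;
      if (!encode_kmer(s, i, k, key)) continue;
      idx->table[key].push_back(pack_hit((uint32_t)c, (uint32_t)i, 0));
      idx->table[rc_key(key, k)].push_back(pack_hit((uint32_t)c, (uint32_t)i, 1));
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  IntegerVector len(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) len[i] = (int)idx->seqs[i].size();
  return List::create(_["k"] = idx->k,
                      _["contig"] = wrap(idx->names),
                      _["length"] = len,
                      _["n_kmers"] = (double)idx->table.size());
}

// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  std::vector<int> contig, pos;
  std::vector<std::string> strand;
  uint64_t key;
  if ((int)kmer.size() == idx->k && encode_kmer(kmer, 0, idx->k, key)) {
    auto it = idx->table.find(key);
    if (it != idx->table.end()) {
      for (uint64_t h : it->second) {
        contig.push_back((int)(h >> 33) + 1);
        pos.push_back((int)((h >> 1) & 0xFFFFFFFFULL));
        strand.push_back((h & 1ULL) ? "-" : "+");
      }
    }
  }
  return DataFrame::create(_["contig"] = wrap(contig), _["pos"] = wrap(pos),
                           _["strand"] = wrap(strand),
                           _["stringsAsFactors"] = false);
}

static inline int count_mismatches(const std::string& read, const std::string& ref,
                                   int start, int cap) {
  int mm = 0;
  const size_t L = read.size();
  for (size_t i = 0; i < L; ++i) {
    char a = read[i], b = ref[start + i];
    int ba = base2bit(a), bb = base2bit(b);
    if (ba < 0 || bb < 0 || ba != bb) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// Map reads against the index. Seeds are taken at n_seeds evenly spaced
// offsets. Uses R's RNG for tie-breaking so results are reproducible under
// set.seed().
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp, CharacterVector reads, double max_mismatch_rate,
                        int n_seeds) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  std::vector<int> out_read, out_contig, out_start, out_mm, out_nbest;
  std::vector<int> out_strand; // 0 = +, 1 = -
  RNGScope scope;

  std::vector<uint64_t> cand; // packed (contig << 33) | (start+1 offset<<1) | strand
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    const int L = (int)read.size();
    if (L < k) continue;
    const int cap = (int)std::ceil(max_mismatch_rate * L);
    cand.clear();
    int span = L - k;
    int ns = std::max(1, n_seeds);
    for (int si = 0; si < ns; ++si) {
      int j = (ns == 1) ? 0 : (int)std::llround((double)si * span / (ns - 1));
      uint64_t key;
      if (!encode_kmer(read, (size_t)j, k, key)) continue;
      auto it = idx->table.find(key);
      if (it == idx->table.end()) continue;
      for (uint64_t h : it->second) {
        uint32_t c = (uint32_t)(h >> 33);
        int pos = (int)((h >> 1) & 0xFFFFFFFFULL);
        int rc = (int)(h & 1ULL);
        // + hit: read aligns forward, start = pos - j
        // - hit: read k-mer equals revcomp of contig k-mer; revcomp(read)
        //   aligns forward with its k-mer at offset L-k-j
        int start = rc ? pos - (L - k - j) : pos - j;
        if (start < 0 || start + L > (int)idx->seqs[c].size()) continue;
        // start+1 so the packed value stays non-negative in 32 bits
        cand.push_back(pack_hit(c, (uint32_t)(start), rc));
      }
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    std::string rcread;
    int best_mm = cap + 1;
    std::vector<uint64_t> best;
    for (uint64_t h : cand) {
      uint32_t c = (uint32_t)(h >> 33);
      int start = (int)((h >> 1) & 0xFFFFFFFFULL);
      int rc = (int)(h & 1ULL);
      const std::string& q = rc ? (rcread.empty() ? (rcread = revcomp(read)) : rcread)
                                : read;
      int mm = count_mismatches(q, idx->seqs[c], start, best_mm);
      if (mm < best_mm) {
        best_mm = mm;
        best.clear();
        best.push_back(h);
      } else if (mm == best_mm && mm <= cap) {
        best.push_back(h);
      }
    }
    if (best_mm > cap || best.empty()) continue;
    size_t pick = 0;
    if (best.size() > 1) pick = (size_t)std::floor(unif_rand() * best.size());
    if (pick >= best.size()) pick = best.size() - 1;
    uint64_t h = best[pick];
    out_read.push_back((int)r + 1);
    out_contig.push_back((int)(h >> 33) + 1);
    out_start.push_back((int)((h >> 1) & 0xFFFFFFFFULL));
    out_strand.push_back((int)(h & 1ULL));
    out_mm.push_back(best_mm);
    out_nbest.push_back((int)best.size());
  }
  return DataFrame::create(_["read"] = wrap(out_read),
                           _["contig"] = wrap(out_contig),
                           _["start"] = wrap(out_start),
                           _["strand"] = wrap(out_strand),
                           _["mismatches"] = wrap(out_mm),
                           _["n_best"] = wrap(out_nbest),
                           _["stringsAsFactors"] = false);
}

// Exhaustive aligner: slide each read over every position of every contig on
// both strands; report the minimum mismatch count. Independent of the seeded
// path; used as a test oracle.
// [[Rcpp::export]]
IntegerVector cpp_brute_best_mismatch(CharacterVector reads, CharacterVector contigs) {
  IntegerVector out(reads.size());
  std::vector<std::string> refs;
  for (R_xlen_t c = 0; c < contigs.size(); ++c)
    refs.push_back(as<std::string>(contigs[c]));
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fw = as<std::string>(reads[r]);
    std::string rv = revcomp(fw);
    const int L = (int)fw.size();
    int best = L + 1;
    for (const std::string& ref : refs) {
      int n = (int)ref.size() - L;
      for (int s = 0; s <= n; ++s) {
        int mm = count_mismatches(fw, ref, s, best - 1);
        if (mm < best) best = mm;
        mm = count_mismatches(rv, ref, s, best - 1);
        if (mm < best) best = mm;
      }
    }
    out[r] = (best > L) ? NA_INTEGER : best;
  }
  return out;
}

// Pileup: per-contig total coverage (all aligned bases) and per-position
// counts of A/C/G/T restricted to bases with phred >= min_base_quality.
// Alignments on the minus strand contribute the reverse complement of the
// read with reversed qualities.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector contig_len,
                IntegerVector aln_contig, IntegerVector aln_start,
                IntegerVector aln_strand, IntegerVector aln_read,
                CharacterVector read_seq, CharacterVector read_qual,
                int min_base_quality) {
  const int nc = contig_len.size();
  std::vector<std::vector<int> > cov(nc);
  std::vector<std::vector<int> > cnt(nc); // 4 * len, base-major rows A,C,G,T
  for (int c = 0; c < nc; ++c) {
    cov[c].assign(contig_len[c], 0);
    cnt[c].assign(4 * (size_t)contig_len[c], 0);
  }
  const R_xlen_t na = aln_contig.size();
  for (R_xlen_t a = 0; a < na; ++a) {
    int c = aln_contig[a] - 1;
    int start = aln_start[a];
    int rc = aln_strand[a];
    int ri = aln_read[a] - 1;
    std::string s = as<std::string>(read_seq[ri]);
    std::string q = as<std::string>(read_qual[ri]);
    if (rc) {
      s = revcomp(s);
      std::reverse(q.begin(), q.end());
    }
    const int L = (int)s.size();
    const int clen = contig_len[c];
    for (int i = 0; i < L; ++i) {
      int p = start + i;
      if (p < 0 || p >= clen) continue;
      cov[c][p] += 1;
      int b = base2bit(s[i]);
      if (b < 0) continue;
      int phred = (int)q[i] - 33;
      if (phred >= min_base_quality) cnt[c][(size_t)4 * p + b] += 1;
    }
  }
  List out(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerVector coverage(cov[c].begin(), cov[c].end());
    IntegerMatrix counts(4, contig_len[c]);
    std::copy(cnt[c].begin(), cnt[c].end(), counts.begin());
    rownames(counts) = CharacterVector::create("A", "C", "G", "T");
    out[c] = List::create(_["coverage"] = coverage, _["counts"] = counts);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
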