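// Exact multi-mapping short-read aligner.
//
// Reports every placement of every read with <= m mismatches, both strands,
// by pigeonhole seeding: a read is split into m+1 disjoint segments; any
// valid placement matches at least one segment exactly. Segments (capped at
// 32 bp for 2-bit encoding) are looked up in a sorted k-mer index of the
// concatenated genome and candidates are verified over the full read.
// Reference N never matches. Reverse-strand placements are reported at
// their forward-strand start.

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

struct SeedIndex {
  int slen;
  std::vector<uint64_t> keys;   // sorted
  std::vector<int> pos;         // genome positions, co-sorted with keys
};

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector ref_seqs, CharacterVector read_seqs,
                   int max_mismatches) {
  const int ncontig = ref_seqs.size();
  std::vector<int> offset(ncontig + 1, 0);
  for (int i = 0; i < ncontig; ++i)
    offset[i + 1] = offset[i] + LENGTH(STRING_ELT(ref_seqs, i));
  const int G = offset[ncontig];

  std::vector<int8_t> g(G);
  for (int i = 0; i < ncontig; ++i) {
    const char* s = CHAR(STRING_ELT(ref_seqs, i));
    for (int j = offset[i]; j < offset[i + 1]; ++j) g[j] = code(s[j - offset[i]]);
  }

  const int nreads = read_seqs.size();
  if (nreads == 0)
    return List::create(_["read"] = IntegerVector(0),
                        _["contig"] = IntegerVector(0),
                        _["start"] = IntegerVector(0),
                        _["strand"] = CharacterVector(0));
  const int L = LENGTH(STRING_ELT(read_seqs, 0));
  const int nseg = max_mismatches + 1;
  const int flen = L / nseg;                 // disjoint segment stride
  const int slen = std::min(32, flen);
  if (slen < 8) stop("reads too short for the requested mismatch count");

  // index every genome position whose next slen bases are unambiguous
  SeedIndex idx;
  idx.slen = slen;
  {
    std::vector<std::pair<uint64_t, int>> kv;
    kv.reserve(G);
    for (int c = 0; c < ncontig; ++c) {
      int lo = offset[c], hi = offset[c + 1];
      if (hi - lo < slen) continue;
      uint64_t key = 0; int run = 0;
      const uint64_t mask =
        (slen == 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * slen)) - 1);
      for (int p = lo; p < hi; ++p) {
        int b = g[p];
        if (b == 4) { run = 0; key = 0; continue; }
        key = ((key << 2) | uint64_t(b)) & mask;
        if (++run >= slen) kv.emplace_back(key, p - slen + 1);
      }
    }
    std::sort(kv.begin(), kv.end());
    idx.keys.resize(kv.size());
    idx.pos.resize(kv.size());
    for (size_t i = 0; i < kv.size(); ++i) {
      idx.keys[i] = kv[i].first;
      idx.pos[i] = kv[i].second;
    }
  }

  std::vector<int> out_read, out_contig, out_start;
  std::vector<char> out_strand;

  std::vector<int8_t> fwd(L), rev(L);
  std::vector<int> cand;
  for (int r = 0; r < nreads; ++r) {
    const char* s = CHAR(STRING_ELT(read_seqs, r));
    if ((int) LENGTH(STRING_ELT(read_seqs, r)) != L)
      stop("all reads must have equal length");
    bool ambiguous = false;
    for (int i = 0; i < L; ++i) {
      fwd[i] = code(s[i]);
      if (fwd[i] == 4) ambiguous = true;
    }
    if (ambiguous) continue;               // simulated reads carry no N
    for (int i = 0; i < L; ++i) rev[i] = 3 - fwd[L - 1 - i];

    for (int st = 0; st < 2; ++st) {
      const std::vector<int8_t>& rd = (st == 0) ? fwd : rev;
      cand.clear();
      for (int sgi = 0; sgi < nseg; ++sgi) {
        int off = sgi * flen;
        uint64_t key = 0;
        for (int i = 0; i < slen; ++i) key = (key << 2) | uint64_t(rd[off + i]);
        auto lohi = std::equal_range(idx.keys.begin(), idx.keys.end(), key);
        for (auto it = lohi.first; it != lohi.second; ++it) {
          int p = idx.pos[it - idx.keys.begin()] - off;
          if (p >= 0) cand.push_back(p);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (int p : cand) {
        // locate contig, check bounds
        int c = int(std::upper_bound(offset.begin(), offset.end(), p) -
                    offset.begin()) - 1;
        if (p + L > offset[c + 1]) continue;
        int mm = 0;
        for (int i = 0; i < L; ++i) {
          if (g[p + i] != rd[i]) { if (++mm > max_mismatches) break; }
        }
        if (mm <= max_mismatches) {
          out_read.push_back(r + 1);
          out_contig.push_back(c + 1);
          out_start.push_back(p - offset[c]);
          out_strand.push_back(st == 0 ? '+' : '-');
        }
      }
    }
  }

  CharacterVector strand(out_strand.size());
  for (size_t i = 0; i < out_strand.size(); ++i)
    strand[i] = std::string(1, out_strand[i]);
  return List::create(_["read"] = wrap(out_read),
                      _["contig"] = wrap(out_contig),
                      _["start"] = wrap(out_start),
                      _["strand"] = strand);
}
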