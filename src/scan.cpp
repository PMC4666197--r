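// Core read scanner: seeded, ungapped V/J segment matching against short reads.
//
// A read is called when (i) some V segment has an ungapped diagonal match of
// length >= min_v whose end in V coordinates reaches the conserved Cys anchor
// or beyond (the anchor read position is extrapolated along the diagonal, so
// it need not be covered by the matched run), and (ii) some J segment has an
// ungapped match of length >= min_j covering its [FW]GXG anchor codon, with
// the V anchor strictly upstream of the J anchor inside the read.  The CDR3
// is the anchor-to-anchor span, inclusive of both anchor codons.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and anything else: never matches
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

struct SeedHit { int seg; int pos; };

struct BestMatch {
  int len = 0;      // matched window length
  int seg = -1;     // segment index (order as passed: pre-sorted by name)
  int p   = -1;     // anchor position in the read (0-based)
  bool valid() const { return seg >= 0; }
};

// Prefer longer windows; ties by segment order (callers pass segments sorted
// by name), then by leftmost anchor position in the read.
static inline void update_best(BestMatch &best, int len, int seg, int p) {
  if (len > best.len ||
      (len == best.len && (seg < best.seg ||
                           (seg == best.seg && p < best.p)))) {
    best.len = len; best.seg = seg; best.p = p;
  }
}

class SegmentIndex {
public:
  int k;
  std::unordered_map<uint64_t, std::vector<SeedHit> > table;
  SegmentIndex(const std::vector<std::string> &segs, int k_) : k(k_) {
    for (size_t s = 0; s < segs.size(); ++s) {
      const std::string &seq = segs[s];
      int n = (int)seq.size();
      if (n < k) continue;
      uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      int run = 0;
      for (int i = 0; i < n; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= k)
          table[key].push_back(SeedHit{(int)s, i - k + 1});
      }
    }
  }
};

// Longest window [s,e) on one diagonal with <= max_mm mismatches subject to
// an anchor condition.  seg coordinates; read position = seg position + d.
static void scan_diagonal_v(const std::string &seg, const std::string &read,
                            int d, int anchor, int max_mm, BestMatch &best,
                            int seg_idx) {
  int L = (int)read.size(), n = (int)seg.size();
  int lo = std::max(0, -d), hi = std::min(n, L - d);
  if (hi <= lo) return;
  int p = anchor + d;              // extrapolated anchor position in read
  if (p < 0 || p > L - 3) return;  // anchor codon must start inside the read
  // two-pointer over window end e (exclusive); require e >= anchor
  int s = lo, mm = 0;
  for (int e = lo + 1; e <= hi; ++e) {
    int cs = base_code(seg[e - 1]), cr = base_code(read[e - 1 + d]);
    if (cs < 0 || cr < 0 || cs != cr) ++mm;
    while (mm > max_mm) {
      int c2s = base_code(seg[s]), c2r = base_code(read[s + d]);
      if (c2s < 0 || c2r < 0 || c2s != c2r) --mm;
      ++s;
    }
    if (e >= anchor) update_best(best, e - s, seg_idx, p);
  }
}

static void scan_diagonal_j(const std::string &seg, const std::string &read,
                            int d, int anchor, int max_mm, BestMatch &best,
                            int seg_idx) {
  int L = (int)read.size(), n = (int)seg.size();
  int lo = std::max(0, -d), hi = std::min(n, L - d);
  if (lo > anchor || hi < anchor + 3) return;  // must be able to cover anchor codon
  int p = anchor + d;
  if (p < 0 || p > L - 3) return;
  int s = lo, mm = 0;
  for (int e = lo + 1; e <= hi; ++e) {
    int cs = base_code(seg[e - 1]), cr = base_code(read[e - 1 + d]);
    if (cs < 0 || cr < 0 || cs != cr) ++mm;
    while (mm > max_mm) {
      int c2s = base_code(seg[s]), c2r = base_code(read[s + d]);
      if (c2s < 0 || c2r < 0 || c2s != c2r) --mm;
      ++s;
    }
    // window must cover [anchor, anchor + 3)
    if (e >= anchor + 3 && s <= anchor) update_best(best, e - s, seg_idx, p);
  }
}

struct Candidate {
  int read, strand, chain, v_seg, j_seg, v_len, j_len, v_pos, j_pos;
  std::string cdr3;
};

// Scan reads against V and J segments of both chains.  Returns one candidate
// row per (read, strand, chain) combination whose best V and best J matches
// satisfy the thresholds and anchor geometry.
// [[Rcpp::export]]
DataFrame scan_reads_cpp(CharacterVector reads,
                         CharacterVector seg_seq,
                         IntegerVector seg_chain,   // 0 = alpha, 1 = beta
                         LogicalVector seg_is_v,    // TRUE = V, FALSE = J
                         IntegerVector seg_anchor,  // 0-based anchor codon start
                         int min_v, int min_j, int max_mismatch,
                         bool both_strands) {
  int nseg = seg_seq.size();
  std::vector<std::string> segs(nseg);
  for (int i = 0; i < nseg; ++i) segs[i] = as<std::string>(seg_seq[i]);

  int min_any = std::min(min_v, min_j);
  int k = std::min(8, min_any);
  if (max_mismatch > 0)
    k = std::max(3, std::min(k, min_any / (max_mismatch + 1)));
  if (k < 1) k = 1;

  SegmentIndex index(segs, k);

  std::vector<Candidate> out;
  int nreads = reads.size();

  for (int r = 0; r < nreads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int n_orient = both_strands ? 2 : 1;
    for (int o = 0; o < n_orient; ++o) {
      std::string read;
      if (o == 0) read = fwd;
      else {
        read.resize(fwd.size());
        for (size_t i = 0; i < fwd.size(); ++i)
          read[i] = comp_base(fwd[fwd.size() - 1 - i]);
      }
      int L = (int)read.size();
      if (L < k) continue;

      // collect candidate diagonals per segment
      std::vector<std::vector<int> > diags(nseg);
      uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      int run = 0;
      for (int i = 0; i < L; ++i) {
        int c = base_code(read[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.table.find(key);
          if (it != index.table.end())
            for (const SeedHit &h : it->second)
              diags[h.seg].push_back((i - k + 1) - h.pos);
        }
      }

      // best V and best J per chain
      BestMatch bestV[2], bestJ[2];
      for (int s = 0; s < nseg; ++s) {
        std::vector<int> &dv = diags[s];
        if (dv.empty()) continue;
        std::sort(dv.begin(), dv.end());
        dv.erase(std::unique(dv.begin(), dv.end()), dv.end());
        int ch = seg_chain[s];
        for (int d : dv) {
          if (seg_is_v[s])
            scan_diagonal_v(segs[s], read, d, seg_anchor[s], max_mismatch,
                            bestV[ch], s);
          else
            scan_diagonal_j(segs[s], read, d, seg_anchor[s], max_mismatch,
                            bestJ[ch], s);
        }
      }

      for (int ch = 0; ch < 2; ++ch) {
        if (!bestV[ch].valid() || !bestJ[ch].valid()) continue;
        if (bestV[ch].len < min_v || bestJ[ch].len < min_j) continue;
        int pv = bestV[ch].p, pj = bestJ[ch].p;
        if (!(pv < pj) || pj + 3 > L) continue;
        Candidate cand;
        cand.read = r + 1;
        cand.strand = (o == 0) ? 1 : -1;
        cand.chain = ch;
        cand.v_seg = bestV[ch].seg + 1;
        cand.j_seg = bestJ[ch].seg + 1;
        cand.v_len = bestV[ch].len;
        cand.j_len = bestJ[ch].len;
        cand.v_pos = pv;
        cand.j_pos = pj;
        cand.cdr3 = read.substr(pv, pj + 3 - pv);
        out.push_back(cand);
      }
    }
  }

  int m = (int)out.size();
  IntegerVector read_(m), strand_(m), chain_(m), vseg_(m), jseg_(m),
      vlen_(m), jlen_(m), vpos_(m), jpos_(m);
  CharacterVector cdr3_(m);
  for (int i = 0; i < m; ++i) {
    read_[i] = out[i].read; strand_[i] = out[i].strand;
    chain_[i] = out[i].chain; vseg_[i] = out[i].v_seg; jseg_[i] = out[i].j_seg;
    vlen_[i] = out[i].v_len; jlen_[i] = out[i].j_len;
    vpos_[i] = out[i].v_pos; jpos_[i] = out[i].j_pos;
    cdr3_[i] = out[i].cdr3;
  }
  return DataFrame::create(
      _["read"] = read_, _["strand"] = strand_, _["chain"] = chain_,
      _["v_seg"] = vseg_, _["j_seg"] = jseg_, _["v_len"] = vlen_,
      _["j_len"] = jlen_, _["v_pos"] = vpos_, _["j_pos"] = jpos_,
      _["cdr3"] = cdr3_, _["stringsAsFactors"] = false);
}

// Tabulate the (min_v, min_j) grid from one loose scan.  Candidates must be
// sorted by read index; for each read and each grid cell the winning
// candidate (max v_len + j_len, ties by chain, then cdr3 id, then V then J
// segment order) is the call.  cdr3 ids are 1-based factor codes whose level
// order is lexicographic, so id comparisons reproduce string tie-breaks.
// recovery_weight[id - 1] is the number of truth transcripts whose truth CDR3
// equals that cdr3 (0 for non-truth sequences); positive reads contribute
// distinct called cdr3 ids weighted by it, negative reads contribute distinct
// called cdr3 ids to the bogus count.
// [[Rcpp::export]]
List grid_tabulate_cpp(IntegerVector cand_read, IntegerVector cand_chain,
                       IntegerVector cand_v, IntegerVector cand_j,
                       IntegerVector cand_vlen, IntegerVector cand_jlen,
                       IntegerVector cand_cdr3, LogicalVector read_negative,
                       NumericVector recovery_weight,
                       IntegerVector v_vals, IntegerVector j_vals,
                       int chain_filter) {  // -1 = all chains
  int m = cand_read.size();
  int nv = v_vals.size(), nj = j_vals.size();
  int nlev = recovery_weight.size();
  NumericMatrix n_recovered(nv, nj);
  IntegerMatrix n_bogus(nv, nj);
  std::vector<int> stamp_pos(nlev + 1, -1), stamp_neg(nlev + 1, -1);

  // group candidates by read (input sorted by read)
  std::vector<int> starts;
  for (int i = 0; i < m; ++i)
    if (i == 0 || cand_read[i] != cand_read[i - 1]) starts.push_back(i);
  starts.push_back(m);

  for (int iv = 0; iv < nv; ++iv) {
    for (int ij = 0; ij < nj; ++ij) {
      int Tv = v_vals[iv], Tj = j_vals[ij];
      int cell = iv * nj + ij;
      double rec = 0.0; int bog = 0;
      for (size_t g = 0; g + 1 < starts.size(); ++g) {
        int lo = starts[g], hi = starts[g + 1];
        int best = -1;
        for (int i = lo; i < hi; ++i) {
          if (cand_vlen[i] < Tv || cand_jlen[i] < Tj) continue;
          if (chain_filter >= 0 && cand_chain[i] != chain_filter) continue;
          if (best < 0) { best = i; continue; }
          int si = cand_vlen[i] + cand_jlen[i];
          int sb = cand_vlen[best] + cand_jlen[best];
          if (si > sb ||
              (si == sb && (cand_chain[i] < cand_chain[best] ||
                (cand_chain[i] == cand_chain[best] &&
                 (cand_cdr3[i] < cand_cdr3[best] ||
                  (cand_cdr3[i] == cand_cdr3[best] &&
                   (cand_v[i] < cand_v[best] ||
                    (cand_v[i] == cand_v[best] && cand_j[i] < cand_j[best]))))))))
            best = i;
        }
        if (best < 0) continue;
        int id = cand_cdr3[best];
        int rd = cand_read[best] - 1;
        if (read_negative[rd]) {
          if (stamp_neg[id] != cell) { stamp_neg[id] = cell; ++bog; }
        } else {
          if (stamp_pos[id] != cell) {
            stamp_pos[id] = cell;
            rec += recovery_weight[id - 1];
          }
        }
      }
      n_recovered(iv, ij) = rec;
      n_bogus(iv, ij) = bog;
    }
  }
  return List::create(_["n_recovered"] = n_recovered, _["n_bogus"] = n_bogus);
}
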