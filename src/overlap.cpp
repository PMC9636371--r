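#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <map>
#include "seqcore.h"

using namespace Rcpp;

// All-vs-all overlap detection from minimizer anchors.
//
// Canonical (w,k)-minimizers are indexed over all reads; for every read pair
// sharing anchors on a consistent strand, anchors are clustered by diagonal
// (gap tolerance 300 bp) and a cluster with >= min_chain anchors yields one
// overlap record spanning the clustered anchors. Symmetric duplicates are
// collapsed by only pairing a read with higher-indexed reads.

namespace {

struct Mini { uint64_t h; int pos; uint8_t strand; };

// canonical minimizers of one sequence
std::vector<Mini> minimizers(const std::vector<uint8_t>& s, int k, int w) {
  std::vector<Mini> out;
  const int n = (int)s.size();
  if (n < k) return out;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  const int shift = 2 * (k - 1);
  std::vector<Mini> ring;          // hashes of k-mers ending at each pos
  ring.reserve(n);
  for (int i = 0; i < n; ++i) {
    fwd = ((fwd << 2) | s[i]) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - s[i]) << shift);
    if (i >= k - 1) {
      if (fwd == rev) { ring.push_back({UINT64_MAX, i - k + 1, 0}); continue; }
      uint8_t str = fwd < rev ? 0 : 1;
      ring.push_back({hash64(str ? rev : fwd), i - k + 1, str});
    }
  }
  const int nk = (int)ring.size();
  int prev_sel = -1;
  for (int start = 0; start + w <= nk; ++start) {
    int best = start;
    for (int t = start + 1; t < start + w; ++t)
      if (ring[t].h < ring[best].h) best = t;
    if (best != prev_sel && ring[best].h != UINT64_MAX) {
      out.push_back(ring[best]);
      prev_sel = best;
    }
  }
  return out;
}

struct Hit { int diag, pa, pb; };

} // namespace

// [[Rcpp::export(name = ".cpp_all_overlaps")]]
DataFrame cpp_all_overlaps(CharacterVector seqs, int k = 15, int w = 5,
                           int min_chain = 4, int max_occ = 500,
                           int diag_gap = 300) {
  const int nr = seqs.size();
  std::vector<std::vector<uint8_t>> enc(nr);
  std::vector<std::vector<Mini>> mins(nr);
  for (int i = 0; i < nr; ++i) {
    enc[i] = enc_seq(as<std::string>(seqs[i]));
    mins[i] = minimizers(enc[i], k, w);
  }
  // postings: hash -> packed (read, pos, strand)
  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  index.reserve(1 << 20);
  for (int i = 0; i < nr; ++i)
    for (const Mini& mz : mins[i])
      index[mz.h].push_back(((uint64_t)i << 33) | ((uint64_t)mz.pos << 1) | mz.strand);

  std::vector<int> o_q, o_t, o_qs, o_qe, o_ts, o_te, o_nm, o_bl;
  std::vector<std::string> o_strand;

  for (int a = 0; a < nr; ++a) {
    // bucket hits by (other read, relative strand); std::map for determinism
    std::map<uint64_t, std::vector<Hit>> buckets;
    for (const Mini& mz : mins[a]) {
      auto it = index.find(mz.h);
      if (it == index.end() || (int)it->second.size() > max_occ) continue;
      for (uint64_t packed : it->second) {
        int b = (int)(packed >> 33);
        if (b <= a) continue;
        int pb = (int)((packed >> 1) & 0xffffffffULL);
        uint8_t sb = packed & 1;
        int rel = (mz.strand == sb) ? 0 : 1;
        int diag = rel == 0 ? mz.pos - pb : mz.pos + pb;
        buckets[((uint64_t)b << 1) | rel].push_back({diag, mz.pos, pb});
      }
    }
    for (auto& kv : buckets) {
      int b = (int)(kv.first >> 1);
      int rel = (int)(kv.first & 1);
      std::vector<Hit>& hs = kv.second;
      if ((int)hs.size() < min_chain) continue;
      std::sort(hs.begin(), hs.end(), [](const Hit& x, const Hit& y) {
        return x.diag != y.diag ? x.diag < y.diag
                                : (x.pa != y.pa ? x.pa < y.pa : x.pb < y.pb);
      });
      // best run of diagonals with consecutive gaps <= diag_gap
      int bs = -1, be = -1, cs = 0;
      for (int i2 = 1; i2 <= (int)hs.size(); ++i2) {
        if (i2 == (int)hs.size() || hs[i2].diag - hs[i2 - 1].diag > diag_gap) {
          if (i2 - cs > be - bs) { bs = cs; be = i2; }
          cs = i2;
        }
      }
      if (be - bs < min_chain) continue;
      // anchor span and approximate match count (collapse overlapping k-mers)
      std::vector<std::pair<int, int>> anc;  // (pa, pb)
      anc.reserve(be - bs);
      for (int i2 = bs; i2 < be; ++i2) anc.push_back({hs[i2].pa, hs[i2].pb});
      std::sort(anc.begin(), anc.end());
      anc.erase(std::unique(anc.begin(), anc.end()), anc.end());
      if ((int)anc.size() < min_chain) continue;
      int qs = anc.front().first, qe = anc.back().first + k;
      int ts = anc.front().second, te = anc.front().second;
      int nm = k;
      for (size_t i2 = 1; i2 < anc.size(); ++i2) {
        nm += std::min(k, anc[i2].first - anc[i2 - 1].first);
        ts = std::min(ts, anc[i2].second);
        te = std::max(te, anc[i2].second);
      }
      te += k;
      int bl = std::max(qe - qs, te - ts);
      o_q.push_back(a + 1); o_t.push_back(b + 1);
      o_qs.push_back(qs); o_qe.push_back(qe);
      o_ts.push_back(ts); o_te.push_back(te);
      o_nm.push_back(nm); o_bl.push_back(bl);
      o_strand.push_back(rel == 0 ? "+" : "-");
    }
  }
  return DataFrame::create(_["qidx"] = o_q, _["tidx"] = o_t,
                           _["qstart"] = o_qs, _["qend"] = o_qe,
                           _["strand"] = o_strand,
                           _["tstart"] = o_ts, _["tend"] = o_te,
                           _["nmatch"] = o_nm, _["blocklen"] = o_bl,
                           _["stringsAsFactors"] = false);
}
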