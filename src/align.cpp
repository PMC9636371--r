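#include <Rcpp.h>
#include <climits>
#include <algorithm>
#include "seqcore.h"

using namespace Rcpp;

// Banded global edit-distance alignment with traceback.
//
// Rows j = 0..m index prefixes of the query q, columns i = 0..n prefixes of
// the target t. The band is centred on the rescaled diagonal i ~ j*n/m. The
// band starts narrow and doubles whenever the optimal path touches a band
// boundary (or the final cell is unreachable), up to a cap expressed as a
// fraction of the longer sequence, after which a full DP is used.

namespace {

const int BIG = INT_MAX / 4;

struct EditResult {
  bool ok;            // band did not clip the optimal path
  int dist;
  int nmatch, nmis, nins, ndel, ncols;
  std::vector<int> colmap;  // per query pos: 0-based target pos or -1 (ins)
};

// moves: 0 none/origin, 1 diag, 2 up (insertion: consume q only),
//        3 left (deletion: consume t only)
EditResult edit_band(const std::vector<uint8_t>& t, const std::vector<uint8_t>& q,
                     int W, bool free_t_ends, int diag_off,
                     int* t_start_out, int* t_end_out,
                     std::vector<int>* rpos_out, std::vector<int>* qpos_out,
                     std::vector<uint8_t>* rmatch_out) {
  const int n = (int)t.size(), m = (int)q.size();
  EditResult res;
  res.ok = true;
  res.nmatch = res.nmis = res.nins = res.ndel = res.ncols = 0;
  res.colmap.assign(m, -1);
  if (m == 0) {
    res.dist = free_t_ends ? 0 : n;
    if (t_start_out) *t_start_out = 0;
    if (t_end_out) *t_end_out = 0;
    return res;
  }

  // band limits per row
  std::vector<int> lo(m + 1), hi(m + 1);
  for (int j = 0; j <= m; ++j) {
    double c = free_t_ends ? (double)j + diag_off : (double)j * n / m;
    int ic = (int)(c + 0.5);
    lo[j] = std::max(0, ic - W);
    hi[j] = std::min(n, ic + W);
    if (lo[j] > hi[j]) { lo[j] = std::max(0, std::min(lo[j], n)); hi[j] = lo[j]; }
  }
  const int bw = std::min(2 * W, n) + 3;
  // full score matrix (moves are reconstructed during traceback);
  // inner sweeps are branch-free min() updates so they vectorise
  std::vector<int> D((size_t)(m + 1) * bw, BIG);
  std::vector<int> buf(bw + 2);

  int* row0 = &D[0];
  for (int i = lo[0]; i <= hi[0]; ++i)
    row0[i - lo[0]] = free_t_ends ? 0 : i;

  for (int j = 1; j <= m; ++j) {
    const int* prev = &D[(size_t)(j - 1) * bw];
    int* cur = &D[(size_t)j * bw];
    // stage prev row aligned to this row's band with sentinels:
    // buf[x] = prev value at i = lo[j] - 1 + x
    const int width = hi[j] - lo[j] + 1;
    for (int x = 0; x < width + 2; ++x) {
      int i = lo[j] - 1 + x;
      buf[x] = (i >= lo[j - 1] && i <= hi[j - 1]) ? prev[i - lo[j - 1]] : BIG;
    }
    const uint8_t qc = q[j - 1];
    const uint8_t* tj = t.data() + lo[j];   // t[i-1] for i = lo[j] + x is tj[x-1]
    int x0 = 0;
    if (lo[j] == 0) { cur[0] = j; x0 = 1; }
    for (int x = x0; x < width; ++x) {
      const int diag = buf[x] + (tj[x - 1] == qc ? 0 : 1);
      cur[x] = std::min(diag, buf[x + 1] + 1);
    }
    if (x0 == 0 && width > 0) cur[0] = std::min(cur[0], buf[1] + 1);
    for (int x = std::max(1, x0); x < width; ++x)
      cur[x] = std::min(cur[x], cur[x - 1] + 1);
  }

  // end cell
  const int* last = &D[(size_t)m * bw];
  int iend = n, dend = BIG;
  if (free_t_ends) {
    for (int i = lo[m]; i <= hi[m]; ++i) {
      int d = last[i - lo[m]];
      if (d < dend) { dend = d; iend = i; }
    }
  } else {
    if (n >= lo[m] && n <= hi[m]) dend = last[n - lo[m]];
  }
  if (dend >= BIG) { res.ok = false; return res; }
  res.dist = dend;

  // traceback; candidate order (diag, up, left) mirrors the forward min
  auto dval = [&](int j, int i) -> int {
    if (i < lo[j] || i > hi[j]) return BIG;
    return D[(size_t)j * bw + (i - lo[j])];
  };
  int i = iend, j = m;
  bool touched = false;
  while (j > 0) {
    if ((i == lo[j] && lo[j] > 0) || (i == hi[j] && hi[j] < n)) touched = true;
    const int val = dval(j, i);
    if (i > 0 && dval(j - 1, i - 1) + (t[i - 1] == q[j - 1] ? 0 : 1) == val) {
      bool ism = (t[i - 1] == q[j - 1]);
      if (ism) res.nmatch++; else res.nmis++;
      res.ncols++;
      res.colmap[j - 1] = i - 1;
      if (rpos_out) { rpos_out->push_back(i - 1); qpos_out->push_back(j - 1);
                      rmatch_out->push_back(ism ? 1 : 0); }
      --i; --j;
    } else if (dval(j - 1, i) + 1 == val) {
      res.nins++; res.ncols++; --j;
    } else if (i > 0 && dval(j, i - 1) + 1 == val) {
      res.ndel++; res.ncols++; --i;
    } else if (i == 0 && val == j) {        // leading insertions column
      res.nins++; res.ncols++; --j;
    } else {
      res.ok = false; return res;
    }
  }
  if (!free_t_ends) {
    // leading target deletions outside traceback loop
    res.ndel += i; res.ncols += i;
    i = 0;
  }
  if (t_start_out) *t_start_out = i;
  if (t_end_out) *t_end_out = iend;
  if (touched) res.ok = false;
  return res;
}

EditResult edit_adaptive(const std::vector<uint8_t>& t, const std::vector<uint8_t>& q,
                         int band0, double band_frac,
                         bool free_t_ends, int diag_off,
                         int* ts, int* te,
                         std::vector<int>* rp = nullptr, std::vector<int>* qp = nullptr,
                         std::vector<uint8_t>* rm = nullptr) {
  int L = std::max((int)t.size(), (int)q.size());
  int cap = std::max(band0, (int)(band_frac * L));
  int W = std::min(band0, cap);
  for (;;) {
    if (rp) { rp->clear(); qp->clear(); rm->clear(); }
    EditResult r = edit_band(t, q, W, free_t_ends, diag_off, ts, te, rp, qp, rm);
    if (r.ok || W >= L) return r;
    if (W >= cap) W = L;           // full DP as last resort
    else W = std::min(2 * W, cap);
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_edit_align")]]
List cpp_edit_align(std::string target, std::string query,
                    int band0 = 64, double band_frac = 0.15) {
  std::vector<uint8_t> t = enc_seq(target), q = enc_seq(query);
  EditResult r = edit_adaptive(t, q, band0, band_frac, false, 0, nullptr, nullptr);
  IntegerVector cm(q.size());
  for (size_t i = 0; i < q.size(); ++i) cm[i] = r.colmap[i];
  return List::create(_["dist"] = r.dist, _["nmatch"] = r.nmatch,
                      _["nmismatch"] = r.nmis, _["nins"] = r.nins,
                      _["ndel"] = r.ndel, _["ncols"] = r.ncols,
                      _["colmap"] = cm);
}

// Locate `query` on `ref` by exact k-mer seeding, then align the located
// region with free ends on the reference (end-to-end in the query).
// Used by the read-vs-truth evaluator and the ANI measurement.
// [[Rcpp::export(name = ".cpp_map_align")]]
List cpp_map_align(std::string ref, std::string query, int k = 13,
                   int band0 = 64, bool pairs = false) {
  std::vector<uint8_t> r = enc_seq(ref), q = enc_seq(query);
  const int n = (int)r.size(), m = (int)q.size();
  if (m < k || n < k)
    return List::create(_["ok"] = false);

  // index query k-mers
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(m * 2);
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int j = 0; j < m; ++j) {
    kmer = ((kmer << 2) | q[j]) & mask;
    if (j >= k - 1) {
      auto& v = idx[kmer];
      if ((int)v.size() < 8) v.push_back(j - k + 1);
    }
  }
  // scan reference, collect seed diagonals
  std::vector<int> diags;
  kmer = 0;
  for (int i = 0; i < n; ++i) {
    kmer = ((kmer << 2) | r[i]) & mask;
    if (i >= k - 1) {
      auto it = idx.find(kmer);
      if (it != idx.end())
        for (int jp : it->second) diags.push_back((i - k + 1) - jp);
    }
  }
  if (diags.empty()) return List::create(_["ok"] = false);
  std::sort(diags.begin(), diags.end());
  // densest window of diagonals within +-300
  int best_cnt = 0, best_at = 0;
  for (int a = 0, b = 0; a < (int)diags.size(); ++a) {
    while (diags[a] - diags[b] > 600) ++b;
    if (a - b + 1 > best_cnt) { best_cnt = a - b + 1; best_at = (a + b) / 2; }
  }
  int dmid = diags[best_at];
  int pad = 600 + band0;
  int rs = std::max(0, dmid - pad);
  int re = std::min(n, dmid + m + pad);
  std::vector<uint8_t> slice(r.begin() + rs, r.begin() + re);

  int ts = 0, te = 0;
  std::vector<int> rp, qp; std::vector<uint8_t> rm;
  EditResult e = edit_adaptive(slice, q, band0, 1.0, true, dmid - rs, &ts, &te,
                               pairs ? &rp : nullptr, pairs ? &qp : nullptr,
                               pairs ? &rm : nullptr);
  List out = List::create(_["ok"] = true, _["dist"] = e.dist,
                          _["ref_start"] = rs + ts, _["ref_end"] = rs + te,
                          _["nmatch"] = e.nmatch, _["nmismatch"] = e.nmis,
                          _["nins"] = e.nins, _["ndel"] = e.ndel,
                          _["ncols"] = e.ncols, _["nseeds"] = (int)diags.size());
  if (pairs) {
    int np = (int)rp.size();
    IntegerVector rpv(np), qpv(np); LogicalVector rmv(np);
    for (int a = 0; a < np; ++a) {       // traceback order is reversed
      rpv[np - 1 - a] = rp[a] + rs; qpv[np - 1 - a] = qp[a];
      rmv[np - 1 - a] = rm[a] != 0;
    }
    out["pair_ref"] = rpv; out["pair_query"] = qpv; out["pair_match"] = rmv;
  }
  return out;
}
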