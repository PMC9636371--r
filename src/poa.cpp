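#include <Rcpp.h>
#include <climits>
#include <algorithm>
#include <queue>
#include "seqcore.h"

using namespace Rcpp;

// Partial-order-alignment variation graph engine.
//
// Nodes are single nucleotides; per-read paths are walks in the DAG. The
// first sequence inserted (the target subread) forms the linear backbone;
// subsequent sequences are aligned to the graph (banded semi-global DP over
// the topological order: free leading/trailing graph nodes, the sequence is
// consumed end to end) and fused: matches reuse nodes, mismatches and
// insertions create nodes, deletions induce skip edges.
//
// Edge statistics follow the frequent-itemset view: w(v) = sum over reads
// consuming v of (1 - p_{r,v}); w(e) = sum over reads traversing e of
// (1 - p_i/2 - p_j/2); Support(e) = w(e); Confidence(e) is the maximum of
// w(e) over the out-weight of its source and over the in-weight of its sink.

namespace {

const int NEG = INT_MIN / 4;

struct Scoring { int match, mismatch, gap; };

struct AlnOut {
  bool ok = false, touched = false;
  long score = 0;
  std::vector<int> wnode;        // walk nodes (consumed and deleted)
  std::vector<int> wqpos;        // query pos consumed at node, -1 if deleted
  std::vector<char> wop;         // 'M','X','D'
  std::vector<int> ins_qpos;     // query positions aligned as insertions
};

struct POA {
  std::vector<uint8_t> base;
  std::vector<int> rank;
  std::vector<char> nalive;
  std::vector<int> efrom, eto;
  std::vector<char> ealive;
  std::vector<std::vector<std::pair<int, int>>> out_, in_;  // (node, edge id)

  std::vector<std::string> pid;
  std::vector<std::vector<int>> pwalk;
  std::vector<std::vector<char>> pcons;     // consumed flag per walk step
  std::vector<std::vector<double>> pprob;   // prob per walk step (deleted: inherited)
  bool has_probs = false;

  // originals, for realignment
  std::vector<std::vector<uint8_t>> pseq;
  std::vector<std::vector<double>> pseqprob;
  std::vector<int> poffset;

  std::vector<int> topo, topo_pos;
  bool topo_dirty = true;

  // DP scratch buffers, reused across alignments
  std::vector<int> S_, lo_, hi_;
  std::vector<size_t> off_;

  int n_alive_nodes() const {
    int c = 0;
    for (char a : nalive) c += a != 0;
    return c;
  }

  int new_node(uint8_t b, int rk) {
    base.push_back(b); rank.push_back(rk); nalive.push_back(1);
    out_.emplace_back(); in_.emplace_back();
    topo_dirty = true;
    return (int)base.size() - 1;
  }

  int find_alive_edge(int u, int v) const {
    for (auto& p : out_[u])
      if (p.first == v && ealive[p.second]) return p.second;
    return -1;
  }

  int ensure_edge(int u, int v) {
    int e = find_alive_edge(u, v);
    if (e >= 0) return e;
    e = (int)efrom.size();
    efrom.push_back(u); eto.push_back(v); ealive.push_back(1);
    out_[u].push_back({v, e}); in_[v].push_back({u, e});
    topo_dirty = true;
    return e;
  }

  void compute_topo() {
    int n = (int)base.size();
    std::vector<int> indeg(n, 0);
    for (size_t e = 0; e < efrom.size(); ++e)
      if (ealive[e] && nalive[efrom[e]] && nalive[eto[e]]) indeg[eto[e]]++;
    std::priority_queue<int, std::vector<int>, std::greater<int>> pq;
    for (int v = 0; v < n; ++v)
      if (nalive[v] && indeg[v] == 0) pq.push(v);
    topo.clear(); topo.reserve(n);
    topo_pos.assign(n, -1);
    while (!pq.empty()) {
      int v = pq.top(); pq.pop();
      topo_pos[v] = (int)topo.size();
      topo.push_back(v);
      for (auto& p : out_[v])
        if (ealive[p.second] && nalive[p.first] && --indeg[p.first] == 0)
          pq.push(p.first);
    }
    if ((int)topo.size() != n_alive_nodes())
      stop("variation graph contains a cycle");
    topo_dirty = false;
  }

  // banded semi-global sequence-to-graph alignment
  AlnOut align_band(const std::vector<uint8_t>& q, const Scoring& sc,
                    int offset, int W, bool full) {
    AlnOut res;
    if (topo_dirty) compute_topo();
    const int m = (int)q.size();
    const int T = (int)topo.size();
    if (T == 0 || m == 0) { res.ok = true; res.score = 0; return res; }

    lo_.resize(T); hi_.resize(T); off_.resize(T);
    std::vector<int>& lo = lo_; std::vector<int>& hi = hi_;
    std::vector<size_t>& off = off_;
    size_t total = 0;
    for (int t = 0; t < T; ++t) {
      if (full) { lo[t] = 1; hi[t] = m; }
      else {
        int c = rank[topo[t]] - offset + 1;
        lo[t] = std::max(1, c - W); hi[t] = std::min(m, c + W);
      }
      off[t] = total;
      if (hi[t] >= lo[t]) total += (size_t)(hi[t] - lo[t] + 1);
    }
    S_.resize(total);
    std::vector<int>& S = S_;

    // score-only DP; moves are reconstructed during traceback (candidate
    // evaluation order there must mirror the order here: start, then
    // consume/delete per predecessor in in_ order, then insert).
    // Inner sweeps are branch-free max() updates so they vectorise.
    std::vector<int> subv;
    for (int t = 0; t < T; ++t) {
      const int v = topo[t];
      if (hi[t] < lo[t]) continue;
      const int vlo = lo[t], vhi = hi[t];
      const int w = vhi - vlo + 1;
      int* row = &S[off[t]];
      const uint8_t vb = base[v];
      subv.resize(w);
      for (int x = 0; x < w; ++x)
        subv[x] = (vb == q[vlo + x - 1]) ? sc.match : sc.mismatch;
      // start-anywhere initialisation (leading sequence chars as insertions)
      for (int x = 0; x < w; ++x)
        row[x] = (vlo + x - 1) * sc.gap + subv[x];
      // per-predecessor sweeps (consume and delete moves)
      for (auto& p : in_[v]) {
        if (!ealive[p.second] || !nalive[p.first]) continue;
        const int ut = topo_pos[p.first];
        if (ut < 0 || hi[ut] < lo[ut]) continue;
        const int* urow = &S[off[ut]];
        const int ulo = lo[ut], uhi = hi[ut];
        {
          const int a = std::max(vlo, ulo + 1), b = std::min(vhi, uhi + 1);
          const int* up = urow + (a - 1 - ulo);
          int* rp = row + (a - vlo);
          const int* sp = subv.data() + (a - vlo);
          for (int x = 0; x <= b - a; ++x)
            rp[x] = std::max(rp[x], up[x] + sp[x]);
        }
        {
          const int a = std::max(vlo, ulo), b = std::min(vhi, uhi);
          const int* up = urow + (a - ulo);
          int* rp = row + (a - vlo);
          for (int x = 0; x <= b - a; ++x)
            rp[x] = std::max(rp[x], up[x] + sc.gap);
        }
      }
      // sequential insertion pass within the row
      for (int x = 1; x < w; ++x)
        row[x] = std::max(row[x], row[x - 1] + sc.gap);
    }

    // best end cell at j = m (trailing graph nodes are free); ties prefer
    // the later topological position, i.e. the longest co-optimal walk
    int bv = -1; long bs = NEG;
    for (int t = 0; t < T; ++t) {
      if (m < lo[t] || m > hi[t]) continue;
      long s = S[off[t] + (m - lo[t])];
      if (s >= bs) { bs = s; bv = topo[t]; }
    }
    if (bv < 0) { res.ok = false; return res; }
    res.score = bs;

    // traceback; candidate evaluation order mirrors the forward pass
    int v = bv, j = m;
    for (;;) {
      const int t = topo_pos[v];
      if ((j == lo[t] && lo[t] > 1) || (j == hi[t] && hi[t] < m))
        res.touched = true;
      const int val = S[off[t] + (j - lo[t])];
      const int sub = (base[v] == q[j - 1]) ? sc.match : sc.mismatch;
      // co-optimal candidates are taken in an order that prefers the
      // longest walk: predecessors first, then insertion, "start here" last
      int nxt = -1, mvty = 0;
      for (auto& p : in_[v]) {
        if (!ealive[p.second] || !nalive[p.first]) continue;
        const int ut = topo_pos[p.first];
        if (ut < 0 || hi[ut] < lo[ut]) continue;
        if (j - 1 >= lo[ut] && j - 1 <= hi[ut] &&
            S[off[ut] + (j - 1 - lo[ut])] + sub == val) {
          mvty = 1; nxt = p.first; break;
        }
        if (j >= lo[ut] && j <= hi[ut] &&
            S[off[ut] + (j - lo[ut])] + sc.gap == val) {
          mvty = 3; nxt = p.first; break;
        }
      }
      if (mvty == 1) {
        res.wnode.push_back(v); res.wqpos.push_back(j - 1);
        res.wop.push_back(base[v] == q[j - 1] ? 'M' : 'X');
        v = nxt; --j; continue;
      }
      if (mvty == 3) {
        res.wnode.push_back(v); res.wqpos.push_back(-1); res.wop.push_back('D');
        v = nxt; continue;
      }
      if (j - 1 >= lo[t] && S[off[t] + (j - 1 - lo[t])] + sc.gap == val) {
        res.ins_qpos.push_back(j - 1); --j; continue;
      }
      if (val == (j - 1) * sc.gap + sub) {          // walk starts here
        res.wnode.push_back(v); res.wqpos.push_back(j - 1);
        res.wop.push_back(base[v] == q[j - 1] ? 'M' : 'X');
        break;
      }
      res.ok = false; return res;    // inconsistent matrix; widen the band
    }
    std::reverse(res.wnode.begin(), res.wnode.end());
    std::reverse(res.wqpos.begin(), res.wqpos.end());
    std::reverse(res.wop.begin(), res.wop.end());
    std::reverse(res.ins_qpos.begin(), res.ins_qpos.end());
    res.ok = !res.touched;
    return res;
  }

  AlnOut align(const std::vector<uint8_t>& q, const Scoring& sc,
               int offset, int W0) {
    if (topo_dirty) compute_topo();
    int m = (int)q.size();
    int rlo = INT_MAX, rhi = INT_MIN;
    for (int v : topo) { rlo = std::min(rlo, rank[v]); rhi = std::max(rhi, rank[v]); }
    int cap = m + std::max(0, rhi - rlo + 1);
    int W = W0;
    for (;;) {
      bool full = W >= cap;
      AlnOut r = align_band(q, sc, offset, W, full);
      if (r.ok || full) { r.ok = true; return r; }
      W *= 2;
    }
  }

  // record a walk as path i (replacing if i < npaths)
  void set_path(int i, const std::string& id, const AlnOut& a,
                const std::vector<double>& seqprob) {
    std::vector<char> cons(a.wnode.size());
    std::vector<double> pr(a.wnode.size(), 0.0);
    double last = 0.0;
    for (size_t s = 0; s < a.wnode.size(); ++s) {
      cons[s] = a.wqpos[s] >= 0;
      if (cons[s]) {
        last = seqprob.empty() ? 0.0 : seqprob[a.wqpos[s]];
        pr[s] = last;
      } else pr[s] = last;
    }
    if (i == (int)pid.size()) {
      pid.push_back(id); pwalk.push_back(a.wnode);
      pcons.push_back(cons); pprob.push_back(pr);
    } else {
      pid[i] = id; pwalk[i] = a.wnode; pcons[i] = cons; pprob[i] = pr;
    }
  }

  // fuse one sequence into the graph (build phase)
  void insert_seq(const std::string& id, const std::vector<uint8_t>& q,
                  const std::vector<double>& seqprob, int offset,
                  const Scoring& sc, int W0) {
    const int m = (int)q.size();
    std::vector<int> path; path.reserve(m);
    if (n_alive_nodes() == 0) {
      int prev = -1;
      for (int j = 0; j < m; ++j) {
        int v = new_node(q[j], offset + j);
        if (prev >= 0) ensure_edge(prev, v);
        prev = v; path.push_back(v);
      }
    } else {
      AlnOut a = align(q, sc, offset, W0);
      // consumed entries in query order
      std::vector<std::pair<int, int>> consumed;  // (qpos, node), match flag via base cmp
      std::vector<char> ismatch;
      for (size_t s = 0; s < a.wnode.size(); ++s)
        if (a.wqpos[s] >= 0) {
          consumed.push_back({a.wqpos[s], a.wnode[s]});
          ismatch.push_back(a.wop[s] == 'M');
        }
      int ci = 0, prev = -1;
      for (int j = 0; j < m; ++j) {
        int v;
        if (ci < (int)consumed.size() && consumed[ci].first == j) {
          int gv = consumed[ci].second;
          v = ismatch[ci] ? gv : new_node(q[j], rank[gv]);
          ++ci;
        } else {
          v = new_node(q[j], prev >= 0 ? rank[prev] + 1 : offset + j);
        }
        if (prev >= 0) ensure_edge(prev, v);
        prev = v; path.push_back(v);
      }
    }
    AlnOut fake; fake.wnode = path;
    fake.wqpos.resize(path.size()); fake.wop.assign(path.size(), 'M');
    for (size_t s = 0; s < path.size(); ++s) fake.wqpos[s] = (int)s;
    set_path((int)pid.size(), id, fake, seqprob);
    pseq.push_back(q); pseqprob.push_back(seqprob); poffset.push_back(offset);
    if (!seqprob.empty()) has_probs = true;
  }

  struct Stats {
    std::vector<double> nw, ew, conf_f, conf_b;
    std::vector<int> ncov, ecov;
    double C = 0;
  };

  Stats compute_stats(double L) const {
    Stats st;
    st.nw.assign(base.size(), 0.0); st.ncov.assign(base.size(), 0);
    st.ew.assign(efrom.size(), 0.0); st.ecov.assign(efrom.size(), 0);
    for (size_t i = 0; i < pwalk.size(); ++i) {
      const auto& wk = pwalk[i];
      double pprev = 0.0;
      for (size_t s = 0; s < wk.size(); ++s) {
        int v = wk[s];
        double p = pprob[i].empty() ? 0.0 : pprob[i][s];
        if (!nalive[v]) { pprev = p; continue; }
        if (pcons[i][s]) { st.nw[v] += 1.0 - p; st.ncov[v]++; }
        if (s > 0 && nalive[wk[s - 1]]) {
          int e = find_alive_edge(wk[s - 1], v);
          if (e >= 0) { st.ew[e] += 1.0 - 0.5 * pprev - 0.5 * p; st.ecov[e]++; }
        }
        pprev = p;
      }
    }
    std::vector<double> outsum(base.size(), 0.0), insum(base.size(), 0.0);
    for (size_t e = 0; e < efrom.size(); ++e) {
      if (!ealive[e]) continue;
      outsum[efrom[e]] += st.ew[e];
      insum[eto[e]] += st.ew[e];
    }
    st.conf_f.assign(efrom.size(), 0.0); st.conf_b.assign(efrom.size(), 0.0);
    for (size_t e = 0; e < efrom.size(); ++e) {
      if (!ealive[e]) continue;
      st.conf_f[e] = outsum[efrom[e]] > 0 ? st.ew[e] / outsum[efrom[e]] : 0.0;
      st.conf_b[e] = insum[eto[e]] > 0 ? st.ew[e] / insum[eto[e]] : 0.0;
    }
    double tot = 0;
    for (size_t v = 0; v < base.size(); ++v) if (nalive[v]) tot += st.nw[v];
    st.C = L > 0 ? tot / L : 0.0;
    return st;
  }

  // one prune round; returns number of removed edges
  int prune_once(double c, double s_factor, double L,
                 std::vector<int>* rme = nullptr, std::vector<int>* rmn = nullptr) {
    Stats st = compute_stats(L);
    double s = s_factor * st.C;
    int removed = 0;
    for (size_t e = 0; e < efrom.size(); ++e) {
      if (!ealive[e]) continue;
      double conf = std::max(st.conf_f[e], st.conf_b[e]);
      if (st.ew[e] < s || conf < c) {
        ealive[e] = 0; ++removed;
        if (rme) rme->push_back((int)e);
      }
    }
    if (removed > 0) {
      std::vector<int> deg(base.size(), 0);
      for (size_t e = 0; e < efrom.size(); ++e)
        if (ealive[e]) { deg[efrom[e]]++; deg[eto[e]]++; }
      for (size_t v = 0; v < base.size(); ++v)
        if (nalive[v] && deg[v] == 0) {
          nalive[v] = 0;
          if (rmn) rmn->push_back((int)v);
        }
      topo_dirty = true;
    }
    return removed;
  }

  bool path_intact(int i) const {
    const auto& wk = pwalk[i];
    for (size_t s = 0; s < wk.size(); ++s) {
      if (!nalive[wk[s]]) return false;
      if (s > 0 && find_alive_edge(wk[s - 1], wk[s]) < 0) return false;
    }
    return true;
  }

  void realign_all(const Scoring& sc, int W0) {
    if (n_alive_nodes() == 0) {
      for (size_t i = 0; i < pwalk.size(); ++i) {
        AlnOut empty;
        set_path((int)i, pid[i], empty, pseqprob[i]);
      }
      return;
    }
    for (size_t i = 0; i < pwalk.size(); ++i) {
      if (path_intact((int)i)) continue;
      AlnOut a = align(pseq[i], sc, poffset[i], W0);
      set_path((int)i, pid[i], a, pseqprob[i]);
    }
  }

  // prune -> realign cycle; realignment never modifies the graph
  IntegerVector prune_iterative(const Scoring& sc, int W0,
                                double c, double s_factor, double L, int iters) {
    IntegerVector removed_per_iter(iters, 0);
    for (int it = 0; it < iters; ++it) {
      int removed = prune_once(c, s_factor, L);
      removed_per_iter[it] = removed;
      if (removed == 0) break;
      realign_all(sc, W0);
    }
    return removed_per_iter;
  }

  // complete a walk to the window bounds: extend its ends to a graph
  // source/sink along the heaviest incident edges (deletions of the very
  // first/last window bases would otherwise vanish into the free graph
  // ends of the semi-global alignment)
  void extend_walk(std::vector<int>& walk, const Stats& st) const {
    if (walk.empty()) return;
    for (int guard = 0; guard < 64; ++guard) {
      int v = walk.front();
      int bu = -1; double bw = -1;
      for (auto& p : in_[v]) {
        if (!ealive[p.second] || !nalive[p.first]) continue;
        if (st.ew[p.second] > bw ||
            (st.ew[p.second] == bw && p.first < bu)) {
          bw = st.ew[p.second]; bu = p.first;
        }
      }
      if (bu < 0) break;
      walk.insert(walk.begin(), bu);
    }
    for (int guard = 0; guard < 64; ++guard) {
      int v = walk.back();
      int bu = -1; double bw = -1;
      for (auto& p : out_[v]) {
        if (!ealive[p.second] || !nalive[p.first]) continue;
        if (st.ew[p.second] > bw ||
            (st.ew[p.second] == bw && p.first < bu)) {
          bw = st.ew[p.second]; bu = p.first;
        }
      }
      if (bu < 0) break;
      walk.push_back(bu);
    }
  }

  // maximum-weight source-to-sink path under edge weights w(e)
  std::string heaviest_bundle(double L, std::vector<int>* path_out = nullptr) {
    if (topo_dirty) compute_topo();
    if (topo.empty()) return "";
    Stats st = compute_stats(L);
    std::vector<double> best(base.size(), 0.0);
    std::vector<int> pred(base.size(), -1);
    for (int v : topo) {
      double bw = -1.0; // edge weight of chosen predecessor, for tie-breaks
      for (auto& p : in_[v]) {
        if (!ealive[p.second] || !nalive[p.first]) continue;
        double cand = best[p.first] + st.ew[p.second];
        if (cand > best[v] + 1e-12 ||
            (cand > best[v] - 1e-12 &&
             (st.ew[p.second] > bw + 1e-12 ||
              (st.ew[p.second] > bw - 1e-12 && pred[v] >= 0 && p.first < pred[v])))) {
          if (cand > best[v]) best[v] = cand;
          pred[v] = p.first; bw = st.ew[p.second];
        }
      }
    }
    int vb = topo[0];
    for (int v : topo)
      if (best[v] > best[vb] + 1e-12 || (best[v] > best[vb] - 1e-12 && v < vb)) vb = v;
    std::vector<int> path;
    for (int v = vb; v >= 0; v = pred[v]) path.push_back(v);
    std::reverse(path.begin(), path.end());
    std::string s(path.size(), 'N');
    for (size_t i = 0; i < path.size(); ++i) s[i] = dec_base(base[path[i]]);
    if (path_out) *path_out = path;
    return s;
  }
};

std::vector<double> probs_from_sexp(SEXP p) {
  if (Rf_isNull(p)) return {};
  NumericVector v(p);
  return std::vector<double>(v.begin(), v.end());
}

Scoring scoring_from(List sc) {
  return Scoring{as<int>(sc["match"]), as<int>(sc["mismatch"]), as<int>(sc["gap"])};
}

// serialise: renumber alive nodes 1..n', drop dead entries from paths
List poa_to_list(POA& g) {
  int n = (int)g.base.size();
  std::vector<int> map(n, -1);
  int nn = 0;
  for (int v = 0; v < n; ++v) if (g.nalive[v]) map[v] = nn++;
  CharacterVector bases(nn); IntegerVector ranks(nn);
  for (int v = 0; v < n; ++v)
    if (map[v] >= 0) {
      bases[map[v]] = std::string(1, dec_base(g.base[v]));
      ranks[map[v]] = g.rank[v];
    }
  std::vector<int> ef, et;
  for (size_t e = 0; e < g.efrom.size(); ++e)
    if (g.ealive[e] && map[g.efrom[e]] >= 0 && map[g.eto[e]] >= 0) {
      ef.push_back(map[g.efrom[e]] + 1); et.push_back(map[g.eto[e]] + 1);
    }
  int np = (int)g.pid.size();
  List paths(np), cons(np), probs(np);
  CharacterVector ids(np);
  for (int i = 0; i < np; ++i) {
    ids[i] = g.pid[i];
    std::vector<int> wk; std::vector<int> cn; std::vector<double> pb;
    for (size_t s = 0; s < g.pwalk[i].size(); ++s) {
      int v = g.pwalk[i][s];
      if (map[v] < 0) continue;
      wk.push_back(map[v] + 1);
      cn.push_back(g.pcons[i][s] ? 1 : 0);
      pb.push_back(g.pprob[i][s]);
    }
    paths[i] = wrap(wk); cons[i] = LogicalVector(cn.begin(), cn.end());
    probs[i] = wrap(pb);
  }
  return List::create(_["bases"] = bases, _["ranks"] = ranks,
                      _["edge_from"] = wrap(ef), _["edge_to"] = wrap(et),
                      _["path_ids"] = ids, _["paths"] = paths,
                      _["path_consumed"] = cons,
                      _["path_probs"] = g.has_probs ? (SEXP)probs : R_NilValue);
}

POA poa_from_list(List gl) {
  POA g;
  CharacterVector bases = gl["bases"];
  IntegerVector ranks = gl["ranks"];
  for (int v = 0; v < bases.size(); ++v)
    g.new_node(enc_base(as<std::string>(bases[v])[0]), ranks[v]);
  IntegerVector ef = gl["edge_from"], et = gl["edge_to"];
  for (int e = 0; e < ef.size(); ++e) g.ensure_edge(ef[e] - 1, et[e] - 1);
  CharacterVector ids = gl["path_ids"];
  List paths = gl["paths"], cons = gl["path_consumed"];
  bool hp = !Rf_isNull(gl["path_probs"]);
  List probs;
  if (hp) { probs = List(gl["path_probs"]); g.has_probs = true; }
  for (int i = 0; i < ids.size(); ++i) {
    IntegerVector wk = paths[i];
    LogicalVector cn = cons[i];
    std::vector<int> w(wk.size());
    std::vector<char> c(wk.size());
    std::vector<double> pb(wk.size(), 0.0);
    if (hp) {
      NumericVector pv = probs[i];
      for (int s = 0; s < pv.size(); ++s) pb[s] = pv[s];
    }
    for (int s = 0; s < wk.size(); ++s) { w[s] = wk[s] - 1; c[s] = cn[s] ? 1 : 0; }
    g.pid.push_back(as<std::string>(ids[i]));
    g.pwalk.push_back(w); g.pcons.push_back(c); g.pprob.push_back(pb);
    // original sequences are unknown here; reconstruct the consumed spelling
    std::vector<uint8_t> sq;
    std::vector<double> sp;
    for (size_t s = 0; s < w.size(); ++s)
      if (c[s]) { sq.push_back(g.base[w[s]]); sp.push_back(pb[s]); }
    g.pseq.push_back(sq);
    g.pseqprob.push_back(hp ? sp : std::vector<double>());
    g.poffset.push_back(w.empty() ? 0 : g.rank[w[0]]);
  }
  return g;
}

void build_from_inputs(POA& g, CharacterVector ids, CharacterVector seqs,
                       SEXP probs, IntegerVector offsets, const Scoring& sc,
                       int W0) {
  List pl;
  bool hp = !Rf_isNull(probs);
  if (hp) pl = List(probs);
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s.empty()) { Rf_warning("skipping empty sequence '%s'",
                                as<std::string>(ids[i]).c_str()); continue; }
    std::vector<double> pr = hp ? probs_from_sexp(pl[i]) : std::vector<double>();
    g.insert_seq(as<std::string>(ids[i]), enc_seq(s), pr,
                 offsets.size() > i ? offsets[i] : 0, sc, W0);
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_poa_build")]]
List cpp_poa_build(CharacterVector ids, CharacterVector seqs, SEXP probs,
                   List scoring, IntegerVector offsets, int band = 32) {
  POA g;
  build_from_inputs(g, ids, seqs, probs, offsets, scoring_from(scoring), band);
  return poa_to_list(g);
}

// [[Rcpp::export(name = ".cpp_align_to_graph")]]
List cpp_align_to_graph(List gl, std::string seq, List scoring,
                        int offset = 0, int band = 32) {
  POA g = poa_from_list(gl);
  AlnOut a = g.align(enc_seq(seq), scoring_from(scoring), offset, band);
  int nw = (int)a.wnode.size();
  IntegerVector wn(nw), wq(nw); CharacterVector wo(nw);
  for (int s = 0; s < nw; ++s) {
    wn[s] = a.wnode[s] + 1; wq[s] = a.wqpos[s];
    wo[s] = std::string(1, a.wop[s]);
  }
  return List::create(_["walk"] = wn, _["qpos"] = wq, _["ops"] = wo,
                      _["ins_qpos"] = wrap(a.ins_qpos),
                      _["score"] = (double)a.score);
}

// [[Rcpp::export(name = ".cpp_graph_stats")]]
List cpp_graph_stats(List gl, double L) {
  POA g = poa_from_list(gl);
  POA::Stats st = g.compute_stats(L);
  int ne = (int)g.efrom.size();
  NumericVector ew(ne), cf(ne), cb(ne), conf(ne);
  IntegerVector ec(ne);
  for (int e = 0; e < ne; ++e) {
    ew[e] = st.ew[e]; ec[e] = st.ecov[e];
    cf[e] = st.conf_f[e]; cb[e] = st.conf_b[e];
    conf[e] = std::max(st.conf_f[e], st.conf_b[e]);
  }
  return List::create(_["node_weight"] = wrap(st.nw),
                      _["node_coverage"] = wrap(st.ncov),
                      _["edge_weight"] = ew, _["edge_coverage"] = ec,
                      _["support"] = ew,
                      _["conf_fwd"] = cf, _["conf_bwd"] = cb,
                      _["confidence"] = conf, _["mean_coverage"] = st.C);
}

// [[Rcpp::export(name = ".cpp_prune_once")]]
List cpp_prune_once(List gl, double conf_min, double s_factor, double L) {
  POA g = poa_from_list(gl);
  std::vector<int> rme, rmn;
  POA::Stats st = g.compute_stats(L);
  g.prune_once(conf_min, s_factor, L, &rme, &rmn);
  IntegerVector ef((int)rme.size()), et((int)rme.size());
  for (size_t i = 0; i < rme.size(); ++i) {
    ef[i] = g.efrom[rme[i]] + 1; et[i] = g.eto[rme[i]] + 1;
  }
  IntegerVector rn((int)rmn.size());
  for (size_t i = 0; i < rmn.size(); ++i) rn[i] = rmn[i] + 1;
  return List::create(_["graph"] = poa_to_list(g),
                      _["removed_from"] = ef, _["removed_to"] = et,
                      _["removed_nodes"] = rn,
                      _["support_threshold"] = s_factor * st.C,
                      _["mean_coverage"] = st.C);
}

// [[Rcpp::export(name = ".cpp_prune_iterative")]]
List cpp_prune_iterative(List gl, CharacterVector ids, CharacterVector seqs,
                         SEXP probs, IntegerVector offsets, List scoring,
                         double conf_min, double s_factor, double L, int iters,
                         int band = 32) {
  POA g = poa_from_list(gl);
  // attach original sequences for realignment, matched by path id
  bool hp = !Rf_isNull(probs);
  List pl; if (hp) pl = List(probs);
  for (int i = 0; i < ids.size(); ++i) {
    std::string id = as<std::string>(ids[i]);
    for (size_t k = 0; k < g.pid.size(); ++k)
      if (g.pid[k] == id) {
        g.pseq[k] = enc_seq(as<std::string>(seqs[i]));
        g.pseqprob[k] = hp ? probs_from_sexp(pl[i]) : std::vector<double>();
        g.poffset[k] = offsets.size() > i ? offsets[i] : 0;
      }
  }
  IntegerVector removed = g.prune_iterative(scoring_from(scoring), band,
                                            conf_min, s_factor, L, iters);
  return List::create(_["graph"] = poa_to_list(g),
                      _["removed_per_iter"] = removed);
}

// [[Rcpp::export(name = ".cpp_heaviest_bundle")]]
List cpp_heaviest_bundle(List gl, double L) {
  POA g = poa_from_list(gl);
  std::vector<int> path;
  std::string s = g.heaviest_bundle(L, &path);
  // recompute weight of returned path for reporting
  POA::Stats st = g.compute_stats(L);
  double wt = 0;
  for (size_t i = 1; i < path.size(); ++i) {
    int e = g.find_alive_edge(path[i - 1], path[i]);
    if (e >= 0) wt += st.ew[e];
  }
  IntegerVector pv((int)path.size());
  for (size_t i = 0; i < path.size(); ++i) pv[i] = path[i] + 1;
  return List::create(_["sequence"] = s, _["weight"] = wt, _["path"] = pv);
}

// Fused per-window correction used by the pipeline: build POA, then either
// iterative pruning + target realignment (cycle 1) or heaviest-bundle
// consensus (cycle 2). Calls the same engine routines as the exported
// stepwise functions.
// [[Rcpp::export(name = ".cpp_correct_window")]]
List cpp_correct_window(std::string target, SEXP target_probs,
                        CharacterVector ids, CharacterVector seqs, SEXP probs,
                        IntegerVector offsets, List scoring,
                        double conf_min, double s_factor, int iters,
                        int cycle, int band = 32) {
  Scoring sc = scoring_from(scoring);
  double L = (double)target.size();
  POA g;
  g.insert_seq("@target", enc_seq(target), probs_from_sexp(target_probs), 0,
               sc, band);
  build_from_inputs(g, ids, seqs, probs, offsets, sc, band);

  if (cycle == 2) {
    std::string cons = g.heaviest_bundle(L);
    if (cons.empty())
      return List::create(_["seq"] = target, _["status"] = 2);
    return List::create(_["seq"] = cons, _["status"] = 0);
  }

  g.prune_iterative(sc, band, conf_min, s_factor, L, iters);
  if (g.n_alive_nodes() == 0)
    return List::create(_["seq"] = target, _["status"] = 2);
  AlnOut a = g.align(enc_seq(target), sc, 0, band);
  std::vector<int> walk = a.wnode;
  POA::Stats st = g.compute_stats(L);
  g.extend_walk(walk, st);
  std::string corrected(walk.size(), 'N');
  for (size_t s = 0; s < walk.size(); ++s)
    corrected[s] = dec_base(g.base[walk[s]]);
  return List::create(_["seq"] = corrected, _["status"] = 0);
}

// [[Rcpp::export(name = ".cpp_topo_order")]]
IntegerVector cpp_topo_order(int n, IntegerVector from, IntegerVector to) {
  POA g;
  for (int v = 0; v < n; ++v) g.new_node(0, v);
  for (int e = 0; e < from.size(); ++e) g.ensure_edge(from[e] - 1, to[e] - 1);
  g.compute_topo();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g.topo[i] + 1;
  return out;
}
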