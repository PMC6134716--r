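// Core clustering engine: segment-filter candidate generation, bounded
// verification (edit-distance and affine-scoring mode), and the iterative
// OTU growth loop. All functions operate on plain character vectors; the
// S4 layer in R/ owns the user-facing containers.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cstdlib>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int NEG_BIG = INT_MIN / 4;

// ---------------------------------------------------------------------------
// Even partition: n segments tiling a sequence of length l, segment lengths
// differing by at most 1, the longer segments placed last.
// ---------------------------------------------------------------------------
static void partition_positions(int l, int n, std::vector<int>& starts,
                                std::vector<int>& lens) {
  int base = l / n, rem = l % n;
  starts.resize(n);
  lens.resize(n);
  int pos = 0;
  for (int i = 0; i < n; ++i) {
    int len = base + (i >= n - rem ? 1 : 0);
    starts[i] = pos;
    lens[i] = len;
    pos += len;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_partition(int l, int n) {
  if (n < 1) stop("segment count must be >= 1");
  if (l < n) stop("sequence length %d shorter than segment count %d", l, n);
  std::vector<int> st, ln;
  partition_positions(l, n, st, ln);
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = st[i];
    out(i, 1) = ln[i];
  }
  colnames(out) = CharacterVector::create("start", "length");
  return out;
}

// ---------------------------------------------------------------------------
// Admissible substring start positions in a query S for segment i (0-based)
// of an indexed sequence of length l. For k = 1 this is the multimatch-aware
// window of Pass-Join (tau + 1 segments); for k > 1 the conservative +-tau
// window is used (complete, possibly over-selective is impossible: it is a
// superset of the tight window).
// ---------------------------------------------------------------------------
static void seg_window(int slen, int l, int i0, int p, int li, int tau, int k,
                       int& lo, int& hi) {
  int delta = slen - l;
  if (k == 1) {
    int nseg = tau + 1;
    int i = i0 + 1;  // 1-based segment index
    lo = std::max(p - (i - 1), p + delta - (nseg - i));
    hi = std::min(p + (i - 1), p + delta + (nseg - i));
  } else {
    lo = p - tau;
    hi = p + tau;
  }
  lo = std::max(lo, 0);
  hi = std::min(hi, slen - li);
}

// [[Rcpp::export]]
IntegerVector cpp_select_positions(int slen, int l, int i, int p, int li,
                                   int tau, int k) {
  if (i < 1) stop("segment index must be >= 1");
  int lo, hi;
  seg_window(slen, l, i - 1, p, li, tau, k, lo, hi);
  if (lo > hi) return IntegerVector(0);
  IntegerVector out(hi - lo + 1);
  for (int w = lo; w <= hi; ++w) out[w - lo] = w;
  return out;
}

// ---------------------------------------------------------------------------
// Inverted segment indices I_{l,i}: per sequence length l and segment index
// i, a hash map from segment string to the posting list of amplicon indices.
// Amplicons shorter than the segment count cannot be partitioned and are
// kept in a side list; they are handed to verification directly.
// ---------------------------------------------------------------------------
struct SegIndex {
  int tau, k, nseg;
  std::unordered_map<int,
                     std::vector<std::unordered_map<std::string, std::vector<int> > > >
      idx;
  std::unordered_map<int, std::vector<int> > starts_by_len, lens_by_len;
  std::vector<std::pair<int, int> > short_amps;  // (amplicon index, length)
};

static void build_index(const std::vector<std::string>& seqs, int tau, int k,
                        SegIndex& out) {
  out.tau = tau;
  out.k = k;
  out.nseg = tau + k;
  for (int id = 0; id < (int)seqs.size(); ++id) {
    const std::string& s = seqs[id];
    int l = (int)s.size();
    if (l < out.nseg) {
      out.short_amps.push_back(std::make_pair(id, l));
      continue;
    }
    std::unordered_map<int, std::vector<std::unordered_map<std::string, std::vector<int> > > >::iterator
        it = out.idx.find(l);
    if (it == out.idx.end()) {
      std::vector<int> st, ln;
      partition_positions(l, out.nseg, st, ln);
      out.starts_by_len[l] = st;
      out.lens_by_len[l] = ln;
      it = out.idx
               .insert(std::make_pair(
                   l, std::vector<std::unordered_map<std::string, std::vector<int> > >(
                          out.nseg)))
               .first;
    }
    const std::vector<int>& st = out.starts_by_len[l];
    const std::vector<int>& ln = out.lens_by_len[l];
    for (int i = 0; i < out.nseg; ++i)
      it->second[i][s.substr(st[i], ln[i])].push_back(id);
  }
}

// First filter stage: all indexed amplicons sharing >= k distinct segment
// indices with admissible substrings of S, plus the length-compatible short
// amplicons. Self-matches excluded; result sorted ascending.
static void find_candidates(const std::string& S, int self, const SegIndex& ix,
                            std::vector<int>& out) {
  int slen = (int)S.size();
  std::unordered_map<int, uint32_t> marks;
  for (std::unordered_map<int, std::vector<std::unordered_map<std::string, std::vector<int> > > >::const_iterator
           kv = ix.idx.begin();
       kv != ix.idx.end(); ++kv) {
    int l = kv->first;
    if (std::abs(slen - l) > ix.tau) continue;
    const std::vector<int>& st = ix.starts_by_len.at(l);
    const std::vector<int>& ln = ix.lens_by_len.at(l);
    for (int i = 0; i < ix.nseg; ++i) {
      const std::unordered_map<std::string, std::vector<int> >& m = kv->second[i];
      if (m.empty()) continue;
      int lo, hi;
      seg_window(slen, l, i, st[i], ln[i], ix.tau, ix.k, lo, hi);
      for (int w = lo; w <= hi; ++w) {
        std::unordered_map<std::string, std::vector<int> >::const_iterator hit =
            m.find(S.substr(w, ln[i]));
        if (hit == m.end()) continue;
        for (size_t z = 0; z < hit->second.size(); ++z) {
          int id = hit->second[z];
          if (id != self) marks[id] |= (1u << i);
        }
      }
    }
  }
  out.clear();
  for (std::unordered_map<int, uint32_t>::iterator it = marks.begin();
       it != marks.end(); ++it) {
    if (__builtin_popcount(it->second) >= ix.k) out.push_back(it->first);
  }
  for (size_t z = 0; z < ix.short_amps.size(); ++z) {
    if (ix.short_amps[z].first != self &&
        std::abs(slen - ix.short_amps[z].second) <= ix.tau)
      out.push_back(ix.short_amps[z].first);
  }
  std::sort(out.begin(), out.end());
}

// Second (bidirectional) filter stage with roles swapped: partition S and
// require >= k of its segments inside C's admissible windows. Sequences too
// short to partition pass through (they are verified anyway).
static bool bidir_ok(const std::string& S, const std::string& C, int tau,
                     int k) {
  int nseg = tau + k;
  int slen = (int)S.size(), clen = (int)C.size();
  if (std::abs(slen - clen) > tau) return false;
  if (slen < nseg) return true;
  std::vector<int> st, ln;
  partition_positions(slen, nseg, st, ln);
  int cnt = 0;
  for (int i = 0; i < nseg; ++i) {
    int lo, hi;
    seg_window(clen, slen, i, st[i], ln[i], tau, k, lo, hi);
    bool found = false;
    for (int w = lo; w <= hi && !found; ++w)
      if (C.compare(w, ln[i], S, st[i], ln[i]) == 0) found = true;
    if (found && ++cnt >= k) return true;
    if (cnt + (nseg - 1 - i) < k) return false;
  }
  return cnt >= k;
}

// [[Rcpp::export]]
IntegerVector cpp_candidates(CharacterVector pool, std::string query,
                             int self, int tau, int k) {
  std::vector<std::string> seqs(pool.size());
  for (int i = 0; i < pool.size(); ++i) seqs[i] = as<std::string>(pool[i]);
  SegIndex ix;
  build_index(seqs, tau, k, ix);
  std::vector<int> cand;
  find_candidates(query, self - 1, ix, cand);  // self is 1-based or 0 for none
  IntegerVector out(cand.size());
  for (size_t i = 0; i < cand.size(); ++i) out[i] = cand[i] + 1;
  return out;
}

// [[Rcpp::export]]
bool cpp_bidirectional(std::string s, std::string c, int tau, int k) {
  return bidir_ok(s, c, tau, k);
}

// ---------------------------------------------------------------------------
// Bounded edit distance: banded DP over the 2*tau+1 diagonals |j - i| <= tau
// with early termination once a whole row exceeds tau. Returns the exact
// distance if <= tau, else -1 (EXCEEDS).
// ---------------------------------------------------------------------------
static int bounded_edit(const std::string& a, const std::string& b, int tau) {
  int m = (int)a.size(), n = (int)b.size();
  if (std::abs(n - m) > tau) return -1;
  if (tau == 0) return a == b ? 0 : -1;
  int width = 2 * tau + 1;
  const int INF = tau + 1;
  std::vector<int> prev(width, INF), cur(width, INF);
  for (int o = 0; o < width; ++o) {
    int j = o - tau;  // row i = 0
    if (j >= 0 && j <= n) prev[o] = j;
  }
  for (int i = 1; i <= m; ++i) {
    bool alive = false;
    for (int o = 0; o < width; ++o) {
      int j = i + o - tau;
      if (j < 0 || j > n) {
        cur[o] = INF;
        continue;
      }
      int best = INF;
      if (j == 0) {
        best = i;
      } else {
        int d = prev[o];  // (i-1, j-1) sits at the same offset
        if (d < INF) {
          int v = d + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (v < best) best = v;
        }
        if (o + 1 < width && prev[o + 1] < INF && prev[o + 1] + 1 < best)
          best = prev[o + 1] + 1;  // deletion from a: (i-1, j)
        if (o - 1 >= 0 && cur[o - 1] < INF && cur[o - 1] + 1 < best)
          best = cur[o - 1] + 1;  // insertion into a: (i, j-1)
      }
      cur[o] = best > INF ? INF : best;
      if (cur[o] <= tau) alive = true;
    }
    if (!alive) return -1;
    std::swap(prev, cur);
  }
  int d = prev[n - m + tau];
  return d <= tau ? d : -1;
}

// ---------------------------------------------------------------------------
// Affine-gap (Gotoh) alignment restricted to the band |j - i| <= band.
// Objective is lexicographic: maximise score, then minimise the number of
// difference columns (mismatches + gap columns), then minimise alignment
// columns. Gap cost convention: a gap of length g costs open + g * extend.
// ---------------------------------------------------------------------------
struct Cell {
  int s, d, c;
};

static inline bool cell_better(const Cell& a, const Cell& b) {
  if (a.s != b.s) return a.s > b.s;
  if (a.d != b.d) return a.d < b.d;
  return a.c < b.c;
}

static inline Cell cell_best(const Cell& a, const Cell& b) {
  return cell_better(a, b) ? a : b;
}

static bool gotoh_banded(const std::string& a, const std::string& b, int band,
                         int match, int mism, int open, int ext, Cell& fin) {
  int m = (int)a.size(), n = (int)b.size();
  if (std::abs(n - m) > band) return false;
  int width = 2 * band + 1;
  Cell BAD = {NEG_BIG, 0, 0};
  std::vector<Cell> Mp(width, BAD), Xp(width, BAD), Yp(width, BAD);
  std::vector<Cell> Mc(width, BAD), Xc(width, BAD), Yc(width, BAD);
  for (int o = 0; o < width; ++o) {
    int j = o - band;
    if (j < 0 || j > n) continue;
    if (j == 0) {
      Cell z = {0, 0, 0};
      Mp[o] = z;
    } else {
      Cell y = {-open - ext * j, j, j};
      Yp[o] = y;
    }
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), BAD);
    std::fill(Xc.begin(), Xc.end(), BAD);
    std::fill(Yc.begin(), Yc.end(), BAD);
    for (int o = 0; o < width; ++o) {
      int j = i + o - band;
      if (j < 0 || j > n) continue;
      if (j == 0) {
        Cell x = {-open - ext * i, i, i};
        Xc[o] = x;
        continue;
      }
      // M from (i-1, j-1): same offset in the previous row
      Cell diag = cell_best(Mp[o], cell_best(Xp[o], Yp[o]));
      if (diag.s > NEG_BIG / 2) {
        bool eq = a[i - 1] == b[j - 1];
        Cell v = {diag.s + (eq ? match : -mism), diag.d + (eq ? 0 : 1),
                  diag.c + 1};
        Mc[o] = v;
      }
      // X: gap column consuming a, from (i-1, j) at offset o+1
      if (o + 1 < width) {
        Cell cand = BAD;
        if (Mp[o + 1].s > NEG_BIG / 2) {
          Cell v = {Mp[o + 1].s - open - ext, Mp[o + 1].d + 1, Mp[o + 1].c + 1};
          cand = cell_best(cand, v);
        }
        if (Xp[o + 1].s > NEG_BIG / 2) {
          Cell v = {Xp[o + 1].s - ext, Xp[o + 1].d + 1, Xp[o + 1].c + 1};
          cand = cell_best(cand, v);
        }
        if (Yp[o + 1].s > NEG_BIG / 2) {
          Cell v = {Yp[o + 1].s - open - ext, Yp[o + 1].d + 1, Yp[o + 1].c + 1};
          cand = cell_best(cand, v);
        }
        Xc[o] = cand;
      }
      // Y: gap column consuming b, from (i, j-1) at offset o-1, current row
      if (o - 1 >= 0) {
        Cell cand = BAD;
        if (Mc[o - 1].s > NEG_BIG / 2) {
          Cell v = {Mc[o - 1].s - open - ext, Mc[o - 1].d + 1, Mc[o - 1].c + 1};
          cand = cell_best(cand, v);
        }
        if (Yc[o - 1].s > NEG_BIG / 2) {
          Cell v = {Yc[o - 1].s - ext, Yc[o - 1].d + 1, Yc[o - 1].c + 1};
          cand = cell_best(cand, v);
        }
        if (Xc[o - 1].s > NEG_BIG / 2) {
          Cell v = {Xc[o - 1].s - open - ext, Xc[o - 1].d + 1, Xc[o - 1].c + 1};
          cand = cell_best(cand, v);
        }
        Yc[o] = cand;
      }
    }
    std::swap(Mp, Mc);
    std::swap(Xp, Xc);
    std::swap(Yp, Yc);
  }
  int o = n - m + band;
  fin = cell_best(Mp[o], cell_best(Xp[o], Yp[o]));
  return fin.s > NEG_BIG / 2;
}

// Difference count of the optimal banded affine alignment if <= tau, else -1.
static int bounded_score(const std::string& a, const std::string& b, int tau,
                         int match, int mism, int open, int ext) {
  int m = (int)a.size(), n = (int)b.size();
  if (std::abs(n - m) > tau) return -1;
  Cell fin;
  if (!gotoh_banded(a, b, tau > 0 ? tau : 0, match, mism, open, ext, fin))
    return -1;
  return fin.d <= tau ? fin.d : -1;
}

// [[Rcpp::export]]
IntegerVector cpp_bounded_edit_batch(CharacterVector a, CharacterVector b,
                                     int tau) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int d = bounded_edit(as<std::string>(a[i]), as<std::string>(b[i]), tau);
    out[i] = d < 0 ? NA_INTEGER : d;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_bounded_score_batch(CharacterVector a, CharacterVector b,
                                      int tau, IntegerVector delta) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int d = bounded_score(as<std::string>(a[i]), as<std::string>(b[i]), tau,
                          delta[0], delta[1], delta[2], delta[3]);
    out[i] = d < 0 ? NA_INTEGER : d;
  }
  return out;
}

// Full-band alignment statistics for one pair: score, difference columns and
// total aligned columns of the optimal alignment (used for identity output).
// [[Rcpp::export]]
IntegerVector cpp_align_stats(std::string a, std::string b,
                              IntegerVector delta) {
  int band = std::max((int)a.size(), (int)b.size());
  if (band == 0) band = 1;
  Cell fin;
  gotoh_banded(a, b, band, delta[0], delta[1], delta[2], delta[3], fin);
  return IntegerVector::create(Named("score") = fin.s, Named("diffs") = fin.d,
                               Named("columns") = fin.c);
}

static inline int verify_pair(const std::string& a, const std::string& b,
                              int tau, int mode, const int* delta) {
  if (mode == 0) return bounded_edit(a, b, tau);
  return bounded_score(a, b, tau, delta[0], delta[1], delta[2], delta[3]);
}

// ---------------------------------------------------------------------------
// Iterative OTU growth over one pool. Amplicons must arrive in processing
// priority order (abundance desc, ties resolved upstream), so index order is
// priority order. mode: 0 = edit distance, 1 = scoring function.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_cluster_pool(CharacterVector seqs_, IntegerVector abund, int t, int k,
                      bool breaking, int mode, IntegerVector delta_) {
  int N = seqs_.size();
  std::vector<std::string> seqs(N);
  for (int i = 0; i < N; ++i) seqs[i] = as<std::string>(seqs_[i]);
  int delta[4] = {0, 0, 0, 0};
  for (int i = 0; i < 4 && i < delta_.size(); ++i) delta[i] = delta_[i];

  SegIndex ix;
  build_index(seqs, t, k, ix);

  std::vector<int> otu(N, -1), parent(N, -1), dist(N, 0), gen(N, 0);
  std::vector<int> attach;
  attach.reserve(N);
  int n_otu = 0;
  std::vector<int> cur, nxt, cand;

  for (int s = 0; s < N; ++s) {
    if (otu[s] >= 0) continue;
    int id = n_otu++;
    otu[s] = id;
    gen[s] = 0;
    attach.push_back(s);
    cur.assign(1, s);
    while (!cur.empty()) {
      nxt.clear();
      std::sort(cur.begin(), cur.end());  // subseeds in global priority order
      for (size_t ai = 0; ai < cur.size(); ++ai) {
        int a = cur[ai];
        find_candidates(seqs[a], a, ix, cand);
        for (size_t ci = 0; ci < cand.size(); ++ci) {
          int c = cand[ci];
          if (otu[c] >= 0) continue;  // first claim wins
          if (breaking && abund[c] > abund[a]) continue;
          if (!bidir_ok(seqs[a], seqs[c], t, k)) continue;
          int d = verify_pair(seqs[a], seqs[c], t, mode, delta);
          if (d < 0) continue;
          otu[c] = id;
          parent[c] = a;
          dist[c] = d;
          gen[c] = gen[a] + 1;
          attach.push_back(c);
          nxt.push_back(c);
        }
      }
      std::swap(cur, nxt);
    }
  }

  IntegerVector otu_(N), parent_(N), dist_(N), gen_(N), attach_(N);
  for (int i = 0; i < N; ++i) {
    otu_[i] = otu[i] + 1;
    parent_[i] = parent[i] < 0 ? NA_INTEGER : parent[i] + 1;
    dist_[i] = parent[i] < 0 ? NA_INTEGER : dist[i];
    gen_[i] = gen[i];
    attach_[i] = attach[i] + 1;
  }
  return List::create(Named("otu") = otu_, Named("parent") = parent_,
                      Named("distance") = dist_, Named("generation") = gen_,
                      Named("attachOrder") = attach_,
                      Named("nOtu") = n_otu);
}

// Partners of one amplicon among the available pool members: full filter
// pipeline plus verification (no abundance rule; applied by the caller).
// Returns a 2-column matrix (index, distance), indices 1-based ascending.
// [[Rcpp::export]]
IntegerMatrix cpp_partners(CharacterVector pool, IntegerVector available,
                           int query, int tau, int k, int mode,
                           IntegerVector delta_) {
  int N = pool.size();
  std::vector<std::string> seqs(N);
  for (int i = 0; i < N; ++i) seqs[i] = as<std::string>(pool[i]);
  int delta[4] = {0, 0, 0, 0};
  for (int i = 0; i < 4 && i < delta_.size(); ++i) delta[i] = delta_[i];
  SegIndex ix;
  build_index(seqs, tau, k, ix);
  std::vector<int> cand;
  find_candidates(seqs[query - 1], query - 1, ix, cand);
  std::vector<std::pair<int, int> > hits;
  for (size_t i = 0; i < cand.size(); ++i) {
    int c = cand[i];
    if (!available[c]) continue;
    if (!bidir_ok(seqs[query - 1], seqs[c], tau, k)) continue;
    int d = verify_pair(seqs[query - 1], seqs[c], tau, mode, delta);
    if (d >= 0) hits.push_back(std::make_pair(c + 1, d));
  }
  IntegerMatrix out(hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].first;
    out(i, 1) = hits[i].second;
  }
  colnames(out) = CharacterVector::create("index", "distance");
  return out;
}

// Batch check of the two filter stages for given (query, candidate) index
// pairs against one shared index: does `cand` survive candidate generation
// from `query`'s side plus the bidirectional check? Used by the tests to
// assert filter completeness against a full-DP oracle.
// [[Rcpp::export]]
LogicalVector cpp_filter_pairs(CharacterVector pool, IntegerVector qi,
                               IntegerVector ci, int tau, int k) {
  int N = pool.size();
  std::vector<std::string> seqs(N);
  for (int i = 0; i < N; ++i) seqs[i] = as<std::string>(pool[i]);
  SegIndex ix;
  build_index(seqs, tau, k, ix);
  int M = qi.size();
  LogicalVector out(M);
  std::vector<int> cand;
  int lastQ = -1;
  std::vector<bool> inCand(N, false);
  for (int z = 0; z < M; ++z) {
    int q = qi[z] - 1, c = ci[z] - 1;
    if (q != lastQ) {
      for (size_t y = 0; y < cand.size(); ++y) inCand[cand[y]] = false;
      find_candidates(seqs[q], q, ix, cand);
      for (size_t y = 0; y < cand.size(); ++y) inCand[cand[y]] = true;
      lastQ = q;
    }
    out[z] = inCand[c] && bidir_ok(seqs[q], seqs[c], tau, k);
  }
  return out;
}

// Grafting candidate links for fastidious refinement: index the amplicons of
// light OTUs at threshold tf, query with each heavy amplicon. Returns all
// verified (heavy, light, distance) triples, 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_graft_links(CharacterVector light_, CharacterVector heavy_,
                              int tf, int k, int mode, IntegerVector delta_) {
  int NL = light_.size(), NH = heavy_.size();
  std::vector<std::string> light(NL), heavy(NH);
  for (int i = 0; i < NL; ++i) light[i] = as<std::string>(light_[i]);
  for (int i = 0; i < NH; ++i) heavy[i] = as<std::string>(heavy_[i]);
  int delta[4] = {0, 0, 0, 0};
  for (int i = 0; i < 4 && i < delta_.size(); ++i) delta[i] = delta_[i];
  SegIndex ix;
  build_index(light, tf, k, ix);
  std::vector<int> cand;
  std::vector<int> hh, ll, dd;
  for (int h = 0; h < NH; ++h) {
    find_candidates(heavy[h], -1, ix, cand);
    for (size_t i = 0; i < cand.size(); ++i) {
      int l = cand[i];
      if (!bidir_ok(heavy[h], light[l], tf, k)) continue;
      int d = verify_pair(heavy[h], light[l], tf, mode, delta);
      if (d >= 0) {
        hh.push_back(h + 1);
        ll.push_back(l + 1);
        dd.push_back(d);
      }
    }
  }
  IntegerMatrix out(hh.size(), 3);
  for (size_t i = 0; i < hh.size(); ++i) {
    out(i, 0) = hh[i];
    out(i, 1) = ll[i];
    out(i, 2) = dd[i];
  }
  colnames(out) = CharacterVector::create("heavy", "light", "distance");
  return out;
}
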