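#include "vcatac.h"
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Streaming k-mer query, virtual-color pseudoalignment, and the paired-end
// merge pipeline. All exported per-operation entry points call the same
// static *_impl routines used by the batch mapper, so toggling streaming or
// the cache, or calling operations individually from R, cannot change
// results.

namespace {

struct Slot { int32_t uid, off; uint8_t fwd, present; };
struct Hit { int32_t ref, pos, vid, support; uint8_t fwd; };
struct Merged { int32_t ref, start, end; uint8_t fwd1; double frac; };

const double EPS = 1e-9;

// one slot per read k-mer; identical to independent index lookups.
// state carries (unitig, orientation, offset, distance-to-end) of the
// previous k-mer; extension succeeds when the next unitig nucleotide
// matches the new k-mer's last nucleotide. A query is terminal-eligible
// when the previous k-mer sat at the unitig end (distance 0); only those
// queries consult/populate the write-once cache.
void stream_query_impl(const IndexView &V, const char *read, int rl,
                       bool streaming, KmerCache *cache,
                       std::vector<Slot> &slots, int *n_queries) {
  const int k = V.k;
  slots.assign(rl >= k ? (size_t)(rl - k + 1) : 0, Slot{0, 0, 0, 0});
  int nq = 0;
  if (rl < k) { if (n_queries) *n_queries = 0; return; }
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  uint64_t cur = 0, rcur = 0;
  int run = 0;
  bool active = false, s_fwd = true;
  int32_t s_uid = 0, s_off = 0, s_rem = 0;
  const char *useq = NULL;

  for (int i = 0; i < rl; ++i) {
    int b = base2bits(read[i]);
    if (b < 0) { run = 0; active = false; continue; }
    cur = ((cur << 2) | (uint64_t)b) & mask;
    rcur = (rcur >> 2) | (((uint64_t)(b ^ 3)) << (2 * (k - 1)));
    if (++run < k) continue;
    const int si = i - k + 1;

    if (streaming && active && s_rem > 0) {
      char expected = s_fwd ? useq[s_off + k] : comp_base(useq[s_off - 1]);
      if (expected == read[i]) {
        s_off += s_fwd ? 1 : -1;
        s_rem -= 1;
        slots[si] = Slot{s_uid, s_off, (uint8_t)(s_fwd ? 1 : 0), 1};
        continue;
      }
      active = false; // extension failed mid-unitig: plain full query
    }
    const bool terminal = streaming && active && s_rem == 0;
    active = false;
    const uint64_t c = cur < rcur ? cur : rcur;
    Entry e;
    bool found = false;
    if (terminal && cache) {
      std::unordered_map<uint64_t, Entry>::const_iterator it = cache->m.find(c);
      if (it != cache->m.end()) {
        e = it->second;
        found = true;
      } else {
        ++nq;
        found = V.find(c, e);
        if (found && cache->m.size() < cache->cap) cache->m.emplace(c, e);
      }
    } else {
      ++nq;
      found = V.find(c, e);
    }
    if (found) {
      const bool qfwd = (cur == c) ? (e.fwd != 0) : (e.fwd == 0);
      slots[si] = Slot{e.uid, e.off, (uint8_t)(qfwd ? 1 : 0), 1};
      const int lu = V.unitig_len(e.uid);
      active = true;
      s_uid = e.uid; s_off = e.off; s_fwd = qfwd;
      s_rem = qfwd ? (lu - k - e.off) : e.off;
      useq = V.unitig_seq(e.uid);
    }
  }
  if (n_queries) *n_queries = nq;
}

// threshold-union pseudoalignment of one mate over virtual colors.
// support is tallied per (virtual color, read orientation), each read
// k-mer counted at most once per pair; the reported position is inferred
// from the leftmost-in-read supporting k-mer (smallest reference
// coordinate within the bin when it occurs several times).
void pseudoalign_impl(const IndexView &V, const char *read, int rl,
                      const int *cb, const int *nbins, int lvcol, int ov,
                      double tau, bool streaming, KmerCache *cache,
                      std::vector<Hit> &out, int &kq) {
  struct Acc { int32_t ref, support, last_k, first_k, minpos; };
  out.clear();
  kq = 0;
  const int k = V.k;
  if (rl < k) return;
  std::vector<Slot> slots;
  stream_query_impl(V, read, rl, streaming, cache, slots, NULL);

  std::unordered_map<int64_t, Acc> acc;
  for (size_t si = 0; si < slots.size(); ++si) {
    if (!slots[si].present) continue;
    ++kq;
    const int uid = slots[si].uid, off = slots[si].off;
    const bool qf = slots[si].fwd != 0;
    const int lu = V.unitig_len(uid);
    for (int j = V.occ_ptr[uid - 1]; j < V.occ_ptr[uid]; ++j) {
      const int ref = V.occ_ref[j];
      const bool ofwd = V.occ_fwd[j] != 0;
      const int kpos = ofwd ? V.occ_pos[j] + off : V.occ_pos[j] + (lu - k - off);
      const bool kf = (qf == ofwd);
      const int bbin = kpos / lvcol;
      int vids[2] = {cb[ref] + bbin, 0};
      int nv = 1;
      if ((kpos % lvcol) >= lvcol - ov && bbin + 1 < nbins[ref]) {
        vids[1] = vids[0] + 1;
        nv = 2;
      }
      for (int t = 0; t < nv; ++t) {
        const int64_t key = ((int64_t)vids[t] << 1) | (kf ? 1 : 0);
        std::unordered_map<int64_t, Acc>::iterator it = acc.find(key);
        if (it == acc.end()) {
          Acc a; a.ref = ref; a.support = 1;
          a.last_k = a.first_k = (int32_t)si; a.minpos = kpos;
          acc.emplace(key, a);
        } else {
          Acc &a = it->second;
          if (a.last_k != (int32_t)si) { a.support += 1; a.last_k = (int32_t)si; }
          if (a.first_k == (int32_t)si && kpos < a.minpos) a.minpos = kpos;
        }
      }
    }
  }
  for (std::unordered_map<int64_t, Acc>::const_iterator it = acc.begin();
       it != acc.end(); ++it) {
    const Acc &a = it->second;
    if (a.support + EPS < tau * kq) continue;
    const int vid = (int)(it->first >> 1);
    const bool kf = (it->first & 1) != 0;
    int pos = kf ? a.minpos - a.first_k : a.minpos - (rl - k - a.first_k);
    if (pos < 0) pos = 0;
    Hit h; h.ref = a.ref; h.pos = pos; h.vid = vid;
    h.support = a.support; h.fwd = (uint8_t)(kf ? 1 : 0);
    out.push_back(h);
  }
  std::sort(out.begin(), out.end(), [](const Hit &x, const Hit &y) {
    if (x.vid != y.vid) return x.vid < y.vid;
    return x.fwd < y.fwd;
  });
}

// among hits equal on (orientation, reference, position) keep the smaller
// virtual color id; returns the largest duplicate-group size seen.
int dedup_impl(std::vector<Hit> &hits) {
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    if (a.fwd != b.fwd) return a.fwd < b.fwd;
    if (a.ref != b.ref) return a.ref < b.ref;
    if (a.pos != b.pos) return a.pos < b.pos;
    return a.vid < b.vid;
  });
  std::vector<Hit> kept;
  int max_group = 0, gsz = 0;
  for (size_t i = 0; i < hits.size(); ++i) {
    if (i == 0 || hits[i].fwd != hits[i - 1].fwd ||
        hits[i].ref != hits[i - 1].ref || hits[i].pos != hits[i - 1].pos) {
      kept.push_back(hits[i]);
      gsz = 1;
    } else {
      ++gsz;
    }
    if (gsz > max_group) max_group = gsz;
  }
  hits.swap(kept);
  return max_group;
}

void merge_impl(const std::vector<Hit> &h1, int kq1, int rl1,
                const std::vector<Hit> &h2, int kq2, int rl2,
                int dovetail_max, int ins_max, std::vector<Merged> &out) {
  out.clear();
  for (size_t i = 0; i < h1.size(); ++i) {
    for (size_t j = 0; j < h2.size(); ++j) {
      const Hit &a = h1[i], &b = h2[j];
      if (a.ref != b.ref) continue;
      if (std::abs(a.vid - b.vid) > 1) continue;
      if (a.fwd == b.fwd) continue;
      const int d = a.fwd ? (b.pos - a.pos) : (a.pos - b.pos);
      if (d < -dovetail_max || d > ins_max) continue;
      Merged m;
      m.ref = a.ref;
      m.start = std::min(a.pos, b.pos);
      m.end = (a.pos >= b.pos) ? a.pos + rl1 : b.pos + rl2;
      m.fwd1 = a.fwd;
      m.frac = (double)(a.support + b.support) / (double)(kq1 + kq2);
      out.push_back(m);
    }
  }
}

// keep only merged mappings tied for the largest support fraction
void filter_best_impl(std::vector<Merged> &m) {
  if (m.empty()) return;
  double fmax = m[0].frac;
  for (size_t i = 1; i < m.size(); ++i) fmax = std::max(fmax, m[i].frac);
  std::vector<Merged> kept;
  for (size_t i = 0; i < m.size(); ++i)
    if (m[i].frac + EPS >= fmax) kept.push_back(m[i]);
  m.swap(kept);
}

KmerCache *cache_ptr(SEXP s) {
  if (Rf_isNull(s)) return NULL;
  Rcpp::XPtr<KmerCache> p(s);
  return p.get();
}

List hits_to_list(const std::vector<Hit> &hits, int kq) {
  const R_xlen_t n = (R_xlen_t)hits.size();
  IntegerVector ref(n), pos(n), vid(n), support(n);
  LogicalVector fwd(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    ref[i] = hits[i].ref; pos[i] = hits[i].pos; vid[i] = hits[i].vid;
    support[i] = hits[i].support; fwd[i] = hits[i].fwd != 0;
  }
  return List::create(_["ref"] = ref, _["pos"] = pos, _["fwd"] = fwd,
                      _["vid"] = vid, _["support"] = support, _["kq"] = kq);
}

std::vector<Hit> hits_from_args(IntegerVector ref, IntegerVector pos,
                                LogicalVector fwd, IntegerVector vid,
                                IntegerVector support) {
  std::vector<Hit> h((size_t)ref.size());
  for (R_xlen_t i = 0; i < ref.size(); ++i) {
    h[i].ref = ref[i]; h[i].pos = pos[i]; h[i].vid = vid[i];
    h[i].support = support.size() ? support[i] : 0;
    h[i].fwd = (uint8_t)(fwd[i] ? 1 : 0);
  }
  return h;
}

} // namespace

// [[Rcpp::export(name = ".lookup_kmer_cpp")]]
List lookup_kmer_cpp(List index, CharacterVector kmers) {
  IndexView V = make_view(index);
  const int k = V.k;
  const R_xlen_t n = kmers.size();
  LogicalVector present(n);
  IntegerVector uid(n, NA_INTEGER), off(n, NA_INTEGER);
  LogicalVector fwd(n, NA_LOGICAL);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) { present[i] = false; continue; }
    const char *s = CHAR(STRING_ELT(kmers, i));
    if ((int)LENGTH(STRING_ELT(kmers, i)) != k) { present[i] = false; continue; }
    uint64_t x = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { ok = false; break; }
      x = (x << 2) | (uint64_t)b;
    }
    if (!ok) { present[i] = false; continue; }
    const uint64_t r = revcomp_bits(x, k);
    const uint64_t c = x < r ? x : r;
    Entry e;
    if (V.find(c, e)) {
      present[i] = true;
      uid[i] = e.uid;
      off[i] = e.off;
      fwd[i] = (x == c) ? (e.fwd != 0) : (e.fwd == 0);
    } else {
      present[i] = false;
    }
  }
  return List::create(_["present"] = present, _["uid"] = uid,
                      _["off"] = off, _["fwd"] = fwd);
}

// [[Rcpp::export(name = ".kmer_positions_cpp")]]
DataFrame kmer_positions_cpp(List index, CharacterVector kmers) {
  IndexView V = make_view(index);
  const int k = V.k;
  List lk = lookup_kmer_cpp(index, kmers);
  LogicalVector present = lk["present"];
  IntegerVector uid = lk["uid"], off = lk["off"];
  LogicalVector fwd = lk["fwd"];
  std::vector<int> q_out, ref_out, pos_out;
  std::vector<int> fwd_out;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (!present[i]) continue;
    const int u = uid[i], o = off[i];
    const bool qf = fwd[i] != 0;
    const int lu = V.unitig_len(u);
    std::vector<std::pair<std::pair<int, int>, int> > rows;
    for (int j = V.occ_ptr[u - 1]; j < V.occ_ptr[u]; ++j) {
      const bool ofwd = V.occ_fwd[j] != 0;
      const int kpos = ofwd ? V.occ_pos[j] + o : V.occ_pos[j] + (lu - k - o);
      rows.push_back(std::make_pair(std::make_pair(V.occ_ref[j], kpos),
                                    (qf == ofwd) ? 1 : 0));
    }
    std::sort(rows.begin(), rows.end());
    for (size_t t = 0; t < rows.size(); ++t) {
      q_out.push_back((int)i + 1);
      ref_out.push_back(rows[t].first.first);
      pos_out.push_back(rows[t].first.second);
      fwd_out.push_back(rows[t].second);
    }
  }
  const R_xlen_t n = (R_xlen_t)q_out.size();
  IntegerVector q(n), ref(n), pos(n);
  LogicalVector fw(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    q[i] = q_out[i]; ref[i] = ref_out[i]; pos[i] = pos_out[i];
    fw[i] = fwd_out[i] != 0;
  }
  return DataFrame::create(_["query"] = q, _["ref"] = ref, _["pos"] = pos,
                           _["fwd"] = fw);
}

// [[Rcpp::export(name = ".query_kmers_streaming_cpp")]]
List query_kmers_streaming_cpp(List index, std::string read, bool streaming,
                               SEXP cache) {
  IndexView V = make_view(index);
  std::vector<Slot> slots;
  int nq = 0;
  stream_query_impl(V, read.c_str(), (int)read.size(), streaming,
                    cache_ptr(cache), slots, &nq);
  const R_xlen_t n = (R_xlen_t)slots.size();
  LogicalVector present(n);
  IntegerVector uid(n, NA_INTEGER), off(n, NA_INTEGER);
  LogicalVector fwd(n, NA_LOGICAL);
  for (R_xlen_t i = 0; i < n; ++i) {
    present[i] = slots[i].present != 0;
    if (slots[i].present) {
      uid[i] = slots[i].uid;
      off[i] = slots[i].off;
      fwd[i] = slots[i].fwd != 0;
    }
  }
  return List::create(_["present"] = present, _["uid"] = uid, _["off"] = off,
                      _["fwd"] = fwd, _["n_queries"] = nq);
}

// [[Rcpp::export(name = ".pseudoalign_mate_cpp")]]
List pseudoalign_mate_cpp(List index, std::string read, IntegerVector cb,
                          IntegerVector nbins, int lvcol, int ov, double tau,
                          bool streaming, SEXP cache) {
  IndexView V = make_view(index);
  std::vector<Hit> hits;
  int kq = 0;
  pseudoalign_impl(V, read.c_str(), (int)read.size(), INTEGER(cb),
                   INTEGER(nbins), lvcol, ov, tau, streaming,
                   cache_ptr(cache), hits, kq);
  return hits_to_list(hits, kq);
}

// [[Rcpp::export(name = ".dedup_hits_cpp")]]
List dedup_hits_cpp(IntegerVector ref, IntegerVector pos, LogicalVector fwd,
                    IntegerVector vid, IntegerVector support) {
  std::vector<Hit> h = hits_from_args(ref, pos, fwd, vid, support);
  const int max_group = dedup_impl(h);
  const R_xlen_t n = (R_xlen_t)h.size();
  IntegerVector oref(n), opos(n), ovid(n), osup(n);
  LogicalVector ofwd(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    oref[i] = h[i].ref; opos[i] = h[i].pos; ovid[i] = h[i].vid;
    osup[i] = h[i].support; ofwd[i] = h[i].fwd != 0;
  }
  return List::create(_["ref"] = oref, _["pos"] = opos, _["fwd"] = ofwd,
                      _["vid"] = ovid, _["support"] = osup,
                      _["max_group"] = max_group);
}

// [[Rcpp::export(name = ".merge_mates_cpp")]]
DataFrame merge_mates_cpp(IntegerVector ref1, IntegerVector pos1,
                          LogicalVector fwd1, IntegerVector vid1,
                          IntegerVector sup1, int kq1, int rl1,
                          IntegerVector ref2, IntegerVector pos2,
                          LogicalVector fwd2, IntegerVector vid2,
                          IntegerVector sup2, int kq2, int rl2,
                          int dovetail_max, int ins_max) {
  std::vector<Hit> h1 = hits_from_args(ref1, pos1, fwd1, vid1, sup1);
  std::vector<Hit> h2 = hits_from_args(ref2, pos2, fwd2, vid2, sup2);
  std::vector<Merged> m;
  merge_impl(h1, kq1, rl1, h2, kq2, rl2, dovetail_max, ins_max, m);
  const R_xlen_t n = (R_xlen_t)m.size();
  IntegerVector ref(n), start(n), end(n);
  LogicalVector f1(n);
  NumericVector frac(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    ref[i] = m[i].ref; start[i] = m[i].start; end[i] = m[i].end;
    f1[i] = m[i].fwd1 != 0; frac[i] = m[i].frac;
  }
  return DataFrame::create(_["ref"] = ref, _["start"] = start,
                           _["end"] = end, _["fwd1"] = f1, _["frac"] = frac);
}

// [[Rcpp::export(name = ".map_pairs_cpp")]]
List map_pairs_cpp(List index, CharacterVector r1, CharacterVector r3,
                   IntegerVector cb, IntegerVector nbins, int lvcol, int ov,
                   double tau, int dovetail_max, int ins_max, bool streaming,
                   SEXP cache) {
  IndexView V = make_view(index);
  KmerCache *kc = cache_ptr(cache);
  const R_xlen_t n = r1.size();
  if (r3.size() != n) stop("mate files have different numbers of reads");
  IntegerVector status(n);
  std::vector<int> f_pair, f_ref, f_start, f_end;
  std::vector<int> f_fwd1;
  std::vector<double> f_frac;
  int dup_violation = 0;
  std::vector<Hit> h1, h2;
  std::vector<Merged> m;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s1 = CHAR(STRING_ELT(r1, i));
    const char *s2 = CHAR(STRING_ELT(r3, i));
    const int rl1 = (int)LENGTH(STRING_ELT(r1, i));
    const int rl2 = (int)LENGTH(STRING_ELT(r3, i));
    int kq1 = 0, kq2 = 0;
    pseudoalign_impl(V, s1, rl1, INTEGER(cb), INTEGER(nbins), lvcol, ov, tau,
                     streaming, kc, h1, kq1);
    pseudoalign_impl(V, s2, rl2, INTEGER(cb), INTEGER(nbins), lvcol, ov, tau,
                     streaming, kc, h2, kq2);
    if (dedup_impl(h1) > 2) ++dup_violation;
    if (dedup_impl(h2) > 2) ++dup_violation;
    merge_impl(h1, kq1, rl1, h2, kq2, rl2, dovetail_max, ins_max, m);
    filter_best_impl(m);
    if (m.size() == 1) {
      status[i] = 0;
      f_pair.push_back((int)i + 1);
      f_ref.push_back(m[0].ref);
      f_start.push_back(m[0].start);
      f_end.push_back(m[0].end);
      f_fwd1.push_back(m[0].fwd1);
      f_frac.push_back(m[0].frac);
    } else if (m.empty()) {
      status[i] = 1;
    } else {
      status[i] = 2;
    }
  }
  const R_xlen_t nf = (R_xlen_t)f_pair.size();
  IntegerVector pair(nf), ref(nf), start(nf), end(nf);
  LogicalVector fwd1(nf);
  NumericVector frac(nf);
  for (R_xlen_t i = 0; i < nf; ++i) {
    pair[i] = f_pair[i]; ref[i] = f_ref[i]; start[i] = f_start[i];
    end[i] = f_end[i]; fwd1[i] = f_fwd1[i] != 0; frac[i] = f_frac[i];
  }
  return List::create(
    _["status"] = status,
    _["pair"] = pair, _["ref"] = ref, _["start"] = start, _["end"] = end,
    _["fwd1"] = fwd1, _["frac"] = frac,
    _["dup_violation"] = dup_violation);
}

// [[Rcpp::export(name = ".new_kmer_cache_cpp")]]
SEXP new_kmer_cache_cpp(double capacity) {
  if (capacity < 0) stop("cache capacity must be non-negative");
  XPtr<KmerCache> p(new KmerCache((size_t)capacity), true);
  return p;
}

// [[Rcpp::export(name = ".kmer_cache_size_cpp")]]
double kmer_cache_size_cpp(SEXP cache) {
  return (double)XPtr<KmerCache>(cache)->m.size();
}

// [[Rcpp::export(name = ".kmer_cache_capacity_cpp")]]
double kmer_cache_capacity_cpp(SEXP cache) {
  return (double)XPtr<KmerCache>(cache)->cap;
}

// [[Rcpp::export(name = ".kmer_cache_entries_cpp")]]
DataFrame kmer_cache_entries_cpp(SEXP cache, int k) {
  XPtr<KmerCache> p(cache);
  std::vector<std::pair<uint64_t, Entry> > v(p->m.begin(), p->m.end());
  std::sort(v.begin(), v.end(),
            [](const std::pair<uint64_t, Entry> &a,
               const std::pair<uint64_t, Entry> &b) { return a.first < b.first; });
  const R_xlen_t n = (R_xlen_t)v.size();
  CharacterVector kmer(n);
  IntegerVector uid(n), off(n);
  LogicalVector fwd(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    kmer[i] = decode_bits(v[i].first, k);
    uid[i] = v[i].second.uid;
    off[i] = v[i].second.off;
    fwd[i] = v[i].second.fwd != 0;
  }
  return DataFrame::create(_["kmer"] = kmer, _["uid"] = uid, _["off"] = off,
                           _["fwd"] = fwd, _["stringsAsFactors"] = false);
}
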