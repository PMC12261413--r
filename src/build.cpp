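#include "vcatac.h"
#include <algorithm>

using namespace Rcpp;

// Compacted reference de Bruijn graph construction.
//
// Nodes are canonical k-mers (lexicographic min of the k-mer and its reverse
// complement; k is odd so no k-mer equals its own reverse complement). Edges
// are implicit k-1 overlaps between k-mers present in the set. Unitigs are
// maximal non-branching paths, additionally split wherever a reference
// contig starts or ends mid-path, so that every reference is tiled by
// *complete* oriented unitig occurrences (the reference-cdBG convention).
// References are split into contigs at non-ACGT characters before k-mer
// extraction, so no k-mer spans an ambiguous base.

namespace {

struct Builder {
  int k;
  uint64_t mask;
  std::unordered_set<uint64_t> kset;

  uint64_t canon(uint64_t x) const {
    uint64_t r = revcomp_bits(x, k);
    return x < r ? x : r;
  }
  bool has(uint64_t x) const { return kset.count(canon(x)) > 0; }

  int succ_list(uint64_t x, uint64_t out[4]) const {
    int n = 0;
    for (uint64_t c = 0; c < 4; ++c) {
      uint64_t nx = ((x << 2) | c) & mask;
      if (has(nx)) out[n++] = nx;
    }
    return n;
  }
  int pred_list(uint64_t x, uint64_t out[4]) const {
    int n = 0;
    const int shift = 2 * (k - 1);
    for (uint64_t c = 0; c < 4; ++c) {
      uint64_t px = (x >> 2) | (c << shift);
      if (has(px)) out[n++] = px;
    }
    return n;
  }
  bool is_start(uint64_t x) const {
    uint64_t pin[4], out[4];
    if (pred_list(x, pin) != 1) return true;
    // hairpin: the unique predecessor is this k-mer's own reverse
    // complement, so a simple path cannot extend through it
    if (canon(pin[0]) == canon(x)) return true;
    return succ_list(pin[0], out) != 1;
  }
};

struct OccRec {
  int32_t uid, ref, pos;
  uint8_t fwd;
};

// iterate maximal ACGT runs of length >= k; cb(ref, start, end_exclusive)
template <typename F>
void for_each_contig(CharacterVector seqs, int k, F cb) {
  for (int r = 0; r < seqs.size(); ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, r));
    R_xlen_t start = -1;
    for (R_xlen_t i = 0; i <= n; ++i) {
      bool ok = (i < n) && base2bits(s[i]) >= 0;
      if (ok && start < 0) start = i;
      if (!ok && start >= 0) {
        if (i - start >= k) cb(r, start, i);
        start = -1;
      }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".build_index_cpp")]]
List build_index_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer between 1 and 31");
  Builder B;
  B.k = k;
  B.mask = (1ULL << (2 * k)) - 1ULL;

  std::vector<uint64_t> korder; // canonical k-mers in first-seen order

  // pass 1: collect distinct canonical k-mers
  for_each_contig(seqs, k, [&](int r, R_xlen_t from, R_xlen_t to) {
    (void)r;
    const char *s = CHAR(STRING_ELT(seqs, r));
    uint64_t cur = 0, rcur = 0;
    for (R_xlen_t i = from; i < to; ++i) {
      int b = base2bits(s[i]);
      cur = ((cur << 2) | (uint64_t)b) & B.mask;
      rcur = (rcur >> 2) | (((uint64_t)(b ^ 3)) << (2 * (k - 1)));
      if (i - from + 1 >= k) {
        uint64_t c = cur < rcur ? cur : rcur;
        if (B.kset.insert(c).second) korder.push_back(c);
      }
    }
  });
  if (korder.empty())
    stop("no indexable k-mer: no reference has a non-N stretch of length >= k");

  // pass 2: walk maximal non-branching paths
  std::unordered_map<uint64_t, Entry> kmap;
  kmap.reserve(korder.size() * 2);
  std::unordered_set<uint64_t> visited;
  visited.reserve(korder.size() * 2);
  std::vector<std::string> unitigs_v;

  auto emit_walk = [&](uint64_t start_x) {
    int32_t uid1 = (int32_t)unitigs_v.size() + 1;
    std::string useq = decode_bits(start_x, k);
    uint64_t cur = start_x;
    uint64_t curc = B.canon(cur);
    kmap[curc] = Entry{uid1, 0, (uint8_t)(cur == curc)};
    visited.insert(curc);
    int32_t offv = 0;
    uint64_t out[4], pin[4];
    while (true) {
      if (B.succ_list(cur, out) != 1) break;
      uint64_t nx = out[0];
      if (B.pred_list(nx, pin) != 1) break;
      uint64_t nc = B.canon(nx);
      if (visited.count(nc)) break;
      useq.push_back(bits2base(nx & 3ULL));
      ++offv;
      kmap[nc] = Entry{uid1, offv, (uint8_t)(nx == nc)};
      visited.insert(nc);
      cur = nx;
    }
    unitigs_v.push_back(std::move(useq));
  };

  for (uint64_t c : korder) {
    if (visited.count(c)) continue;
    if (B.is_start(c)) emit_walk(c);
    else if (B.is_start(revcomp_bits(c, k))) emit_walk(revcomp_bits(c, k));
    // interior k-mers are covered when their unitig's start is reached
  }
  for (uint64_t c : korder) { // leftovers lie on isolated cycles
    if (!visited.count(c)) emit_walk(c);
  }

  // pass 3: record cut points where a contig starts/ends mid-unitig, so
  // every reference occurrence of a (split) unitig is complete
  auto encode_at = [&](const char *s, R_xlen_t p, uint64_t &x) {
    x = 0;
    for (int i = 0; i < k; ++i) x = (x << 2) | (uint64_t)base2bits(s[p + i]);
  };
  std::vector<std::vector<int32_t> > cuts(unitigs_v.size());
  for_each_contig(seqs, k, [&](int r, R_xlen_t from, R_xlen_t to) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    uint64_t x;
    // first k-mer of the contig
    encode_at(s, from, x);
    {
      const Entry &e = kmap.find(B.canon(x))->second;
      bool q = (x == B.canon(x)) ? (e.fwd != 0) : (e.fwd == 0);
      int32_t cut = q ? e.off : e.off + 1;
      int32_t nku = (int32_t)unitigs_v[e.uid - 1].size() - k + 1;
      if (cut > 0 && cut < nku) cuts[e.uid - 1].push_back(cut);
    }
    // last k-mer of the contig
    encode_at(s, to - k, x);
    {
      const Entry &e = kmap.find(B.canon(x))->second;
      bool q = (x == B.canon(x)) ? (e.fwd != 0) : (e.fwd == 0);
      int32_t cut = q ? e.off + 1 : e.off;
      int32_t nku = (int32_t)unitigs_v[e.uid - 1].size() - k + 1;
      if (cut > 0 && cut < nku) cuts[e.uid - 1].push_back(cut);
    }
  });

  // pass 4: split unitigs at cut points, remap K->U entries
  std::vector<std::string> unitigs2;
  // per old unitig: sorted sub-unitig start offsets and new 1-based ids
  std::vector<std::vector<int32_t> > sub_start(unitigs_v.size());
  std::vector<std::vector<int32_t> > sub_uid(unitigs_v.size());
  for (size_t u = 0; u < unitigs_v.size(); ++u) {
    std::vector<int32_t> &cv = cuts[u];
    cv.push_back(0);
    std::sort(cv.begin(), cv.end());
    cv.erase(std::unique(cv.begin(), cv.end()), cv.end());
    int32_t nku = (int32_t)unitigs_v[u].size() - k + 1;
    for (size_t j = 0; j < cv.size(); ++j) {
      int32_t a = cv[j];
      int32_t b = (j + 1 < cv.size()) ? cv[j + 1] : nku;
      sub_start[u].push_back(a);
      sub_uid[u].push_back((int32_t)unitigs2.size() + 1);
      unitigs2.push_back(unitigs_v[u].substr(a, (b - a) + k - 1));
    }
  }
  for (auto &kv : kmap) {
    Entry &e = kv.second;
    const std::vector<int32_t> &ss = sub_start[e.uid - 1];
    size_t j = std::upper_bound(ss.begin(), ss.end(), e.off) - ss.begin() - 1;
    Entry ne{sub_uid[e.uid - 1][j], e.off - ss[j], e.fwd};
    e = ne;
  }
  unitigs_v.swap(unitigs2);

  // pass 5: tile each reference by oriented unitig occurrences (U->R)
  std::vector<OccRec> occs;
  for_each_contig(seqs, k, [&](int r, R_xlen_t from, R_xlen_t to) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    uint64_t cur = 0, rcur = 0;
    bool have_prev = false;
    OccRec prev{0, 0, 0, 0};
    for (R_xlen_t i = from; i < to; ++i) {
      int b = base2bits(s[i]);
      cur = ((cur << 2) | (uint64_t)b) & B.mask;
      rcur = (rcur >> 2) | (((uint64_t)(b ^ 3)) << (2 * (k - 1)));
      if (i - from + 1 < k) continue;
      int32_t p = (int32_t)(i - k + 1);
      uint64_t c = cur < rcur ? cur : rcur;
      const Entry &e = kmap.find(c)->second;
      bool q = (cur == c) ? (e.fwd != 0) : (e.fwd == 0);
      int32_t lu = (int32_t)unitigs_v[e.uid - 1].size();
      int32_t rpos = q ? p - e.off : p - (lu - k - e.off);
      OccRec oc{e.uid, (int32_t)r, rpos, (uint8_t)q};
      if (!have_prev || prev.uid != oc.uid || prev.fwd != oc.fwd ||
          prev.pos != oc.pos) {
        occs.push_back(oc);
        prev = oc;
        have_prev = true;
      }
    }
  });

  std::sort(occs.begin(), occs.end(), [](const OccRec &a, const OccRec &b) {
    if (a.uid != b.uid) return a.uid < b.uid;
    if (a.ref != b.ref) return a.ref < b.ref;
    if (a.pos != b.pos) return a.pos < b.pos;
    return a.fwd < b.fwd;
  });

  const int U = (int)unitigs_v.size();
  IntegerVector occ_ptr(U + 1), occ_ref(occs.size()), occ_pos(occs.size()),
    occ_fwd(occs.size());
  {
    std::vector<int> cnt(U + 1, 0);
    for (const OccRec &o : occs) cnt[o.uid] += 1;
    occ_ptr[0] = 0;
    for (int u = 1; u <= U; ++u) occ_ptr[u] = occ_ptr[u - 1] + cnt[u];
    for (size_t i = 0; i < occs.size(); ++i) {
      occ_ref[i] = occs[i].ref;
      occ_pos[i] = occs[i].pos;
      occ_fwd[i] = occs[i].fwd;
    }
  }

  // sorted canonical k-mer table (uint64 order) for binary search
  std::vector<std::pair<uint64_t, Entry> > tab(kmap.begin(), kmap.end());
  std::sort(tab.begin(), tab.end(),
            [](const std::pair<uint64_t, Entry> &a,
               const std::pair<uint64_t, Entry> &b) { return a.first < b.first; });

  const R_xlen_t nk = (R_xlen_t)tab.size();
  IntegerVector khi(nk), klo(nk), kuid(nk), koff(nk), kfwd(nk);
  for (R_xlen_t i = 0; i < nk; ++i) {
    khi[i] = (int32_t)(uint32_t)(tab[i].first >> 32);
    klo[i] = (int32_t)(uint32_t)(tab[i].first & 0xffffffffULL);
    kuid[i] = tab[i].second.uid;
    koff[i] = tab[i].second.off;
    kfwd[i] = tab[i].second.fwd;
  }

  CharacterVector unitigs(U);
  IntegerVector ulen(U);
  for (int u = 0; u < U; ++u) {
    unitigs[u] = unitigs_v[u];
    ulen[u] = (int)unitigs_v[u].size();
  }

  return List::create(
    _["k"] = k,
    _["unitigs"] = unitigs,
    _["unitig_len"] = ulen,
    _["kmer_hi"] = khi, _["kmer_lo"] = klo,
    _["kmer_uid"] = kuid, _["kmer_off"] = koff, _["kmer_fwd"] = kfwd,
    _["occ_ptr"] = occ_ptr, _["occ_ref"] = occ_ref,
    _["occ_pos"] = occ_pos, _["occ_fwd"] = occ_fwd);
}
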